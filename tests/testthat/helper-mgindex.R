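# Shared fixtures and independent oracles for the test suite.

# brute-force comb membership: check every (reflection, node) pair
bruteCombMembers <- function(projections, dstar, eps, qmax) {
  nmax <- floor(qmax / dstar * (1 + 1e-12))
  if (nmax < 1 || !length(projections)) return(integer(0))
  nodes <- c(-(nmax:1), seq_len(nmax)) * dstar
  which(vapply(projections, function(x) any(abs(x - nodes) <= eps), TRUE))
}

granitePhases <- function()
  unname(builtinPhases(c("quartz", "biotite", "orthoclase", "plagioclase")))

# single-grain scene plus the rotation used for it (replaying the
# simulator's seeded RNG stream)
singleGrainScene <- function(phaseName = "cementite", sigma = 1e-4,
                             seed = 1L, qMin = 0.1, qMax = 0.6,
                             cell = NULL) {
  phase <- if (is.null(cell)) builtinPhases(phaseName)[[1]]
           else PhaseSpec(phaseName, cell)
  cfg <- SimulationConfig(list(phase), 1L, qMin = qMin, qMax = qMax,
                          sigma = sigma, seed = seed)
  pool <- simulatePool(cfg)
  set.seed(seed)
  R <- randomOrientation()
  A <- directBasisFromCell(phase@cell) %*% t(R)   # rotated direct basis
  list(pool = pool, phase = phase, rotation = R, basis = A)
}

# uniformly random points in the spherical shell [qMin, qMax]
uniformShell <- function(n, qMin, qMax) {
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  r <- (qMin^3 + stats::runif(n) * (qMax^3 - qMin^3))^(1 / 3)
  u * r
}

# small hand-built labeled pool + indexed grains for evaluation tests
fakeIndexedGrain <- function(serial, basis, index, distance = 0) {
  n <- length(index)
  methods::new("IndexedGrain", serial = as.integer(serial), basis = basis,
               cell = cellFromBasis(basis),
               assignments = data.frame(h = seq_len(n), k = 0L, l = 0L,
                                        index = as.integer(index),
                                        distance = rep(distance, n)),
               matchedCount = as.integer(n))
}
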