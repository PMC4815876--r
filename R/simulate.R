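# Forward simulator: multiphase grain ensembles -> noisy g-vector pools with
# ground-truth labels. Geometry-free: every reciprocal lattice point of a
# grain with q_min <= |g| <= q_max is observed (full-rotation coverage, both
# Friedel mates), with i.i.d. Gaussian noise on each Cartesian component.

#' Random orientation
#'
#' Draws a rotation matrix uniformly from SO(3) (Haar measure) via a
#' normalized Gaussian quaternion. Uses the current RNG stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @return 3 x 3 proper rotation matrix.
#' @export
randomOrientation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Reflections of one grain
#'
#' Enumerates every integer triplet `h != (0,0,0)` whose rotated reciprocal
#' lattice point has length in `[qMin, qMax]` and passes the phase's
#' reflection condition. Both Friedel mates are present. The per-axis search
#' bound follows from `|h_i| = |g . a_i| <= qMax |a_i|`.
#'
#' @param phase A [PhaseSpec-class].
#' @param orientation 3 x 3 rotation applied to the grain.
#' @param qMin,qMax Observable g-length range (1/Angstrom).
#' @return List with `hkl` (n x 3 integer) and `g` (n x 3 numeric, 1/Angstrom).
#' @export
grainReflections <- function(phase, orientation = diag(3), qMin, qMax) {
  stopifnot(qMin < qMax)
  A <- directBasisFromCell(phase@cell)
  B <- reciprocalBasis(A)
  hmax <- floor(qMax * sqrt(rowSums(A^2)) * (1 + 1e-12))
  H <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                             l = -hmax[3]:hmax[3], KEEP.OUT.ATTRS = FALSE))
  dimnames(H) <- NULL
  H <- H[rowSums(H != 0L) > 0L, , drop = FALSE]
  if (!is.null(phase@condition))
    H <- H[phase@condition(H), , drop = FALSE]
  G <- H %*% (B %*% t(orientation))
  q <- sqrt(rowSums(G^2))
  keep <- q >= qMin & q <= qMax
  list(hkl = H[keep, , drop = FALSE], g = G[keep, , drop = FALSE])
}

#' Simulate a multiphase g-vector pool
#'
#' Draws a uniformly random orientation for every grain, collects its
#' reflections in the configured q-range, pools everything, and adds
#' independent Gaussian noise (standard deviation `sigma`) to each Cartesian
#' component. Fully reproducible from the configuration seed.
#'
#' @param config A [SimulationConfig-class].
#' @return A [GVectorPool-class] with truth labels (`grain`, `phase`, `h`,
#'   `k`, `l`).
#' @examples
#' cfg <- SimulationConfig(builtinPhases("cementite"), 2, qMin = 0.1,
#'                         qMax = 0.6, sigma = 1e-4, seed = 7)
#' simulatePool(cfg)
#' @export
simulatePool <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  gs <- list(); hs <- list(); lab <- list()
  serial <- 0L
  for (p in seq_along(config@phases)) {
    phase <- config@phases[[p]]
    for (k in seq_len(config@grainsPerPhase[p])) {
      serial <- serial + 1L
      R <- randomOrientation()
      refl <- grainReflections(phase, R, config@qMin, config@qMax)
      n <- nrow(refl$g)
      gs[[serial]] <- refl$g
      hs[[serial]] <- refl$hkl
      lab[[serial]] <- data.frame(grain = rep(serial, n),
                                  phase = rep(phase@name, n))
    }
  }
  if (serial == 0L)
    return(GVectorPool(matrix(numeric(0), 0, 3),
                       labels = data.frame(grain = integer(0),
                                           phase = character(0),
                                           h = integer(0), k = integer(0),
                                           l = integer(0))))
  G <- do.call(rbind, gs)
  H <- do.call(rbind, hs)
  labels <- do.call(rbind, lab)
  labels$h <- H[, 1]; labels$k <- H[, 2]; labels$l <- H[, 3]
  rownames(labels) <- NULL
  if (config@sigma > 0)
    G <- G + matrix(stats::rnorm(length(G), 0, config@sigma), nrow(G), 3)
  GVectorPool(G, labels = labels)
}
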