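# Cell correction, least-squares refinement, grain peeling and the global
# stopping rule.

# Canonical transformations to the distinct sublattices of the direct
# lattice with index n (their reciprocal lattices are denser, i.e. the cell
# volume grows n-fold): the Hermite normal forms with determinant n — upper
# triangular, positive diagonal with product n, above-diagonal entries
# reduced modulo the diagonal of their column. There are 7 for n = 2 and 13
# for n = 3; every integer matrix with |det| = n generates the same lattice
# as exactly one of them.
.supercellTransforms <- function(dets = c(2L, 3L)) {
  out <- list()
  for (n in dets) {
    divs <- which(n %% seq_len(n) == 0L)
    for (d1 in divs) for (d2 in which((n %/% d1) %% seq_len(n %/% d1) == 0L)) {
      d3 <- n %/% (d1 * d2)
      for (b in seq_len(d2) - 1L) for (cc in seq_len(d3) - 1L)
        for (e in seq_len(d3) - 1L)
          out[[length(out) + 1L]] <- rbind(c(d1, b, cc),
                                           c(0L, d2, e),
                                           c(0L, 0L, d3))
    }
  }
  out
}

#' Supercell check
#'
#' The shortest-independent-vector heuristic can land on a sub-cell (a
#' sublattice of the true reciprocal lattice whose direct cell is a half or
#' a third of the true one). This check re-indexes the pool against every
#' distinct enlargement of the cell volume by a factor in `dets` (simple
#' integer combinations of the basis vectors) and accepts the best one iff
#' it matches more than 20% more reflections; the accepted cell is checked
#' again (at most two rounds, covering volume factors up to 9).
#'
#' @param hypothesis A [GrainHypothesis-class].
#' @param pool A [GVectorPool-class].
#' @param params A [CombParams-class].
#' @param dets Allowed volume-enlargement factors (subset of 2:3).
#' @return A [GrainHypothesis-class] matching at least as many reflections
#'   as the input.
#' @export
trySupercells <- function(hypothesis, pool, params, dets = c(2L, 3L)) {
  if (!length(dets)) return(hypothesis)
  Ms <- .supercellTransforms(as.integer(dets))
  cur <- hypothesis
  for (round in 1:2) {
    best <- NULL
    for (M in Ms) {
      h2 <- indexAgainstPool(M %*% cur@basis, pool, params)
      if (is.null(best) || h2@matchedCount > best@matchedCount) best <- h2
    }
    if (!is.null(best) && best@matchedCount > 1.2 * cur@matchedCount)
      cur <- best
    else break
  }
  cur
}

#' Least-squares basis refinement
#'
#' Given hkl-to-g-vector assignments, finds the reciprocal basis `B`
#' minimizing `sum_i |h_i B - g_i|^2` (closed-form linear least squares) and
#' returns the corresponding direct basis (inverse transpose).
#'
#' @param hkl n x 3 matrix of Miller indices (rank 3 required).
#' @param g n x 3 matrix of the assigned g-vectors (1/Angstrom).
#' @return 3 x 3 refined direct basis (Angstrom).
#' @export
refineBasis <- function(hkl, g) {
  H <- as.matrix(hkl)
  storage.mode(H) <- "double"
  dimnames(H) <- NULL
  if (nrow(H) < 3L || qr(H)$rank < 3L)
    stop("rank-deficient hkl set: need 3 non-coplanar Miller indices")
  B <- qr.solve(H, as.matrix(g))
  t(solve(B))
}

#' Attempt to index one grain
#'
#' One iteration of the outer loop: two-pass candidate search, basis
#' determination and validation, supercell check, then a refine / re-index /
#' refine cycle so reflections joining after refinement inform the final
#' basis. On success the assigned reflections are marked inactive (peeled)
#' in the returned pool; on failure the pool is returned untouched.
#'
#' @param pool A [GVectorPool-class].
#' @param config An [IndexingConfig-class].
#' @param serial Serial number given to the grain if found.
#' @return List with `grain` (an [IndexedGrain-class] or `NULL`) and `pool`.
#' @export
indexOneGrain <- function(pool, config, serial = 1L) {
  if (nActive(pool) < config@minReflections)
    return(list(grain = NULL, pool = pool))
  params <- config@comb
  cands <- findCandidates(pool, params, config@search)
  hyp <- bestHypothesis(cands, pool, params, config@minReflections)
  if (is.null(hyp)) return(list(grain = NULL, pool = pool))
  hyp <- trySupercells(hyp, pool, params, config@supercellDets)
  for (cycle in 1:2) {
    a <- hyp@assignments
    bas <- tryCatch(
      refineBasis(as.matrix(a[, c("h", "k", "l")]),
                  pool@gvec[a$index, , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(bas)) break
    h2 <- indexAgainstPool(bas, pool, params)
    if (h2@matchedCount < 3L) break
    hyp <- h2
  }
  if (hyp@matchedCount < config@minReflections)
    return(list(grain = NULL, pool = pool))
  pool@active[hyp@assignments$index] <- FALSE
  grain <- methods::new("IndexedGrain", serial = as.integer(serial),
                        basis = hyp@basis,
                        cell = cellFromBasis(hyp@basis),
                        assignments = hyp@assignments,
                        matchedCount = hyp@matchedCount)
  list(grain = grain, pool = pool)
}

#' Run the full indexing loop
#'
#' Repeats [indexOneGrain()], peeling each found grain's reflections from
#' the pool, until `nT` consecutive attempts fail or fewer than
#' `minReflections` reflections remain active. Fully reproducible from the
#' configuration seed.
#'
#' @param pool A [GVectorPool-class].
#' @param config An [IndexingConfig-class].
#' @param verbose Log per-iteration progress to stderr.
#' @return An [IndexingResult-class].
#' @examples
#' cfg <- SimulationConfig(builtinPhases("cementite"), 2, qMin = 0.1,
#'                         qMax = 0.6, sigma = 1e-4, seed = 3)
#' pool <- simulatePool(cfg)
#' icfg <- IndexingConfig(search = SearchConfig(nU1 = 800, nU2 = 400),
#'                        seed = 3)
#' runIndexing(pool, icfg)
#' @export
runIndexing <- function(pool, config, verbose = FALSE) {
  set.seed(config@seed)
  grainsList <- list()
  fails <- 0L
  iter <- 0L
  logRows <- list()
  repeat {
    if (nActive(pool) < config@minReflections) {
      reason <- "too few remaining reflections"
      break
    }
    iter <- iter + 1L
    res <- indexOneGrain(pool, config, serial = length(grainsList) + 1L)
    pool <- res$pool
    found <- !is.null(res$grain)
    if (found) {
      fails <- 0L
      grainsList[[length(grainsList) + 1L]] <- res$grain
    } else {
      fails <- fails + 1L
    }
    logRows[[iter]] <- data.frame(
      iteration = iter, found = found,
      matched = if (found) res$grain@matchedCount else 0L,
      volume = if (found) cellVolume(res$grain@cell) else NA_real_,
      activeLeft = nActive(pool))
    if (verbose)
      message(sprintf("iteration %d: %s, %d reflections left", iter,
                      if (found) sprintf("grain %d (%d reflections, V=%.1f)",
                                         res$grain@serial,
                                         res$grain@matchedCount,
                                         cellVolume(res$grain@cell))
                      else "no grain", nActive(pool)))
    if (fails >= config@nT) {
      reason <- sprintf("%d consecutive failed tries", fails)
      break
    }
  }
  methods::new("IndexingResult", grains = grainsList, pool = pool,
               stopReason = reason,
               log = if (length(logRows)) do.call(rbind, logRows)
                     else data.frame(iteration = integer(0),
                                     found = logical(0),
                                     matched = integer(0),
                                     volume = numeric(0),
                                     activeLeft = integer(0)))
}
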