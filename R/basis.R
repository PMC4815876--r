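# From a cleaned candidate subset to a direct-lattice basis: candidate
# plane-normal directions from triples of low-q reflections, a best spacing
# per direction taken from the projected values themselves (80% count rule),
# the three shortest independent direct vectors, and validation of the
# resulting lattice against the full pool.

#' Plane normals from reflection triples
#'
#' For every unordered triple among the `nClosest` reflections nearest the
#' origin, the unit normal of the plane through the three points,
#' `(r2 - r1) x (r3 - r1)`, discarding near-degenerate triples whose cross
#' product is shorter than `minCrossRel` times the product of the edge
#' lengths. Antipodally equivalent directions closer than `dedupAngleDeg`
#' are merged (first occurrence kept).
#'
#' @param G n x 3 matrix of subset g-vectors (n >= 3).
#' @param nClosest Number of lowest-|g| reflections used.
#' @param minCrossRel Relative cross-product cutoff for degeneracy.
#' @param dedupAngleDeg Merge angle in degrees.
#' @return m x 3 matrix of unit directions (possibly zero rows).
#' @export
tripleNormals <- function(G, nClosest = 50L, minCrossRel = 0.01,
                          dedupAngleDeg = 1.0) {
  G <- as.matrix(G)
  if (nrow(G) < 3L) stop("need at least 3 reflections")
  q <- sqrt(rowSums(G^2))
  S <- G[order(q)[seq_len(min(nClosest, nrow(G)))], , drop = FALSE]
  cmb <- utils::combn(nrow(S), 3L)
  r1 <- S[cmb[1, ], , drop = FALSE]
  d1 <- S[cmb[2, ], , drop = FALSE] - r1
  d2 <- S[cmb[3, ], , drop = FALSE] - r1
  n <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
             d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
             d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  nn <- sqrt(rowSums(n^2))
  keep <- nn >= minCrossRel * sqrt(rowSums(d1^2)) * sqrt(rowSums(d2^2))
  if (!any(keep)) return(matrix(numeric(0), 0, 3))
  n <- n[keep, , drop = FALSE] / nn[keep]
  neg <- n[, 3] < 0 | (n[, 3] == 0 & (n[, 2] < 0 |
                                      (n[, 2] == 0 & n[, 1] < 0)))
  n[neg, ] <- -n[neg, ]
  n[cpp_dedup_dirs(n, cos(.deg2rad(dedupAngleDeg))), , drop = FALSE]
}

#' Best one-dimensional lattice along a direction, spacings from the data
#'
#' Candidate spacings are the absolute projected values themselves (within
#' `[dstarMin, dstarMax]`); each is scored by [combCount()] on the subset and
#' the LARGEST spacing with a count within 80% of the maximum is returned —
#' sub-multiples of the true spacing index the same reflections, so the
#' largest near-maximal spacing is the fundamental one.
#'
#' @param G n x 3 matrix of subset g-vectors.
#' @param direction Unit 3-vector.
#' @param params A [CombParams-class].
#' @return List with `dstar` and `count`, or `NULL` when no projected value
#'   falls in the spacing range.
#' @export
latticeOnDirection <- function(G, direction, params) {
  .checkUnit(direction)
  proj <- as.numeric(as.matrix(G) %*% direction)
  cand <- abs(proj)
  cand <- cand[cand >= params@dstarMin & cand <= params@dstarMax]
  if (!length(cand)) return(NULL)
  # reflections in the central plane (projection ~ 0) are consistent with
  # any direct vector along this direction and count toward every spacing;
  # leaving them out would bias the comparison against short vectors, whose
  # zero-projection plane holds a sizable share of the subset
  nZero <- sum(abs(proj) <= params@epsilon)
  # projected values of one lattice plane differ only by reflection noise
  # (well under the box half-width); collapse each such cluster to its
  # centroid — an extreme cluster member is ~epsilon off center, an error
  # the outermost comb node amplifies n-fold
  cand <- sort.int(cand)
  grp <- cumsum(c(TRUE, diff(cand) > params@epsilon / 2))
  cand <- as.numeric(rowsum.default(cand, grp)) / tabulate(grp)
  counts <- cpp_count_multi(proj, cand, params@epsilon, params@qMax) + nZero
  ok <- counts >= 0.8 * max(counts)
  i <- which(ok)[which.max(cand[ok])]
  list(dstar = cand[i], count = as.integer(counts[i]))
}

#' Potential direct-lattice vectors of a candidate grain
#'
#' Applies [latticeOnDirection()] to each direction, polishes each
#' surviving (direction, spacing) pair with [refineCombLS()] — a
#' triple-normal direction carries the angular noise of a single reflection
#' triple, enough to scramble the counts the 80% rule relies on — drops
#' directions whose polished count falls below 80% of the best count over
#' all directions, and converts the survivors to direct-space vectors
#' `direction / dstar` (length `1/dstar` Angstrom).
#'
#' @param G n x 3 matrix of subset g-vectors.
#' @param directions m x 3 matrix of unit directions (from
#'   [tripleNormals()]).
#' @param params A [CombParams-class].
#' @return List with `vectors` (k x 3, Angstrom), `dstar`, `count`.
#' @export
collectDirectVectors <- function(G, directions, params) {
  G <- as.matrix(G)
  res <- apply(directions, 1L, latticeOnDirection, G = G, params = params,
               simplify = FALSE)
  ok <- which(!vapply(res, is.null, TRUE))
  if (!length(ok))
    return(list(vectors = matrix(numeric(0), 0, 3), dstar = numeric(0),
                count = integer(0)))
  snap <- cpp_snap_ls(G, directions[ok, , drop = FALSE],
                      vapply(res[ok], `[[`, 0, "dstar"), params@epsilon,
                      params@qMin, params@qMax, params@dstarMin,
                      params@dstarMax, 12L, includeOrigin = TRUE)
  dirs <- snap[, 1:3, drop = FALSE]
  dstar <- snap[, 4]
  count <- snap[, 5]
  keep <- count >= 0.8 * max(count)
  list(vectors = dirs[keep, , drop = FALSE] / dstar[keep],
       dstar = dstar[keep], count = as.integer(count[keep]))
}

#' Shortest independent direct vectors spanning the minimal cell
#'
#' Selects three genuinely independent candidate vectors forming the cell
#' of minimal volume: among the shortest candidates (up to 40), every trio
#' whose scalar triple product exceeds 0.01 times the product of its
#' lengths (and whose pairwise angles have sine above 0.01) is considered,
#' and the one with the smallest |determinant| wins, ties broken toward
#' shorter vectors. Taking the three shortest independent vectors alone can
#' land on a trio spanning only a sublattice of the candidates' lattice (a
#' doubled cell) when one short lattice vector escaped detection; the
#' minimal-volume trio is the primitive cell of whatever lattice the
#' candidates support. The returned basis is right-handed (third vector
#' flipped if needed), rows ordered by increasing length.
#'
#' @param vectors k x 3 matrix of candidate direct vectors (Angstrom).
#' @return 3 x 3 direct basis (rows = vectors), or `NULL` when fewer than
#'   three independent vectors exist.
#' @export
chooseBasis <- function(vectors) {
  if (is.null(vectors) || nrow(vectors) < 3L) return(NULL)
  len <- sqrt(rowSums(vectors^2))
  ord <- order(len)[seq_len(min(40L, nrow(vectors)))]
  V <- vectors[ord, , drop = FALSE]
  len <- len[ord]
  k <- nrow(V)
  cmb <- utils::combn(k, 3L)
  i1 <- cmb[1, ]; i2 <- cmb[2, ]; i3 <- cmb[3, ]
  cr <- cbind(V[i2, 2] * V[i3, 3] - V[i2, 3] * V[i3, 2],
              V[i2, 3] * V[i3, 1] - V[i2, 1] * V[i3, 3],
              V[i2, 1] * V[i3, 2] - V[i2, 2] * V[i3, 1])
  dets <- rowSums(V[i1, , drop = FALSE] * cr)
  lp <- len[i1] * len[i2] * len[i3]
  sin12 <- sqrt(pmax(0, 1 - (rowSums(V[i1, , drop = FALSE] *
                                     V[i2, , drop = FALSE]) /
                             (len[i1] * len[i2]))^2))
  ok <- abs(dets) > 0.01 * lp & sin12 > 0.01
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  best <- cand[order(abs(dets[cand]), lp[cand])][1]
  chosen <- V[cmb[, best], , drop = FALSE]
  chosen <- chosen[order(sqrt(rowSums(chosen^2))), , drop = FALSE]
  if (det(chosen) < 0) chosen[3, ] <- -chosen[3, ]
  dimnames(chosen) <- NULL
  chosen
}

#' Index the full pool against a candidate basis
#'
#' Enumerates every reciprocal lattice point of the basis with
#' `|g| <= qMax + 5 epsilon` (per-axis bound `|h_i| <= |a_i| (qMax + 5
#' epsilon)`), finds the nearest ACTIVE reflection to each point, and keeps
#' assignments closer than `5 epsilon`. Conflicts — several lattice points
#' nearest to one reflection — are resolved greedily by ascending distance,
#' so assignments are one-to-one.
#'
#' @param basis 3 x 3 direct basis (rows = lattice vectors, Angstrom).
#' @param pool A [GVectorPool-class].
#' @param params A [CombParams-class] (uses `epsilon`, `qMax`).
#' @return A [GrainHypothesis-class].
#' @export
indexAgainstPool <- function(basis, pool, params) {
  d <- det(basis)
  if (!is.finite(d) || abs(d) < 1e-12) stop("singular basis")
  B <- reciprocalBasis(basis)
  qlim <- params@qMax + 5 * params@epsilon
  hmax <- floor(qlim * sqrt(rowSums(basis^2)) * (1 + 1e-12))
  H <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                             l = -hmax[3]:hmax[3], KEEP.OUT.ATTRS = FALSE))
  dimnames(H) <- NULL
  H <- H[rowSums(H != 0L) > 0L, , drop = FALSE]
  P <- H %*% B
  keep <- sqrt(rowSums(P^2)) <= qlim
  H <- H[keep, , drop = FALSE]
  P <- P[keep, , drop = FALSE]
  idxActive <- which(activeMask(pool))
  empty <- data.frame(h = integer(0), k = integer(0), l = integer(0),
                      index = integer(0), distance = numeric(0))
  if (!length(idxActive) || !nrow(P))
    return(methods::new("GrainHypothesis", basis = basis,
                        assignments = empty, matchedCount = 0L))
  nr <- cpp_nearest(P, pool@gvec[idxActive, , drop = FALSE])
  ok <- which(nr$distance < 5 * params@epsilon)
  ok <- ok[order(nr$distance[ok])]
  sel <- ok[!duplicated(nr$index[ok])]
  assign <- data.frame(h = H[sel, 1], k = H[sel, 2], l = H[sel, 3],
                       index = idxActive[nr$index[sel]],
                       distance = nr$distance[sel])
  methods::new("GrainHypothesis", basis = basis, assignments = assign,
               matchedCount = nrow(assign))
}

#' Best grain hypothesis among candidate subsets
#'
#' Runs the basis-determination chain (triple normals, spacing from
#' projections, minimal-cell vector trio) on each candidate grain,
#' validates each resulting lattice against the full pool, and returns the
#' hypothesis matching the most reflections — provided it reaches
#' `minReflections`, otherwise `NULL` (caller retries with fresh random
#' directions). Hypotheses whose matched counts lie within 5% of the best
#' are treated as ties and resolved toward the smallest cell volume: a
#' lattice of a multiple cell volume indexes every reflection the true
#' lattice does plus a handful of chance coincidences from its surplus
#' lattice points, so a razor-thin count advantage must not outrank a
#' smaller cell.
#'
#' @param candidates List of [CandidateGrain-class].
#' @param pool A [GVectorPool-class].
#' @param params A [CombParams-class].
#' @param minReflections Acceptance threshold on the matched count.
#' @return A [GrainHypothesis-class] or `NULL`.
#' @export
bestHypothesis <- function(candidates, pool, params, minReflections = 20L) {
  hyps <- list()
  for (cand in candidates) {
    Gs <- pool@gvec[cand@members, , drop = FALSE]
    if (nrow(Gs) < 3L) next
    dirs <- tripleNormals(Gs)
    if (nrow(dirs) == 0L) next
    dv <- collectDirectVectors(Gs, dirs, params)
    bas <- chooseBasis(dv$vectors)
    if (is.null(bas)) next
    hyps[[length(hyps) + 1L]] <- indexAgainstPool(bas, pool, params)
  }
  if (!length(hyps)) return(NULL)
  matched <- vapply(hyps, function(h) h@matchedCount, 0L)
  vol <- vapply(hyps, function(h) abs(det(h@basis)), 0)
  near <- which(matched >= 0.95 * max(matched))
  best <- hyps[[near[order(vol[near], -matched[near])[1]]]]
  if (best@matchedCount >= minReflections) best else NULL
}
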