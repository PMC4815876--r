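# members of a candidate's comb plus the reflections in its central plane
# (|projection| <= epsilon): a zero projection is consistent with the 1-D
# lattice, and a grain's reflections perpendicular to the comb direction
# belong in its candidate subset even though the scan scores combs without
# an origin node
.membersWithOrigin <- function(G, candidate, params) {
  proj <- as.numeric(G %*% candidate@direction)
  cc <- combCount(proj, candidate@dstar, params)
  sort(union(cc$members, which(abs(proj) <= params@epsilon)))
}

# Two-pass random-direction candidate search: pass 1 scans many random
# directions over the full active pool and keeps the best-scoring
# one-dimensional lattices; pass 2 re-runs the scan on each candidate's
# member subset along fresh directions (away from the first direction, with a
# wider box) to shed chance members from other grains.

#' Sample random directions
#'
#' Uniform directions on the unit hemisphere (antipodal directions are
#' equivalent for the symmetric comb): normalized Gaussian 3-vectors folded
#' to non-negative z. Uses the current RNG stream.
#'
#' @param n Number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
sampleDirections <- function(n) {
  stopifnot(n >= 1)
  U <- matrix(stats::rnorm(3 * n), n, 3)
  U <- U / sqrt(rowSums(U^2))
  flip <- U[, 3] < 0 |
    (U[, 3] == 0 & (U[, 2] < 0 | (U[, 2] == 0 & U[, 1] < 0)))
  U[flip, ] <- -U[flip, ]
  U
}

#' First search pass over the full pool
#'
#' Scans `nU1` random directions with [scanDstar()] (vectorized in C++),
#' keeps the `topK` candidates with the highest background-subtracted
#' scores, refines each with [refineLocal()], and returns them re-ranked,
#' with member indices referring to pool rows.
#'
#' @param pool A [GVectorPool-class].
#' @param params A [CombParams-class].
#' @param search A [SearchConfig-class].
#' @return List of [LatticeCandidate-class], best first.
#' @export
firstPass <- function(pool, params, search) {
  G <- gVectors(pool, activeOnly = TRUE)
  if (nrow(G) == 0L) return(list())
  idxActive <- which(activeMask(pool))
  U <- sampleDirections(search@nU1)
  grid <- dstarGrid(params)
  bg <- .backgroundOnGrid(nrow(G), grid, params)
  res <- cpp_scan_dirs(G, U, grid, bg, params@epsilon, params@qMax)
  # snap every scanned (direction, spacing) onto the 1-D lattice its comb
  # members suggest: a sampled direction is typically a fraction of a degree
  # off a lattice direction, catching only the inner-node reflections, and
  # its raw score badly understates the aligned comb
  snap <- cpp_snap_ls(G, U, res[, 1], params@epsilon, params@qMin,
                      params@qMax, params@dstarMin, params@dstarMax, 12L)
  take <- order(snap[, 6], decreasing = TRUE)[seq_len(min(search@topK,
                                                          nrow(U)))]
  cands <- lapply(take, function(m) {
    u <- snap[m, 1:3]
    cc <- combCount(as.numeric(G %*% u), snap[m, 4], params)
    cand <- methods::new("LatticeCandidate", direction = u,
                         dstar = snap[m, 4], rawCount = as.numeric(cc$count),
                         score = snap[m, 6], members = cc$members)
    refineCombLS(G, refineLocal(G, cand, params), params)
  })
  ord <- order(vapply(cands, function(x) x@score, 0), decreasing = TRUE)
  lapply(cands[ord], function(cand) {
    cand@members <- idxActive[.membersWithOrigin(G, cand, params)]
    cand
  })
}

#' Second (cleaning) pass on a candidate subset
#'
#' Repeats the random-direction scan restricted to the candidate's member
#' reflections, with box half-width `epsilon2Factor * epsilon` and directions
#' at more than `minAngleDeg` degrees from the first-pass direction. The best
#' refined lattice's members (a subset of the input members) become the
#' cleaned candidate grain.
#'
#' @param candidate A [LatticeCandidate-class] from [firstPass()] (members
#'   are pool indices).
#' @param pool A [GVectorPool-class].
#' @param params A [CombParams-class].
#' @param search A [SearchConfig-class].
#' @return A [CandidateGrain-class], or `NULL` when the subset has fewer
#'   than 4 reflections or no direction survives the exclusion cone.
#' @export
secondPass <- function(candidate, pool, params, search) {
  mem <- candidate@members
  if (length(mem) < 4L) return(NULL)
  Gs <- pool@gvec[mem, , drop = FALSE]
  params2 <- CombParams(epsilon = params@epsilon * search@epsilon2Factor,
                        qMax = params@qMax, dstarMin = params@dstarMin,
                        qMin = params@qMin, dstarMax = params@dstarMax)
  U <- sampleDirections(search@nU2)
  keep <- abs(U %*% candidate@direction) <=
    cos(.deg2rad(search@minAngleDeg))
  U <- U[keep, , drop = FALSE]
  if (nrow(U) == 0L) return(NULL)
  grid <- dstarGrid(params2)
  bg <- .backgroundOnGrid(nrow(Gs), grid, params2)
  res <- cpp_scan_dirs(Gs, U, grid, bg, params2@epsilon, params2@qMax)
  snap <- cpp_snap_ls(Gs, U, res[, 1], params2@epsilon, params2@qMin,
                      params2@qMax, params2@dstarMin, params2@dstarMax, 12L)
  take <- order(snap[, 6], decreasing = TRUE)[seq_len(min(search@topK,
                                                          nrow(U)))]
  cands <- lapply(take, function(m) {
    u <- snap[m, 1:3]
    cc <- combCount(as.numeric(Gs %*% u), snap[m, 4], params2)
    cand <- methods::new("LatticeCandidate", direction = u,
                         dstar = snap[m, 4], rawCount = as.numeric(cc$count),
                         score = snap[m, 6], members = cc$members)
    refineCombLS(Gs, refineLocal(Gs, cand, params2), params2)
  })
  best <- cands[[which.max(vapply(cands, function(x) x@score, 0))]]
  bestMembers <- .membersWithOrigin(Gs, best, params2)
  if (length(bestMembers) == 0L) return(NULL)
  methods::new("CandidateGrain",
               members = as.integer(mem[bestMembers]),
               provenance = list(
                 first = list(direction = candidate@direction,
                              dstar = candidate@dstar),
                 second = list(direction = best@direction,
                               dstar = best@dstar)))
}

#' Candidate grains from the two-pass search
#'
#' Runs [firstPass()], keeps the `nJ` best candidates, and cleans each with
#' [secondPass()]. Results are ordered by descending first-pass score.
#'
#' @param pool A [GVectorPool-class].
#' @param params A [CombParams-class].
#' @param search A [SearchConfig-class].
#' @return List of [CandidateGrain-class] (possibly shorter than `nJ`).
#' @export
findCandidates <- function(pool, params, search) {
  fp <- firstPass(pool, params, search)
  fp <- fp[seq_len(min(search@nJ, length(fp)))]
  out <- lapply(fp, secondPass, pool = pool, params = params,
                search = search)
  out[!vapply(out, is.null, TRUE)]
}
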