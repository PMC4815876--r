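# One-dimensional lattice detection: project g-vectors onto a direction and
# count members of a symmetric comb of boxes (half-width epsilon, spacing
# dstar, nodes +-n*dstar, no node at the origin), minus the expected count
# for reflections placed uniformly at random in the spherical shell
# [qMin, qMax].

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.checkUnit <- function(direction) {
  if (length(direction) != 3L || abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    stop("direction must be a unit 3-vector")
  invisible(direction)
}

#' Project g-vectors onto a direction
#'
#' Signed scalar projections `x_i = g_i . u` of the active reflections, in
#' pool order.
#'
#' @param pool A [GVectorPool-class] or an n x 3 matrix.
#' @param direction Unit 3-vector.
#' @return Numeric vector of signed projections.
#' @export
projectPool <- function(pool, direction) {
  .checkUnit(direction)
  G <- if (methods::is(pool, "GVectorPool")) gVectors(pool, activeOnly = TRUE)
       else as.matrix(pool)
  as.numeric(G %*% direction)
}

#' Adaptive spacing grid
#'
#' Spacings scanned by [scanDstar()]: from `dstarMin` to `dstarMax` with
#' steps `epsilon / floor(qMax / dstar)`, so the comb node furthest from the
#' origin (within `qMax`) moves by at most `epsilon` per step and no
#' one-dimensional lattice can slip between consecutive grid values.
#'
#' @param params A [CombParams-class].
#' @return Increasing numeric vector of spacings.
#' @export
dstarGrid <- function(params) {
  out <- numeric(200000L)
  d <- params@dstarMin
  j <- 0L
  while (d <= params@dstarMax + 1e-15) {
    j <- j + 1L
    out[j] <- d
    d <- d + params@epsilon / floor(params@qMax / d)
  }
  out[seq_len(j)]
}

#' Comb membership count
#'
#' A projection `x` is a member iff the nearest nonzero comb node `n * dstar`
#' (integer `n != 0`, `|n| * dstar <= qMax`) lies within `epsilon` of `x`.
#' Since `dstar > 2 * epsilon`, the qualifying node is unique and each
#' reflection is counted at most once.
#'
#' @param projections Signed projections (from [projectPool()]).
#' @param dstar Node spacing (1/Angstrom), must exceed `2 * epsilon`.
#' @param params A [CombParams-class].
#' @return List with `count` and integer `members` (indices into
#'   `projections`).
#' @export
combCount <- function(projections, dstar, params) {
  eps <- params@epsilon
  if (dstar <= 2 * eps) stop("need dstar > 2 * epsilon")
  nmax <- floor(params@qMax / dstar * (1 + 1e-12))
  if (nmax < 1L || !length(projections))
    return(list(count = 0L, members = integer(0)))
  p <- abs(projections)
  k <- round(p / dstar)
  k[k < 1] <- 1
  k[k > nmax] <- nmax
  mem <- which(abs(p - k * dstar) <= eps)
  list(count = length(mem), members = as.integer(mem))
}

# integral of (q^2 - x^2)+ over [a, b] with 0 <= a <= b
.quadIntPos <- function(a, b, q) {
  a <- pmin(a, q); b <- pmin(b, q)
  (q^2 * b - b^3 / 3) - (q^2 * a - a^3 / 3)
}

# probability that a uniform point in the shell [qMin, qMax], projected on a
# line, lands in [a, b] (0 <= a <= b): marginal density
# p(x) = 3[(qMax^2 - x^2)+ - (qMin^2 - x^2)+] / [4 (qMax^3 - qMin^3)]
.shellBoxProb <- function(a, b, qMin, qMax) {
  3 * (.quadIntPos(a, b, qMax) - .quadIntPos(a, b, qMin)) /
    (4 * (qMax^3 - qMin^3))
}

#' Expected comb count for randomly placed reflections
#'
#' The count [combCount()] would give, in expectation, if the
#' `nReflections` g-vectors were uniformly distributed in the spherical shell
#' `[qMin, qMax]`: the number of points times the shell-projection
#' probability mass inside the comb boxes. This is the background subtracted
#' from the raw count to score a candidate one-dimensional lattice.
#'
#' @param nReflections Number of (active) reflections projected.
#' @param dstar Node spacing (1/Angstrom).
#' @param params A [CombParams-class].
#' @param qMin Inner shell radius; defaults to `params@qMin`.
#' @return Expected count (real).
#' @export
expectedRandomCount <- function(nReflections, dstar, params,
                                qMin = params@qMin) {
  eps <- params@epsilon
  qMax <- params@qMax
  nmax <- floor(qMax / dstar * (1 + 1e-12))
  if (nmax < 1L) return(0)
  centers <- seq_len(nmax) * dstar
  # factor 2: nodes at +-n*dstar, density symmetric
  nReflections * 2 * sum(.shellBoxProb(pmax(0, centers - eps), centers + eps,
                                       qMin, qMax))
}

# background over a whole spacing grid, vectorized over grid values
.backgroundOnGrid <- function(nReflections, grid, params,
                              qMin = params@qMin) {
  eps <- params@epsilon
  qMax <- params@qMax
  bg <- numeric(length(grid))
  nTop <- floor(qMax / grid[1] * (1 + 1e-12))
  for (n in seq_len(nTop)) {
    c0 <- n * grid
    valid <- c0 <= qMax * (1 + 1e-12)
    bg[valid] <- bg[valid] +
      2 * .shellBoxProb(pmax(0, c0[valid] - eps), c0[valid] + eps, qMin, qMax)
  }
  nReflections * bg
}

#' Scan spacings along one direction
#'
#' Evaluates the background-subtracted comb score on the adaptive grid of
#' [dstarGrid()] and returns the best spacing (ties broken toward larger
#' spacing, since a sub-multiple indexes the same members against a larger
#' background).
#'
#' @param projections Signed projections of the active reflections.
#' @param params A [CombParams-class].
#' @param direction Optional unit 3-vector recorded in the result.
#' @param qMin Shell inner radius for the background; defaults to
#'   `params@qMin`.
#' @return A [LatticeCandidate-class].
#' @export
scanDstar <- function(projections, params, direction = NULL,
                      qMin = params@qMin) {
  grid <- dstarGrid(params)
  bg <- .backgroundOnGrid(length(projections), grid, params, qMin)
  res <- cpp_scan_dirs(cbind(as.numeric(projections), 0, 0),
                       matrix(c(1, 0, 0), 1, 3), grid, bg,
                       params@epsilon, params@qMax)
  cc <- combCount(projections, res[1, 1], params)
  methods::new("LatticeCandidate",
               direction = if (is.null(direction)) numeric(0) else direction,
               dstar = res[1, 1], rawCount = as.numeric(cc$count),
               score = cc$count -
                 expectedRandomCount(length(projections), res[1, 1], params,
                                     qMin),
               members = cc$members)
}

#' Local grid refinement of a lattice candidate
#'
#' Exhaustive search on a local grid around a candidate: the direction is
#' tilted about two orthogonal axes over `+-2 epsilon floor(qMax/dstar)/qMax`
#' radians (9 steps per axis, enough to move the outermost comb node by about
#' one box half-width) and the spacing over +- one adaptive grid step (9
#' steps). Returns the best-scoring point of the grid, or the input candidate
#' unchanged when nothing scores strictly better.
#'
#' @param pool A [GVectorPool-class] or n x 3 matrix of g-vectors to count
#'   against (typically the same set the candidate was scanned on).
#' @param candidate A [LatticeCandidate-class] with a direction.
#' @param params A [CombParams-class].
#' @param qMin Shell inner radius for the background.
#' @return A [LatticeCandidate-class] scoring at least as well as the input.
#' @export
refineLocal <- function(pool, candidate, params, qMin = params@qMin) {
  isPool <- methods::is(pool, "GVectorPool")
  G <- if (isPool) gVectors(pool, activeOnly = TRUE) else as.matrix(pool)
  u <- .checkUnit(candidate@direction)
  d0 <- candidate@dstar
  eps <- params@epsilon
  nfar <- floor(params@qMax / d0)
  tilts <- seq(-2 * eps * nfar / params@qMax, 2 * eps * nfar / params@qMax,
               length.out = 9)
  ds <- d0 + seq(-eps / nfar, eps / nfar, length.out = 9)
  ds <- ds[ds >= params@dstarMin & ds <= params@dstarMax & ds > 2 * eps]
  # orthonormal complement of u
  e <- diag(3)[, which.min(abs(u))]
  v <- .cross3(u, e); v <- v / sqrt(sum(v^2))
  w <- .cross3(u, v)
  grid <- expand.grid(a = tilts, b = tilts, d = ds, KEEP.OUT.ATTRS = FALSE)
  U <- cbind(u[1] + grid$a * v[1] + grid$b * w[1],
             u[2] + grid$a * v[2] + grid$b * w[2],
             u[3] + grid$a * v[3] + grid$b * w[3])
  U <- U / sqrt(rowSums(U^2))
  counts <- cpp_count_pairs(G, U, grid$d, eps, params@qMax)
  scores <- counts - vapply(grid$d, function(d)
    expectedRandomCount(nrow(G), d, params, qMin), 0)
  best <- which.max(scores)
  inCount <- cpp_count_pairs(G, matrix(u, 1, 3), d0, eps, params@qMax)
  inScore <- inCount - expectedRandomCount(nrow(G), d0, params, qMin)
  if (scores[best] <= inScore) return(candidate)
  ub <- U[best, ]
  cc <- combCount(as.numeric(G %*% ub), grid$d[best], params)
  memb <- cc$members
  if (isPool) memb <- which(activeMask(pool))[memb]
  methods::new("LatticeCandidate", direction = ub, dstar = grid$d[best],
               rawCount = as.numeric(cc$count), score = scores[best],
               members = as.integer(memb))
}

#' Least-squares refinement of a lattice candidate
#'
#' The sampled direction of a comb candidate is typically a fraction of a
#' degree off the true lattice direction, close enough to catch reflections
#' near the inner comb nodes but not the outer ones (the projection error
#' grows with the transverse g-component). Rather than searching direction
#' space at the sub-box-width resolution this would require, the comb's own
#' membership supplies node numbers `n_i = round(x_i / dstar)`, and the
#' direction and spacing solving `min_y sum_i (g_i . y - n_i)^2` (with
#' `u = y/|y|`, `dstar = 1/|y|`) snap onto the 1-D lattice; membership is
#' then re-collected and the fit iterated until the background-subtracted
#' score stops improving. Never returns a worse-scoring candidate than the
#' input.
#'
#' @param pool A [GVectorPool-class] or n x 3 matrix of g-vectors.
#' @param candidate A [LatticeCandidate-class] with a direction.
#' @param params A [CombParams-class].
#' @param qMin Shell inner radius for the background.
#' @param maxIter Maximum number of fit / re-collect rounds.
#' @return A [LatticeCandidate-class].
#' @export
refineCombLS <- function(pool, candidate, params, qMin = params@qMin,
                         maxIter = 15L) {
  isPool <- methods::is(pool, "GVectorPool")
  G <- if (isPool) gVectors(pool, activeOnly = TRUE) else as.matrix(pool)
  .checkUnit(candidate@direction)
  u <- candidate@direction
  d <- candidate@dstar
  bgN <- nrow(G)
  best <- list(u = u, d = d,
               cc = combCount(as.numeric(G %*% u), d, params))
  best$score <- best$cc$count - expectedRandomCount(bgN, d, params, qMin)
  cur <- best
  for (it in seq_len(maxIter)) {
    mem <- cur$cc$members
    if (length(mem) < 3L) break
    proj <- as.numeric(G[mem, , drop = FALSE] %*% cur$u)
    n <- round(proj / cur$d)
    n[n == 0] <- sign(proj[n == 0])
    y <- tryCatch(qr.solve(G[mem, , drop = FALSE], n),
                  error = function(e) NULL)
    if (is.null(y)) break
    len <- sqrt(sum(y^2))
    d2 <- 1 / len
    if (!is.finite(d2) || d2 <= 2 * params@epsilon ||
        d2 < params@dstarMin || d2 > params@dstarMax) break
    u2 <- y / len
    cc2 <- combCount(as.numeric(G %*% u2), d2, params)
    score2 <- cc2$count - expectedRandomCount(bgN, d2, params, qMin)
    cur <- list(u = u2, d = d2, cc = cc2, score = score2)
    if (score2 > best$score) best <- cur else break
  }
  if (best$score <= candidate@score &&
      identical(best$u, candidate@direction))
    return(candidate)
  memb <- best$cc$members
  if (isPool) memb <- which(activeMask(pool))[memb]
  methods::new("LatticeCandidate", direction = best$u, dstar = best$d,
               rawCount = as.numeric(best$cc$count), score = best$score,
               members = as.integer(memb))
}
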