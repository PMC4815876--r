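test_that("projection is the signed dot product with the direction", {
  expect_equal(projectPool(matrix(c(0.1, 0.2, 0.3), 1), c(0, 0, 1)), 0.3)
  G <- matrix(rnorm(30), 10, 3)
  u <- c(1, 2, 2) / 3
  expect_equal(projectPool(G, u), -projectPool(G, -u))
  expect_error(projectPool(G, c(1, 1, 0)), "unit")
})

test_that("comb membership matches hand counts and the brute-force oracle", {
  p <- CombParams(epsilon = 5e-4, qMax = 0.35, dstarMin = 0.01)
  expect_identical(combCount(c(0.1, 0.2, 0.3001), 0.1, p)$count, 3L)
  expect_identical(combCount(c(0.15), 0.1, p)$count, 0L)
  expect_identical(combCount(numeric(0), 0.1, p)$count, 0L)
  expect_error(combCount(c(0.1), 5e-4, p))
  set.seed(11)
  for (case in 1:25) {
    proj <- runif(300, -0.6, 0.6)
    d <- runif(1, 0.05, 0.3)
    p2 <- CombParams(epsilon = runif(1, 1e-4, 1e-2), qMax = 0.6,
                     dstarMin = 0.04)
    expect_identical(combCount(proj, d, p2)$members,
                     bruteCombMembers(proj, d, p2@epsilon, 0.6))
  }
})

test_that("comb count is non-decreasing in the box half-width", {
  set.seed(3)
  proj <- runif(500, -0.6, 0.6)
  counts <- vapply(c(1e-4, 5e-4, 2e-3, 5e-3), function(e)
    combCount(proj, 0.17, CombParams(epsilon = e, qMax = 0.6,
                                     dstarMin = 0.1))$count, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("random-placement expectation matches the analytic shell integral", {
  p <- CombParams(epsilon = 5e-4, qMax = 0.6, dstarMin = 0.1)
  # frozen from numerical integration of the shell-projection density
  expect_equal(expectedRandomCount(1000, 0.3, p, qMin = 0), 1.876041,
               tolerance = 1e-4)
  tiny <- CombParams(epsilon = 1e-9, qMax = 0.6, dstarMin = 0.1)
  expect_lt(expectedRandomCount(1000, 0.3, tiny, qMin = 0), 1e-4)
  # the projection density integrates to one over its support
  dens <- function(x, qmin, qmax)
    3 * (pmax(qmax^2 - x^2, 0) - pmax(qmin^2 - x^2, 0)) /
      (4 * (qmax^3 - qmin^3))
  expect_equal(integrate(dens, -0.6, 0.6, qmin = 0.1, qmax = 0.6)$value, 1,
               tolerance = 1e-6)
})

test_that("random-placement expectation matches Monte-Carlo to 3 SE", {
  set.seed(19)
  n <- 1e6
  G <- uniformShell(n, 0.1, 0.6)
  p <- CombParams(epsilon = 5e-4, qMax = 0.6, dstarMin = 0.1)
  for (d in c(0.12, 0.21, 0.29)) {
    cc <- combCount(G[, 3], d, p)$count
    expect_lt(abs(cc - expectedRandomCount(n, d, p)), 3 * sqrt(cc + 1))
  }
})

test_that("the adaptive spacing grid never moves the far node by > epsilon", {
  for (p in list(CombParams(),
                 CombParams(epsilon = 5e-4, qMax = 0.5, dstarMin = 0.05))) {
    g <- dstarGrid(p)
    expect_equal(g[1], p@dstarMin)
    expect_lte(max(g), p@dstarMax + 1e-15)
    far <- floor(p@qMax / g[-length(g)])
    expect_true(all(far * diff(g) <= p@epsilon + 1e-12))
  }
})

test_that("spacing scan prefers the fundamental over sub-multiples", {
  p <- CombParams(epsilon = 5e-4, qMax = 0.65, dstarMin = 0.1)
  cand <- scanDstar(c(-0.6, -0.4, -0.2, 0.2, 0.4, 0.6), p, qMin = 0.1)
  # d* = 0.1 indexes the same six projections with a larger background
  expect_lt(abs(cand@dstar - 0.2), 1e-3)
  expect_identical(as.integer(cand@rawCount), 6L)
  expect_identical(cand@members, 1:6)
})

test_that("scan recovers the plane spacing of a simulated grain", {
  sc <- singleGrainScene("cementite", sigma = 1e-4, seed = 13)
  p <- CombParams()
  for (i in 1:3) {
    a <- sc$basis[i, ]
    cand <- scanDstar(projectPool(sc$pool, a / sqrt(sum(a^2))), p)
    expect_lt(abs(cand@dstar - 1 / sqrt(sum(a^2))), 2 * p@epsilon)
  }
})

test_that("local grid refinement never worsens and fixes a small tilt", {
  sc <- singleGrainScene("cementite", sigma = 0, seed = 17)
  G <- gVectors(sc$pool)
  p <- CombParams()
  cvec <- sc$basis[3, ]                    # 6.73 A axis
  u <- cvec / sqrt(sum(cvec^2))
  d <- 1 / sqrt(sum(cvec^2))
  # perturb the direction by 0.2 degrees
  set.seed(2)
  for (rep in 1:5) {
    w <- rnorm(3); w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
    th <- 0.2 * pi / 180
    u2 <- cos(th) * u + sin(th) * w
    cc <- combCount(as.numeric(G %*% u2), d, p)
    cand <- methods::new("LatticeCandidate", direction = u2, dstar = d,
                         rawCount = as.numeric(cc$count),
                         score = cc$count -
                           expectedRandomCount(nrow(G), d, p),
                         members = cc$members)
    ref <- refineLocal(G, cand, p)
    expect_gte(ref@score, cand@score)
    ang <- acos(min(1, abs(sum(ref@direction * u)))) * 180 / pi
    expect_lt(ang, 0.05)
    # a second application cannot improve further
    again <- refineLocal(G, ref, p)
    expect_identical(again@dstar, ref@dstar)
  }
})

test_that("refinement never worsens arbitrary candidates", {
  sc <- singleGrainScene("quartz", sigma = 1e-4, seed = 23,
                         qMin = 0.05, qMax = 0.5)
  G <- gVectors(sc$pool)
  p <- CombParams(epsilon = 5e-4, qMax = 0.5, dstarMin = 0.05)
  set.seed(31)
  U <- sampleDirections(40)
  for (m in seq_len(nrow(U))) {
    d <- runif(1, p@dstarMin, p@dstarMax)
    cc <- combCount(as.numeric(G %*% U[m, ]), d, p)
    cand <- methods::new("LatticeCandidate", direction = U[m, ], dstar = d,
                         rawCount = as.numeric(cc$count),
                         score = cc$count -
                           expectedRandomCount(nrow(G), d, p),
                         members = cc$members)
    expect_gte(refineLocal(G, cand, p)@score, cand@score)
    expect_gte(refineCombLS(G, cand, p)@score, cand@score)
  }
})

test_that("least-squares snap locks onto a lattice direction from far outside the comb tolerance", {
  # the comb itself only tolerates direction errors ~ epsilon / qMax
  # (0.048 deg); the snap recovers from several times that
  sc <- singleGrainScene("cementite", sigma = 1e-4, seed = 29)
  G <- gVectors(sc$pool)
  lab <- truthLabels(sc$pool)
  p <- CombParams()
  set.seed(4)
  w0 <- rnorm(3)
  for (axis in 1:2) {
    avec <- sc$basis[axis, ]
    u <- avec / sqrt(sum(avec^2))
    d <- 1 / sqrt(sum(avec^2))
    w <- w0 - sum(w0 * u) * u; w <- w / sqrt(sum(w^2))
    th <- 0.3 * pi / 180
    u2 <- cos(th) * u + sin(th) * w
    cc <- combCount(as.numeric(G %*% u2), d, p)
    cand <- methods::new("LatticeCandidate", direction = u2, dstar = d,
                         rawCount = as.numeric(cc$count), score = -Inf,
                         members = cc$members)
    ref <- refineCombLS(G, cand, p)
    ang <- acos(min(1, abs(sum(ref@direction * u)))) * 180 / pi
    expect_lt(ang, 0.05)
    # recovers (at least) the exactly-aligned comb's membership
    ccTrue <- combCount(as.numeric(G %*% u), d, p)
    expect_gte(ref@rawCount, ccTrue$count - 2)
  }
})
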