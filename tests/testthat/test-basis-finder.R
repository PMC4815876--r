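test_that("triple normals find the plane normal and discard degenerates", {
  G <- rbind(c(0.1, 0, 0.2), c(0, 0.1, 0.2), c(0.05, 0.02, 0.2))
  n <- tripleNormals(G, nClosest = 3)
  expect_identical(nrow(n), 1L)
  expect_equal(abs(n[1, ]), c(0, 0, 1), tolerance = 1e-12)
  collinear <- rbind(c(0.1, 0, 0), c(0.2, 0, 0), c(0.3, 0, 0))
  expect_identical(nrow(tripleNormals(collinear, nClosest = 3)), 0L)
  expect_error(tripleNormals(G[1:2, ]), "3 reflections")
})

test_that("spacing-from-projections follows the largest-within-80% rule", {
  p <- CombParams(epsilon = 5e-4, qMax = 0.45, dstarMin = 0.05,
                  dstarMax = 0.45)
  G1 <- cbind(0, 0, c(-0.4, -0.3, -0.2, -0.1, 0.1, 0.2, 0.3, 0.4))
  r1 <- latticeOnDirection(G1, c(0, 0, 1), p)
  expect_equal(r1$dstar, 0.1, tolerance = 1e-9)
  expect_identical(r1$count, 8L)
  G2 <- cbind(0, 0, c(-0.4, -0.2, 0.2, 0.4))
  r2 <- latticeOnDirection(G2, c(0, 0, 1), p)
  expect_equal(r2$dstar, 0.2, tolerance = 1e-9)
  expect_identical(r2$count, 4L)
  # nothing projects into the spacing window
  G3 <- cbind(0, 0, c(-0.02, 0.02))
  expect_null(latticeOnDirection(G3, c(0, 0, 1), p))
})

test_that("direct vectors of a noise-free cubic grain include the axes", {
  sc <- singleGrainScene("cubic5", sigma = 0, seed = 57,
                         cell = UnitCell(5, 5, 5))
  G <- gVectors(sc$pool)
  p <- CombParams()
  dirs <- tripleNormals(G)
  dv <- collectDirectVectors(G, dirs, p)
  expect_equal(sqrt(rowSums(dv$vectors^2)), 1 / dv$dstar, tolerance = 1e-9)
  for (i in 1:3) {
    axis <- sc$basis[i, ]
    dev <- apply(dv$vectors, 1, function(v) min(sqrt(sum((v - axis)^2)),
                                                sqrt(sum((v + axis)^2))))
    expect_lt(min(dev), 1e-4)
  }
})

test_that("basis choice spans the minimal cell from shortest candidates", {
  vecs <- rbind(c(5, 0, 0), c(10, 0, 0), c(0, 4, 0), c(0, 0, 6))
  bas <- chooseBasis(vecs)
  expect_equal(abs(bas), rbind(c(0, 4, 0), c(5, 0, 0), c(0, 0, 6)),
               tolerance = 1e-12)
  expect_gt(det(bas), 0)
  expect_equal(abs(det(bas)), 120)
  expect_null(chooseBasis(rbind(c(1, 0, 0), c(0, 1, 0))))
  expect_null(chooseBasis(rbind(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))))
  ortho <- diag(3)[c(2, 1, 3), ]
  expect_equal(abs(det(chooseBasis(ortho))), 1)
})

test_that("indexing against the pool is exact, tolerant and one-to-one", {
  sc0 <- singleGrainScene("cementite", sigma = 0, seed = 61)
  p <- CombParams()
  hyp <- indexAgainstPool(sc0$basis, sc0$pool, p)
  expect_identical(matchedCount(hyp), nrow(gVectors(sc0$pool)))
  expect_lt(max(assignments(hyp)$distance), 1e-9)
  expect_false(anyDuplicated(assignments(hyp)$index) > 0)
  # noisy grain: 5 epsilon = 25 sigma per component, virtually all matched
  scn <- singleGrainScene("cementite", sigma = 1e-4, seed = 62)
  hypn <- indexAgainstPool(scn$basis, scn$pool, p)
  expect_gte(matchedCount(hypn), 0.99 * nrow(gVectors(scn$pool)))
  expect_error(indexAgainstPool(matrix(0, 3, 3), sc0$pool, p), "singular")
})

test_that("an incommensurate lattice matches almost nothing", {
  sc <- singleGrainScene("cubic10", sigma = 1e-4, seed = 63,
                         cell = UnitCell(10, 10, 10),
                         qMin = 0.05, qMax = 0.5)
  p <- CombParams(epsilon = 5e-4, qMax = 0.5, dstarMin = 0.05)
  alien <- directBasisFromCell(UnitCell(pi * 10, pi * 10, pi * 10))
  hyp <- indexAgainstPool(alien, sc$pool, p)
  expect_lt(matchedCount(hyp), 20)
})

test_that("pool indexing is invariant under unimodular changes of basis", {
  sc <- singleGrainScene("biotite", sigma = 1e-4, seed = 64)
  p <- CombParams()
  M <- rbind(c(1, 1, 0), c(0, 1, 0), c(1, 1, 1))   # det = 1
  h1 <- indexAgainstPool(sc$basis, sc$pool, p)
  h2 <- indexAgainstPool(M %*% sc$basis, sc$pool, p)
  expect_identical(sort(assignments(h1)$index), sort(assignments(h2)$index))
})

test_that("best hypothesis recovers a full grain from a multigrain scene", {
  pool <- simulatePool(SimulationConfig(builtinPhases("cementite"), 5,
                                        qMin = 0.1, qMax = 0.6,
                                        sigma = 0, seed = 66))
  p <- CombParams()
  set.seed(67)
  cands <- findCandidates(pool, p, SearchConfig(nU1 = 1200, nU2 = 600))
  hyp <- bestHypothesis(cands, pool, p, 20L)
  lab <- truthLabels(pool)
  tg <- as.integer(names(which.max(table(lab$grain[assignments(hyp)$index]))))
  own <- assignments(hyp)$index[lab$grain[assignments(hyp)$index] == tg]
  expect_identical(length(own), sum(lab$grain == tg))
  expect_null(bestHypothesis(list(), pool, p, 20L))
  expect_null(bestHypothesis(cands, pool, p,
                             10L * nrow(gVectors(pool))))
})
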