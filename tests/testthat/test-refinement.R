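test_that("least-squares basis refinement is exact on clean assignments", {
  set.seed(71)
  A <- matrix(rnorm(9), 3, 3) + diag(3) * 3
  B <- reciprocalBasis(A)
  H <- as.matrix(expand.grid(-2:2, -2:2, -2:2))[-63, ]   # drop (0,0,0)
  G <- H %*% B
  expect_lt(max(abs(refineBasis(H, G) - A)), 1e-10)
})

test_that("refined basis residuals match the injected noise level", {
  set.seed(72)
  A <- directBasisFromCell(UnitCell(4.51, 5.05, 6.73))
  B <- reciprocalBasis(A)
  H <- matrix(sample(-4:4, 300, replace = TRUE), 100, 3)
  H <- H[rowSums(H != 0) > 0, ]
  G <- H %*% B + matrix(rnorm(3 * nrow(H), 0, 1e-4), ncol = 3)
  A2 <- refineBasis(H, G)
  resid <- H %*% reciprocalBasis(A2) - G
  expect_equal(sqrt(mean(resid^2)), 1e-4, tolerance = 0.15)
})

test_that("coplanar Miller indices are rejected", {
  H <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(2, 1, 0))
  G <- H %*% diag(c(0.2, 0.2, 0.2))
  expect_error(refineBasis(H, G), "rank")
})

test_that("supercell check corrects a planted half cell", {
  sc <- singleGrainScene("cubic4", sigma = 0, seed = 73,
                         cell = UnitCell(4, 4, 4))
  p <- CombParams()
  half <- diag(c(0.5, 1, 1)) %*% sc$basis    # a/2, b, c: volume 32
  hyp <- indexAgainstPool(half, sc$pool, p)
  fixed <- trySupercells(hyp, sc$pool, p)
  expect_gte(matchedCount(fixed), 1.2 * matchedCount(hyp))
  expect_equal(abs(det(basisMatrix(fixed))), 64, tolerance = 1e-6)
  expect_identical(matchedCount(fixed), nrow(gVectors(sc$pool)))
  # an already-correct hypothesis is returned unchanged
  good <- indexAgainstPool(sc$basis, sc$pool, p)
  same <- trySupercells(good, sc$pool, p)
  expect_identical(basisMatrix(same), basisMatrix(good))
  expect_gte(matchedCount(same), matchedCount(good))
})

test_that("one grain is indexed exactly from a noise-free scene", {
  sc <- singleGrainScene("cementite", sigma = 0, seed = 74)
  cfg <- IndexingConfig(search = SearchConfig(nU1 = 800, nU2 = 400),
                        seed = 74)
  set.seed(74)
  res <- indexOneGrain(sc$pool, cfg)
  expect_s4_class(res$grain, "IndexedGrain")
  expect_identical(matchedCount(res$grain), nrow(gVectors(sc$pool)))
  expect_equal(cellVolume(res$grain@cell), cellVolume(sc$phase@cell),
               tolerance = 1e-6)
  expect_identical(nActive(res$pool), 0L)
})

test_that("no grain is invented from structureless reflections", {
  set.seed(75)
  pool <- GVectorPool(uniformShell(200, 0.1, 0.6))
  cfg <- IndexingConfig(search = SearchConfig(nU1 = 500, nU2 = 250),
                        seed = 75)
  set.seed(75)
  res <- indexOneGrain(pool, cfg)
  expect_null(res$grain)
  expect_identical(nActive(res$pool), 200L)
  # below the minimum pool size nothing is attempted
  tiny <- GVectorPool(uniformShell(10, 0.1, 0.6))
  expect_null(indexOneGrain(tiny, cfg)$grain)
})

test_that("the peeling loop recovers disjoint grains deterministically", {
  pool <- simulatePool(SimulationConfig(builtinPhases("cementite"), 3,
                                        qMin = 0.1, qMax = 0.6,
                                        sigma = 1e-4, seed = 76))
  cfg <- IndexingConfig(search = SearchConfig(nU1 = 1200, nU2 = 600),
                        seed = 77)
  res1 <- runIndexing(pool, cfg)
  res2 <- runIndexing(pool, cfg)
  expect_identical(length(grains(res1)), 3L)
  idx <- unlist(lapply(grains(res1), function(g) assignments(g)$index))
  expect_false(anyDuplicated(idx) > 0)
  expect_identical(lapply(grains(res1), assignments),
                   lapply(grains(res2), assignments))
  expect_identical(lapply(grains(res1), basisMatrix),
                   lapply(grains(res2), basisMatrix))
  expect_identical(vapply(grains(res1), function(g) g@serial, 0L), 1:3)
})

test_that("a four-phase scene is indexed with no phase information", {
  pool <- simulatePool(SimulationConfig(granitePhases(), c(1, 1, 1, 1),
                                        qMin = 0.05, qMax = 0.5,
                                        sigma = 1e-4, seed = 78))
  cfg <- IndexingConfig(
    comb = CombParams(epsilon = 5e-4, qMax = 0.5, dstarMin = 0.05),
    search = SearchConfig(nU1 = 1500, nU2 = 700), seed = 79)
  res <- runIndexing(pool, cfg)
  expect_identical(length(grains(res)), 4L)
  rep <- figuresOfMerit(res, pool, granitePhases())
  expect_identical(rep@fractionIdentified, 1)
  expect_setequal(rep@perGrain$phase,
                  c("quartz", "biotite", "orthoclase", "plagioclase"))
})

test_that("an empty pool yields an empty result", {
  res <- runIndexing(GVectorPool(matrix(numeric(0), 0, 3)),
                     IndexingConfig(seed = 1))
  expect_identical(grains(res), list())
  expect_match(res@stopReason, "remaining")
})
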