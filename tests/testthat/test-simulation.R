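test_that("base matrix generator is positive, deterministic and block-correlated", {
  atlas <- blockAtlas(40, 4)
  Z1 <- generateBaseMatrix(100, 40, atlas, seed = 1)
  Z2 <- generateBaseMatrix(100, 40, atlas, seed = 1)
  Z3 <- generateBaseMatrix(100, 40, atlas, seed = 2)
  expect_true(all(Z1 > 0))
  expect_identical(Z1, Z2)
  expect_false(identical(Z1, Z3))

  # correlation structure at large n
  Zb <- generateBaseMatrix(2000, 40, atlas, seed = 3)
  cm <- cor(Zb)
  within <- unlist(lapply(roiMasks(atlas), function(m) {
    cc <- cm[m, m]; cc[upper.tri(cc)]
  }))
  expect_gt(mean(within), 0.4)
  expect_lt(mean(within), 0.6)
  m1 <- roiMasks(atlas)[[1]]; m2 <- roiMasks(atlas)[[2]]
  expect_lt(abs(mean(cm[m1, m2]) - 0.1), 0.05)
  expect_equal(mean(colMeans(Zb)), 2.5, tolerance = 0.1)
  expect_equal(mean(apply(Zb, 2, sd)), 0.3, tolerance = 0.05)
})

test_that("perturbation is a masked rank-one update", {
  Z0 <- matrix(1:12, 3, 4) * 1.0
  # no effect sizes or no driver: untouched
  expect_equal(perturbMatrix(Z0, c(1, 2, 3), 1:4, rep(0, 4)), Z0)
  expect_equal(perturbMatrix(Z0, rep(0, 3), 1:4, runif(4)), Z0)

  # single signal feature: outer-product column update
  g <- c(0, 0, 2, 0)
  Z <- perturbMatrix(Z0, c(1, -1, 0), 3L, g)
  expect_equal(Z[, 3], Z0[, 3] + c(2, -2, 0))
  expect_equal(Z[, -3], Z0[, -3])

  # gamma outside the mask union is zeroed by V
  Z2 <- perturbMatrix(Z0, c(1, 1, 1), 1:2, c(1, 1, 5, 5))
  expect_equal(Z2[, 3:4], Z0[, 3:4])
})

test_that("binarization thresholds the latent response at zero", {
  expect_equal(binarizeResponse(c(-1, 0, 1)), c(0L, 0L, 1L))
  expect_equal(binarizeResponse(c(-2, -0.5)), c(0L, 0L))
  grid <- seq(-5, 5, length.out = 100)
  expect_equal(binarizeResponse(grid),
               as.integer(exp(grid) / (1 + exp(grid)) > 0.5))
})

test_that("mass-univariate baseline is calibrated and detects planted means", {
  atlas <- blockAtlas(20, 4)
  set.seed(21)
  X <- cbind(1, rnorm(200))

  # planted signal: the response is an ROI's mean
  Z <- matrix(rnorm(200 * 20), 200)
  y <- rowMeans(Z[, roiMasks(atlas)[[2]]])
  p <- massUnivariateBaseline(y, X, Z, atlas)
  expect_lt(p[[2]], 1e-6)

  # null uniformity across replicates (gaussian)
  pnull <- replicate(150, {
    Zr <- matrix(rnorm(60 * 20), 60)
    massUnivariateBaseline(rnorm(60), cbind(1, rnorm(60)), Zr, atlas)[[1]]
  })
  expect_gt(suppressWarnings(stats::ks.test(pnull, "punif"))$p.value, 0.01)

  # degenerate ROI mean collinear with the intercept
  Zdeg <- matrix(rnorm(40 * 20), 40)
  Zdeg[, roiMasks(atlas)[[3]]] <- 1
  expect_warning(
    pd <- massUnivariateBaseline(rnorm(40), cbind(1, rnorm(40)), Zdeg, atlas),
    "collinear")
  expect_equal(pd[[3]], 1)

  # bernoulli route returns valid p-values
  yb <- rbinom(200, 1, 0.5)
  pb <- massUnivariateBaseline(yb, X, Z, atlas, family = "bernoulli")
  expect_true(all(pb > 0 & pb <= 1))
})

test_that("runExperiment produces a reproducible tidy power table", {
  sc <- simScenario(n = 60, p = 40, atlas = blockAtlas(40, 4),
                    signalROIs = 1L, tau2Grid = c(0, 0.01),
                    nReps = 6L, nPerm = 49L, seed = 5L)
  out1 <- runExperiment(sc)
  out2 <- runExperiment(sc)
  expect_identical(out1$summary, out2$summary)

  s <- out1$summary
  expect_setequal(unique(s$metric),
                  c("global_power", "any_local_rejection", "fdr",
                    "local_power"))
  expect_true(all(s$value >= 0 & s$value <= 1))
  expect_setequal(unique(s$method), c("laxkat", "skat", "baseline"))
  # at tau2 = 0 the perturbation degenerates: Z = Z0, rates near nominal
  expect_true(all(s$value[s$tau2 == 0 & s$metric == "global_power"] <= 0.7))
  expect_equal(nrow(out1$replicates), 12)
})
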