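test_that("skatStatistic equals the dense kernel quadratic form", {
  expect_equal(skatStatistic(rep(0, 3), matrix(rnorm(6), 3), c(1, 1)), 0)

  # identity kernel: sum of squared residuals
  r <- c(1.5, -2, 0.5, 3)
  expect_equal(skatStatistic(r, diag(4)), sum(r^2))

  # fixed 3 x 2 instance, hand value 13
  expect_equal(
    skatStatistic(c(1, -1, 2), cbind(c(1, 0, 1), c(0, 1, 1)), c(1, 2)), 13)

  set.seed(7)
  for (i in 1:10) {
    n <- sample(5:50, 1); p <- sample(2:12, 1)
    r <- rnorm(n); Z <- matrix(rnorm(n * p), n); w <- runif(p, 0, 2)
    expect_equal(skatStatistic(r, Z, w), denseQuadForm(r, Z, w),
                 tolerance = 1e-10)
  }
})

test_that("roiStatistic matches the dense trace-scaled quadratic form", {
  Z <- matrix(rnorm(9), 3)
  expect_equal(roiStatistic(rep(0, 3), Z, rep(1, 3), 1:2), 0)

  # single feature, gaussian: (z'r)^2 / ||z||^2
  r <- c(1, 2, -1)
  expect_equal(roiStatistic(r, Z, rep(1, 3), 2),
               drop(crossprod(Z[, 2], r))^2 / sum(Z[, 2]^2))

  set.seed(8)
  r <- c(0.3, -1.2, 0.8)
  Z <- matrix(rnorm(9), 3)
  w <- c(1, 1, 0)   # mask {1,2} as a weight vector
  expect_equal(roiStatistic(r, Z, rep(1, 3), 1:2),
               denseQuadForm(r, Z, w) / denseTrace(Z, rep(1, 3), w),
               tolerance = 1e-12)

  expect_error(roiStatistic(r, matrix(0, 3, 2), rep(1, 3), 1:2, label = "roiX"),
               "roiX")
})

test_that("exclusive-basis maximum agrees with the subspace random-search oracle", {
  set.seed(9)
  for (i in 1:8) {
    inst <- randomInstance(20, 12, 3)
    delta <- rep(1, 20)
    s <- laxkatStatistic(inst$y, inst$Z, delta, inst$atlas)
    expect_equal(unname(s@value), max(s@perROI))
    oracle <- randomSearchLaxKAT(inst$y, inst$Z, delta,
                                 asGeneralBasis(inst$atlas)@basis,
                                 nPoints = 1e5)
    expect_equal(unname(s@value), oracle, tolerance = 1e-6)
  }

  # single ROI: reduces to roiStatistic; zero residuals: zero statistic
  inst <- randomInstance(10, 6, 1)
  s1 <- laxkatStatistic(inst$y, inst$Z, rep(1, 10), inst$atlas)
  expect_equal(unname(s1@value),
               roiStatistic(inst$y, inst$Z, rep(1, 10), 1:6))
  s0 <- laxkatStatistic(rep(0, 10), inst$Z, rep(1, 10), inst$atlas)
  expect_equal(unname(s0@value), 0)
  expect_true(all(s0@perROI == 0))
})

test_that("general-basis eigen route agrees with the exclusive maximum and the oracle", {
  set.seed(10)
  for (i in 1:8) {
    inst <- randomInstance(15, 10, 3)
    delta <- runif(15, 0.1, 0.25)
    se <- laxkatStatistic(inst$y, inst$Z, delta, inst$atlas)
    sg <- laxkatStatistic(inst$y, inst$Z, delta, asGeneralBasis(inst$atlas))
    expect_equal(unname(se@value), unname(sg@value), tolerance = 1e-10)
  }

  # overlapping 2-column basis on a fixed 10 x 6 instance
  set.seed(11)
  Z <- matrix(rnorm(60), 10)
  r <- rnorm(10)
  delta <- rep(1, 10)
  B <- cbind(c(1, 1, 1, 0.5, 0, 0), c(0, 0, 0.7, 1, 1, 1))
  sg <- laxkatStatistic(r, Z, delta, generalBasis(B))
  oracle <- randomSearchLaxKAT(r, Z, delta, B, nPoints = 1e5)
  expect_equal(unname(sg@value), oracle, tolerance = 1e-5)

  # q = 1 general basis: weighted single-kernel statistic
  b1 <- generalBasis(matrix(c(0.5, 2, 0, 1, 0, 0), 6))
  s1 <- laxkatStatistic(r, Z, delta, b1)
  w <- b1@basis[, 1]
  expect_equal(unname(s1@value),
               denseQuadForm(r, Z, w) / denseTrace(Z, delta, w),
               tolerance = 1e-10)

  expect_error(
    laxkatStatistic(r, matrix(0, 10, 6), delta, generalBasis(B)),
    "singular")
})

test_that("statistic invariances: scaling, dominance, subject permutation", {
  set.seed(12)
  inst <- randomInstance(25, 16, 4)
  delta <- rep(1, 25)
  a <- inst$atlas
  s <- laxkatStatistic(inst$y, inst$Z, delta, a)

  # per-ROI stats dominate none; maximum dominates all
  expect_true(all(s@value >= s@perROI))

  # full-coverage atlas: Q_LaxKAT >= identity-weight scaled statistic
  u <- drop(crossprod(inst$Z, inst$y))
  d <- drop(crossprod(inst$Z^2, delta))
  expect_gte(s@value, sum(u^2) / sum(d))

  # scale invariance of the general route under column rescaling
  B <- asGeneralBasis(a)@basis
  for (cc in c(-3, 0.01, 17)) {
    B2 <- B
    B2[, 2] <- cc * B2[, 2]
    sg <- laxkatStatistic(inst$y, inst$Z, delta, generalBasis(B2))
    expect_equal(unname(sg@value), unname(s@value), tolerance = 1e-10)
  }

  # simultaneous subject permutation leaves everything unchanged
  pi <- sample(25)
  s2 <- laxkatStatistic(inst$y[pi], inst$Z[pi, ], delta[pi], a)
  expect_equal(s2@perROI, s@perROI, tolerance = 1e-12)
})
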