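test_that("profile normalization follows the floor-and-rescale rule", {
  ## degenerate range maps to the zero profile
  expect_equal(normalizeProfile(matrix(1, 1, 3))@field, matrix(0, 1, 3))
  ## plain affine normalization without a floor
  expect_equal(normalizeProfile(matrix(c(0, 5, 10), 1), t0 = 0)@field,
               matrix(c(0, 0.5, 1), 1))
  ## floor at 0.3 of the normalized range: 0.2 falls below and is zeroed,
  ## the maximum stays exactly 1
  expect_equal(normalizeProfile(matrix(c(0, 2, 10), 1), t0 = 0.3)@field,
               matrix(c(0, 0, 1), 1))
  expect_error(normalizeProfile(matrix(c(0, NA), 1)), "finite")
  expect_error(normalizeProfile(matrix(0:1, 1), t0 = 1), "t0")
})

test_that("GRF sampling is deterministic and respects the zero-variance case", {
  g <- gridSpec()
  k <- grfKernel()
  p1 <- sampleInsultProfile(g, k, seed = 7L)
  p2 <- sampleInsultProfile(g, k, seed = 7L)
  expect_identical(p1@field, p2@field)
  p3 <- sampleInsultProfile(g, k, seed = 8L)
  expect_false(identical(p1@field, p3@field))
  ## zero variance -> constant raw field -> zero profile
  p0 <- sampleInsultProfile(g, grfKernel(variance = 0), seed = 7L)
  expect_equal(max(p0@field), 0)
  expect_error(grfKernel(length_theta = 0), "positive")
})

test_that("sampled profiles satisfy the normalized-severity invariants", {
  p <- profileFixture()
  expect_gte(min(p@field), 0)
  expect_equal(max(p@field), 1)
  ## lesion vanishes at the vessel ends (dilatation normalization reference)
  expect_equal(p@field[, 1], rep(0, nrow(p@field)))
  expect_equal(p@field[, ncol(p@field)], rep(0, nrow(p@field)))
  ## smoothness: neighbor increments stay far below the full range, as
  ## expected for a field correlated over ~7 nodes circumferentially
  dth <- abs(p@field - p@field[c(2:41, 1), ])
  dz <- abs(p@field[, -1] - p@field[, -41])
  expect_lt(max(dth, dz), 0.5)
})

test_that("empirical GRF variance matches the kernel variance", {
  ## Monte-Carlo check of the covariance factor on a small grid: the
  ## pre-normalization field at any node has the kernel's marginal variance
  g <- gridSpec(9L, 9L)
  k <- grfKernel(variance = 2.5)
  fac <- TAAinvert:::grfFactor(g, k)
  set.seed(123)
  Z <- matrix(rnorm(81 * 10000), 81, 10000)
  X <- fac %*% Z
  v_emp <- mean(apply(X[c(5, 41, 77), ], 1, var))
  expect_lt(abs(v_emp - 2.5) / 2.5, 0.05)
})

test_that("insult pairs scale the profile into capped contributor fields", {
  apex <- normalizeProfile(matrix(c(0, 0.5, 1), 1), t0 = 0)
  ## pure elastic-fiber insult saturates the 0.48 cap at the apex
  pr <- makeInsultPair(apex, w = 1, s = 1)
  expect_equal(max(pr@theta_ce), 0.48)
  expect_equal(max(pr@theta_delta), 0)
  ## pure mechanosensing insult saturates the 0.28 cap
  pr0 <- makeInsultPair(apex, w = 0, s = 1)
  expect_equal(max(pr0@theta_delta), 0.28)
  expect_equal(max(pr0@theta_ce), 0)
  ## pointwise arithmetic at a half-severity node
  prh <- makeInsultPair(apex, w = 0.5, s = 1)
  expect_equal(prh@theta_ce[1, 2], 0.5 * 0.5 * 0.48)
  expect_equal(prh@theta_delta[1, 2], 0.5 * 0.5 * 0.28)
  ## cap violation rejected
  expect_error(makeInsultPair(apex, w = 1, s = 1.5), "cap")
  expect_equal(maxScale(0.25), 1 / 0.75)
})

test_that("scale calibration hits the aneurysmal dilatation target deterministically", {
  wp <- wallFixture()
  p <- profileFixture()
  s <- calibrateScale(p, w = 0.3, wp)
  expect_lte(abs(attr(s, "dmax") - 1.5), 0.01)
  s2 <- calibrateScale(p, w = 0.3, wp)
  expect_identical(as.numeric(s), as.numeric(s2))
  ## a zero profile cannot dilate
  zero <- normalizeProfile(matrix(0, 41, 41), t0 = 0)
  expect_error(calibrateScale(zero, 0.3, wp), "calibration error")
})

test_that("derived seeds are reproducible and within the 32-bit range", {
  s1 <- deriveSeeds(42L, 10)
  s2 <- deriveSeeds(42L, 10)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 1 & s1 <= 2147483646))
  expect_equal(length(unique(s1)), 10L)
})
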