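test_that("mechanosensing law reproduces the defect-scaled stress deviation", {
  expect_equal(sensedStressDeviation(1, 1, 0), 0)
  expect_equal(sensedStressDeviation(1.2, 1, 0), 0.2)
  expect_equal(sensedStressDeviation(1, 1, 0.28), -0.28)
  expect_error(sensedStressDeviation(1, 1, 1), "parameter error")
  expect_equal(equilibriumTargetStress(1, 0), 1)
  expect_equal(equilibriumTargetStress(1, 0.5), 2)
  expect_equal(equilibriumTargetStress(1, 0.28), 1 / 0.72)
})

test_that("constitutive laws match their analytic values and derivatives", {
  wp <- wallFixture()
  ## elastin: zero stress at the unloaded natural configuration
  expect_equal(elastinStress(1 / wp@G_e, wp), 0)
  ## strictly increasing
  lams <- seq(0.6, 2.5, by = 0.1)
  expect_true(all(diff(elastinStress(lams, wp)) > 0))
  ## finite-difference slope at lambda = 1 vs the analytic derivative
  h <- 1e-6
  fd <- (elastinStress(1 + h, wp) - elastinStress(1 - h, wp)) / (2 * h)
  ana <- wp@c_e * (2 * wp@G_e^2 + 2 * wp@G_e^-2)
  expect_lt(abs(fd - ana) / ana, 1e-6)
  ## collagen pool: deposition stress recovered at lam_rel = 1
  expect_equal(collagenElasticStress(1, wp), wp@s_h)
  expect_lt(collagenElasticStress(0.97, wp), wp@s_h)
  ## derivative at deposition: s_h * (2 + 2 k)
  fd <- (collagenElasticStress(1 + h, wp) -
           collagenElasticStress(1 - h, wp)) / (2 * h)
  expect_lt(abs(fd - wp@s_h * (2 + 2 * wp@k_c)) / fd, 1e-6)
})

test_that("equilibrated node solve recovers homeostasis and satisfies the residual", {
  wp <- wallFixture()
  st <- solveEquilibratedNode(0, 0, wp)
  expect_lt(abs(st$lam - 1), 1e-6)
  ## elastin damage dilates
  st_ce <- solveEquilibratedNode(0.4, 0, wp)
  expect_gt(st_ce$lam, 1)
  ## residual re-substitution at the returned root
  resid <- function(st, wp) {
    st$phi_e * st$eta * elastinStress(st$lam, wp) +
      (1 - st$phi_e) * wp@s_h - st$sigma_star
  }
  expect_lt(abs(resid(st_ce, wp)), 1e-8 * wp@sigma0)
  expect_error(solveEquilibratedNode(1, 0, wp), "parameter error")
})

test_that("production solver agrees with a brute-force residual scan", {
  ## independent oracle: dense grid scan of |R(lambda)| for random defects
  wp <- wallFixture()
  set.seed(42)
  tce <- runif(100, 0, 0.48)
  td <- runif(100, 0, 0.28)
  st <- solveEquilibratedNode(tce, td, wp)
  lgrid <- seq(0.5, 4, by = 5e-4)
  for (i in seq_len(100)) {
    sigma_star <- wp@sigma0 / (1 - td[i])
    M <- wp@P_gr * lgrid * wp@r0 / sigma_star
    phie <- wp@m_e / M
    R <- phie * (1 - tce[i]) * elastinStress(lgrid, wp) +
      (1 - phie) * wp@s_h - sigma_star
    lam_bf <- lgrid[which.min(abs(R))]
    expect_lt(abs(st$lam[i] - lam_bf), 5e-4 + 1e-9)
  }
})

test_that("elastic pressurization is self-consistent and monotone in pressure", {
  wp <- wallFixture()
  st <- solveEquilibratedNode(0.3, 0.1, wp)
  r_gr <- pressurizeVessel(st, wp@P_gr, wp)
  expect_lt(abs(attr(r_gr, "lam_el") - 1), 1e-6)
  r_d <- pressurizeVessel(st, wp@P_dia, wp)
  r_s <- pressurizeVessel(st, wp@P_sys, wp)
  expect_lt(as.numeric(r_d), as.numeric(r_s))
  ## residual of the elastic balance at the returned stretch
  lp <- attr(r_d, "lam_el")
  k_loc <- wp@k_c * st$zeta^wp@q_turn
  g <- st$phi_e * st$eta * elastinStress(st$lam * lp, wp) +
    (1 - st$phi_e) * collagenElasticStress(lp, wp, k = k_loc) -
    wp@P_dia * st$lam * lp^2 * wp@r0 / st$M
  expect_lt(abs(g), 1e-8 * wp@sigma0)
})

test_that("homeostatic calibration hits the baseline distensibility and Laplace stress", {
  wp <- homeostaticCalibration()
  expect_lt(abs(TAAinvert:::baselineDistensibility(wp) - 0.05442), 1e-5)
  ## idempotent
  wp2 <- homeostaticCalibration()
  expect_equal(wp@c_e, wp2@c_e)
  expect_equal(wp@s_h, wp2@s_h)
  ## baseline circumferential stress at P_gr equals the set-point (Laplace)
  st <- solveEquilibratedNode(0, 0, wp)
  sigma_tt <- wp@P_gr * st$lam * wp@r0 / st$h
  expect_lt(abs(sigma_tt - wp@sigma0) / wp@sigma0, 1e-6)
  expect_error(homeostaticCalibration(target_D = 0.5), "distensibility")
})

test_that("zero-insult simulation is uniform at the baseline state", {
  wp <- wallFixture()
  g <- gridSpec()
  zero <- normalizeProfile(matrix(0, 41, 41), t0 = 0)
  pair <- makeInsultPair(zero, w = 0.5, s = 1)   # zero profile: no insult
  vf <- simulateTAA(pair, wp, g)
  d <- dilatationField(vf@r_dia, g)
  expect_equal(max(d) - min(d), 0, tolerance = 1e-12)
  expect_equal(unique(as.vector(d)), 1)
  D <- distensibilityField(vf@r_sys, vf@r_dia)
  expect_lt(max(abs(D - 0.05442)), 1e-5)
  expect_lt(abs(vf@sigma_tt[1, 1] - wp@sigma0) / wp@sigma0, 1e-6)
})

test_that("the simulation pipeline is equivariant under circumferential rotation", {
  wp <- wallFixture()
  g <- gridSpec()
  p <- profileFixture()
  roll <- function(m, k) m[c((k + 1):41, 1:k), , drop = FALSE]
  pair <- makeInsultPair(p, w = 0.3, s = 1.2)
  vf <- simulateTAA(pair, wp, g)
  p_r <- p
  p_r@field <- roll(p@field, 7L)
  vf_r <- simulateTAA(makeInsultPair(p_r, w = 0.3, s = 1.2), wp, g)
  expect_equal(vf_r@r_dia, roll(vf@r_dia, 7L))
  expect_equal(vf_r@r_sys, roll(vf@r_sys, 7L))
  expect_equal(vf_r@sigma_tt, roll(vf@sigma_tt, 7L))
  ## dilatation maps roll identically (end-row normalization is rotation
  ## invariant)
  expect_equal(dilatationField(vf_r@r_dia, g),
               roll(dilatationField(vf@r_dia, g), 7L))
})

test_that("maximum dilatation grows monotonically with the insult scale", {
  wp <- wallFixture()
  g <- gridSpec()
  p <- profileFixture()
  dmax <- vapply(c(0.3, 0.6, 0.9, 1.2, 1.4), function(s) {
    vf <- simulateTAA(makeInsultPair(p, w = 0.3, s = s), wp, g)
    max(dilatationField(vf@r_dia, g))
  }, numeric(1))
  expect_true(all(diff(dmax) > 0))
})

test_that("insult composition leaves the expected mechanical signatures", {
  ## at matched aneurysmal dilatation, elastic-fiber-dominated insults
  ## suppress distensibility more, while mechanosensing-dominated insults
  ## carry higher circumferential stress in the lesion
  wp <- wallFixture()
  g <- gridSpec()
  p <- profileFixture()
  sims <- lapply(c(0, 0.6), function(w) {
    s <- calibrateScale(p, w, wp)
    simulateTAA(makeInsultPair(p, w, as.numeric(s)), wp, g)
  })
  D <- lapply(sims, function(vf) distensibilityField(vf@r_sys, vf@r_dia))
  support <- p@field > 0
  ## distensibility suppressed inside the lesion for both
  expect_lt(min(D[[1]][support]), 0.05442)
  expect_lt(min(D[[2]][support]), 0.05442)
  ## elastic-dominated (w = 0.6) reaches a lower minimum
  expect_lt(min(D[[2]][support]), min(D[[1]][support]))
  ## mechanosensing-dominated carries higher mean lesion stress
  expect_gt(mean(sims[[1]]@sigma_tt[support]),
            mean(sims[[2]]@sigma_tt[support]))
})
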