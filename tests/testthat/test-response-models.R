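test_that("operational model response has the right values and limits", {
  sys <- system_params(1)
  ag <- agonist_params(k_a = 1e-6, tau_a = 3)

  expect_equal(om_response(0, sys, ag), 0)
  # near-saturating agonist approaches tau/(tau+1) of the system maximum
  expect_equal(om_response(1, sys, ag), 0.75, tolerance = 1e-5)
  expect_equal(om_response(1e-5, sys, agonist_params(1e-6, 0)), 0)

  # monotone non-decreasing and bounded by the asymptote
  a <- 10^seq(-10, -2, 0.25)
  y <- om_response(a, sys, ag)
  expect_true(all(diff(y) > 0))
  expect_true(all(y < 0.75))

  # basal is an additive offset
  sysb <- system_params(1, basal = 0.2)
  expect_equal(om_response(0, sysb, ag), 0.2)
  expect_equal(om_response(a, sysb, ag), y + 0.2)

  expect_error(om_response(-1e-9, sys, ag), "non-negative")
  expect_error(om_response(NaN, sys, ag), "finite")
})

test_that("allosteric model reduces exactly to its special cases", {
  set.seed(11)
  a <- c(0, 10^seq(-9, -4, 0.5))
  for (i in 1:20) {
    p <- draw_params()
    # no modulator: plain operational model
    expect_equal(omam_response(a, 0, p$sys, p$ag, p$mod),
                 om_response(a, p$sys, p$ag), tolerance = 1e-14)
    # no agonist: operational model in the allosteric ligand
    b <- c(0, 10^seq(-8, -3, 0.5))
    expect_equal(omam_response(0, b, p$sys, p$ag, p$mod),
                 allosteric_agonist_response(b, p$sys, p$mod),
                 tolerance = 1e-14)
    # neutral ligand: response independent of modulator concentration
    neutral <- modulator_params(p$mod$k_b, alpha = 1, beta = 1, tau_b = 0)
    for (bb in b)
      expect_equal(omam_response(a, bb, p$sys, p$ag, neutral),
                   om_response(a, p$sys, p$ag), tolerance = 1e-12)
    # at fixed [B] the curve in [A] is a hyperbola running monotonically
    # from the allosteric-agonist baseline to the ternary asymptote (it
    # descends when the ligand's own activity exceeds the modulated
    # agonist response); always bounded within [basal, basal + e_max)
    y <- omam_response(a, p$mod$k_b, p$sys, p$ag, p$mod)
    dir <- sign(y[length(y)] - y[1])
    expect_true(all(dir * diff(y) >= 0))
    expect_true(all(y >= p$sys$basal & y < p$sys$basal + p$sys$e_max))
    # a pure modulator never inverts the curve
    pm <- modulator_params(p$mod$k_b, p$mod$alpha, p$mod$beta, 0)
    expect_true(all(diff(omam_response(a, p$mod$k_b, p$sys, p$ag, pm)) >= 0))
  }
})

test_that("allosteric agonist alone follows the operational form in B", {
  sys <- system_params(1)
  mod <- modulator_params(k_b = 1e-6, tau_b = 1)
  expect_equal(allosteric_agonist_response(1e-6, sys, mod), 1 / 3)
  expect_equal(allosteric_agonist_response(1e4, sys, mod), 1 / 2,
               tolerance = 1e-9)
  mod0 <- modulator_params(k_b = 1e-6, tau_b = 0)
  expect_equal(allosteric_agonist_response(10^seq(-9, -3), sys, mod0),
               rep(0, 7))
})

test_that("logistic curve hits its anchor points and overlays the
           operational model when reparameterized", {
  p <- logistic_params(basal = 0.1, e_max_obs = 0.9, ec50 = 1e-7, n_h = 2)
  expect_equal(logistic_response(0, p), 0.1)
  expect_equal(logistic_response(1e-7, p), 0.5)
  expect_equal(logistic_response(1e3, p), 0.9, tolerance = 1e-9)

  # with unit slope and no basal it is the operational-model hyperbola
  sys <- system_params(1); ag <- agonist_params(1e-6, 3)
  pl <- logistic_params(basal = 0, e_max_obs = om_emax_obs(sys, ag),
                        ec50 = om_ec50(ag), n_h = 1)
  a <- 10^seq(-10, -3, 0.25)
  expect_equal(logistic_response(a, pl), om_response(a, sys, ag),
               tolerance = 1e-12)
  expect_error(logistic_response(-1, p), "non-negative")
})

test_that("curves generated by the operational models have unit Hill slope", {
  sys <- system_params(1)
  ag <- agonist_params(1e-6, 3)
  mod <- modulator_params(2e-6, alpha = 5, beta = 0.5, tau_b = 0.8)
  a <- c(0, 10^seq(-9.5, -4, 0.25))
  for (b in c(0, 1e-6, 1e-4)) {
    fit <- fit_logistic(a, omam_response(a, b, sys, ag, mod))
    expect_true(fit$converged)
    expect_equal(unname(coef(fit)[["n_h"]]), 1, tolerance = 1e-6)
  }
})
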