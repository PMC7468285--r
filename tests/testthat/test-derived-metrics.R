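test_that("agonist-alone EC50 and apparent maximum match the curve", {
  ag <- agonist_params(1e-6, 3); sys <- system_params(1)
  expect_equal(om_ec50(agonist_params(1e-6, 0)), 1e-6)
  expect_equal(om_ec50(ag), 2.5e-7)
  # bisection oracle on the forward curve
  mod0 <- modulator_params(1e-6)  # neutral, absent
  expect_equal(numeric_ec50(0, sys, ag, mod0), 2.5e-7, tolerance = 1e-8)

  expect_equal(om_emax_obs(sys, agonist_params(1e-6, 1)), 0.5)
  expect_equal(om_emax_obs(sys, ag), 0.75)
  expect_equal(numeric_emax_obs(0, sys, ag, mod0), 0.75, tolerance = 1e-9)

  # linear apparent-maximum/EC50 relation is consistent with both
  expect_equal(om_emax_vs_ec50(ag$k_a, sys, ag), 0)
  expect_equal(om_emax_vs_ec50(ag$k_a / 4, sys, ag), 0.75)
  expect_equal(om_emax_vs_ec50(om_ec50(ag), sys, ag), om_emax_obs(sys, ag))
  expect_equal(om_emax_vs_ec50(0, sys, ag), 1)
  expect_error(om_emax_vs_ec50(2e-6, sys, ag), "exceeds")
})

test_that("closed-form apparent parameters agree with numerical extraction
           from the forward model", {
  set.seed(21)
  for (i in 1:200) {
    p <- draw_params()
    b <- p$mod$k_b * 10^runif(1, -1.5, 2.5)
    expect_equal(omam_ec50(b, p$ag, p$mod),
                 numeric_ec50(b, p$sys, p$ag, p$mod),
                 tolerance = 1e-8)
    expect_equal(omam_emax_obs(b, p$sys, p$ag, p$mod),
                 numeric_emax_obs(b, p$sys, p$ag, p$mod),
                 tolerance = 1e-8)
  }
})

# The special-case formulas that hold under parameter restrictions
# (pure modulator, neutral affinity or efficacy, pure allosteric agonist)
# are kept here purely as regression oracles against the general forms.
test_that("restricted-case formulas agree with the general implementation", {
  set.seed(22)
  for (i in 1:50) {
    p <- draw_params()
    sys <- p$sys; ag <- p$ag
    ka <- ag$k_a; ta <- ag$tau_a; e <- sys$e_max
    kb <- p$mod$k_b; al <- p$mod$alpha; be <- p$mod$beta; tb <- p$mod$tau_b
    b <- kb * 10^runif(1, -1, 2)

    # agonist alone
    expect_equal(om_ec50(ag), ka / (ta + 1), tolerance = 1e-10)
    expect_equal(om_emax_obs(sys, ag), ta * e / (ta + 1), tolerance = 1e-10)

    # pure modulator (tau_b = 0)
    m0 <- modulator_params(kb, al, be, 0)
    expect_equal(omam_ec50(b, ag, m0),
                 ka * (b + kb) / (al * b + (al * be * b + kb) * ta + kb),
                 tolerance = 1e-10)
    expect_equal(omam_emax_obs(b, sys, ag, m0),
                 (al * be * b + kb) * ta * e /
                   (al * b + (al * be * b + kb) * ta + kb),
                 tolerance = 1e-10)
    expect_equal(dose_ratio(b, ag, m0),
                 (al * b + (kb + al * be * b) * ta + kb) /
                   ((ta + 1) * (kb + b)),
                 tolerance = 1e-10)

    # neutral efficacy (beta = 1, tau_b = 0): affinity-only shift
    m10 <- modulator_params(kb, al, 1, 0)
    expect_equal(dose_ratio(b, ag, m10), (kb + al * b) / (kb + b),
                 tolerance = 1e-10)
    # neutral affinity (alpha = 1, tau_b = 0)
    m01 <- modulator_params(kb, 1, be, 0)
    expect_equal(dose_ratio(b, ag, m01),
                 (ta * (be * b + kb) + b + kb) / (ta * (b + kb) + b + kb),
                 tolerance = 1e-10)

    # full allosteric-agonist dose ratio
    m <- modulator_params(kb, al, be, tb)
    expect_equal(dose_ratio(b, ag, m),
                 (al * be * b * ta + al * b + kb * ta + kb) /
                   ((ta + 1) * (b * tb + b + kb)),
                 tolerance = 1e-10)
    expect_equal(dose_ratio(b, ag, m), om_ec50(ag) / omam_ec50(b, ag, m),
                 tolerance = 1e-10)

    # pure allosteric agonist (alpha = beta = 1)
    m11 <- modulator_params(kb, 1, 1, tb)
    expect_equal(omam_ec50(b, ag, m11),
                 ka * (b * tb + b + kb) / ((ta + 1) * (b + kb)),
                 tolerance = 1e-10)
    expect_equal(dose_ratio(b, ag, m11),
                 (b + kb) / (b * tb + b + kb), tolerance = 1e-10)

    # allosteric agonist with neutral efficacy (beta = 1)
    mb1 <- modulator_params(kb, al, 1, tb)
    expect_equal(dose_ratio(b, ag, mb1),
                 (al * b + kb) / (b * tb + b + kb), tolerance = 1e-10)
    # allosteric agonist with neutral affinity (alpha = 1)
    ma1 <- modulator_params(kb, 1, be, tb)
    expect_equal(dose_ratio(b, ag, ma1),
                 (b + be * b * ta + kb * ta + kb) /
                   ((ta + 1) * (b + b * tb + kb)),
                 tolerance = 1e-10)

    # saturating-limit special cases against the general product form
    expect_equal(dose_ratio_limit(ag, m10), al, tolerance = 1e-10)
    expect_equal(dose_ratio_limit(ag, m01), (be * ta + 1) / (ta + 1),
                 tolerance = 1e-10)
    expect_equal(dose_ratio_limit(ag, m11), 1 / (tb + 1), tolerance = 1e-10)
    expect_equal(dose_ratio_limit(ag, mb1), al / (tb + 1), tolerance = 1e-10)
    expect_equal(dose_ratio_limit(ag, ma1),
                 (be * ta + 1) / ((ta + 1) * (tb + 1)), tolerance = 1e-10)

    # saturating apparent maximum
    expect_equal(omam_emax_obs(1e12 * kb, sys, ag, m),
                 be * ta * e / (be * ta + 1), tolerance = 1e-10)
  }
})

test_that("dose ratio behaves at its anchors and converges to its limit", {
  ag <- agonist_params(1e-6, 3)
  mod <- modulator_params(1e-6, alpha = 5, beta = 2, tau_b = 0.5)
  expect_equal(dose_ratio(0, ag, mod), 1)
  neutral <- modulator_params(1e-6, 1, 1, 0)
  expect_equal(dose_ratio(10^seq(-9, -3), ag, neutral), rep(1, 7))

  set.seed(23)
  for (i in 1:30) {
    p <- draw_params()
    expect_equal(dose_ratio(1e6 * p$mod$k_b, p$ag, p$mod),
                 dose_ratio_limit(p$ag, p$mod), tolerance = 1e-4)
  }
  # pure allosteric agonist at saturation halves the potency when tau_b = 1
  m <- modulator_params(1e-6, 1, 1, 1)
  expect_equal(dose_ratio(1e4 * 1e-6, ag, m), 1 / 2, tolerance = 1e-3)
  # affinity-neutral pure modulator with beta = 2
  m2 <- modulator_params(1e-6, 1, 2, 0)
  expect_equal(dose_ratio(1e6 * 1e-6, ag, m2), 7 / 4, tolerance = 1e-4)
})

test_that("apparent maximum is exactly independent of the allosteric
           ligand's intrinsic efficacy", {
  sys <- system_params(1); ag <- agonist_params(1e-6, 3)
  vals <- sapply(c(0, 0.1, 1, 10, 100), function(tb)
    omam_emax_obs(3e-6, sys, ag, modulator_params(1e-6, 2, 0.5, tb)))
  expect_identical(max(vals) - min(vals), 0)
})

test_that("affinity-only modulation shifts potency with constant maximum;
           efficacy modulation shifts both", {
  sys <- system_params(1); ag <- agonist_params(1e-6, 3)
  b <- 10^seq(-8, -3, 0.5)
  m_aff <- modulator_params(1e-6, alpha = 10, beta = 1, tau_b = 0)
  expect_true(all(diff(omam_ec50(b, ag, m_aff)) < 0))
  expect_equal(omam_emax_obs(b, sys, ag, m_aff),
               rep(om_emax_obs(sys, ag), length(b)), tolerance = 1e-12)
  m_eff <- modulator_params(1e-6, alpha = 1, beta = 5, tau_b = 0)
  expect_true(all(diff(omam_emax_obs(b, sys, ag, m_eff)) > 0))
  expect_true(all(diff(omam_ec50(b, ag, m_eff)) < 0))
})

test_that("an allosteric agonist with positive efficacy cooperativity can
           paradoxically reduce agonist potency", {
  sys <- system_params(1); ag <- agonist_params(1e-6, 3)
  # beta > 1 raises E'MAX, yet intrinsic activity tau_b dominates EC'50
  m <- modulator_params(1e-6, alpha = 1, beta = 2, tau_b = 3)
  b <- 1e-4
  expect_gt(omam_emax_obs(b, sys, ag, m), om_emax_obs(sys, ag))
  expect_gt(omam_ec50(b, ag, m), om_ec50(ag))
  expect_lt(dose_ratio_limit(ag, m), 1)
})

test_that("cooperativity inversions round-trip through the forward
           relations", {
  sys <- system_params(1); ag <- agonist_params(1e-6, 3)

  # beta from saturating apparent maximum
  expect_equal(beta_from_emax(om_emax_obs(sys, ag), sys, ag), 1)
  e8 <- 0.3 * 3 / (0.3 * 3 + 1)          # saturating maximum at beta = 0.3
  expect_equal(beta_from_emax(e8, sys, ag), 0.3, tolerance = 1e-12)
  expect_error(beta_from_emax(1.2, sys, ag), "below")

  # beta from a finite modulator concentration (alpha known)
  mod <- modulator_params(2e-6, alpha = 4, beta = 0.6, tau_b = 0.7)
  b <- 5e-6
  expect_equal(beta_from_emax_at_b(omam_emax_obs(b, sys, ag, mod), b,
                                   mod$alpha, sys, ag, mod$k_b),
               0.6, tolerance = 1e-10)
  expect_equal(beta_from_emax_at_b(om_emax_obs(sys, ag), 0, 4, sys, ag,
                                   mod$k_b), 1)

  # dose ratio expressed through the apparent maximum equals the direct form
  set.seed(24)
  for (i in 1:30) {
    p <- draw_params()
    b <- p$mod$k_b * 10^runif(1, -1, 2)
    e_obs <- omam_emax_obs(b, p$sys, p$ag, p$mod)
    expect_equal(dose_ratio_from_emax(b, e_obs, p$sys, p$ag, p$mod),
                 dose_ratio(b, p$ag, p$mod), tolerance = 1e-10)
    # and inverting it recovers alpha
    expect_equal(alpha_from_dose_ratio(dose_ratio(b, p$ag, p$mod), e_obs,
                                       b, p$sys, p$ag, p$mod$k_b,
                                       p$mod$tau_b),
                 p$mod$alpha, tolerance = 1e-8)
  }

  # named round-trips
  m1 <- modulator_params(1e-6, alpha = 10, beta = 2, tau_b = 0)
  b <- m1$k_b
  expect_equal(alpha_from_dose_ratio(dose_ratio(b, ag, m1),
                                     omam_emax_obs(b, sys, ag, m1),
                                     b, sys, ag, m1$k_b, 0),
               10, tolerance = 1e-10)
  m2 <- modulator_params(1e-6, alpha = 0.3, beta = 1, tau_b = 1)
  expect_equal(alpha_from_dose_ratio(dose_ratio(b, ag, m2),
                                     omam_emax_obs(b, sys, ag, m2),
                                     b, sys, ag, m2$k_b, 1),
               0.3, tolerance = 1e-10)
  # continuity convention at zero modulator
  expect_equal(alpha_from_dose_ratio(1, om_emax_obs(sys, ag), 0, sys, ag,
                                     1e-6, 0), 1)
})
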