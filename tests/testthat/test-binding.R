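test_that("saturation and competition binding curves evaluate correctly", {
  expect_equal(saturation_binding(5e-10, 100, 5e-10), 50)
  expect_equal(saturation_binding(0, 100, 5e-10), 0)
  expect_equal(saturation_binding(1.5e-9, 100, 5e-10), 75)
  expect_error(saturation_binding(-1e-9, 100, 5e-10), "non-negative")

  expect_equal(two_site_competition(0, 1e-8, 1e-6, 30), 100)
  expect_equal(two_site_competition(1e-8, 1e-8, 1e-6, 0), 50)
  # at the high-affinity midpoint, the low-affinity half is still intact
  expect_equal(two_site_competition(1e-9, 1e-9, 1e-3, 50), 75,
               tolerance = 1e-5)
  x <- 10^seq(-11, -3, 0.5)
  y <- two_site_competition(x, 1e-8, 1e-6, 40)
  expect_true(all(diff(y) < 0))
  expect_lt(two_site_competition(1, 1e-8, 1e-6, 40), 0.01)
})

test_that("Cheng-Prusoff correction behaves at its anchors", {
  tr <- tracer_params(d_conc = 1e-12, k_d = 5e-10)
  expect_equal(ki_from_ic50(3e-9, tr), 3e-9, tolerance = 1e-2)
  expect_equal(ki_from_ic50(3e-9, tracer_params(5e-10, 5e-10)), 1.5e-9)
  # tracer at 1 nM with K_D = 0.5 nM: IC50 of 3 nM maps to K_I of 1 nM
  expect_equal(ki_from_ic50(3e-9, tracer_params(1e-9, 5e-10)), 1e-9)
})

test_that("allosteric tracer shift plateaus instead of full inhibition", {
  tr <- tracer_params(d_conc = 1e-9, k_d = 5e-10)
  # neutral cooperativity: binding untouched at any concentration
  expect_equal(tracer_binding_shift(10^seq(-9, -3), tr, 5e-7, 1),
               rep(100, 7))
  # asymptote formula
  set.seed(31)
  for (i in 1:20) {
    d <- 10^runif(1, -10, -8); kd <- 10^runif(1, -10, -8)
    kb <- 10^runif(1, -8, -5); al <- 10^runif(1, -1.5, 1)
    trx <- tracer_params(d, kd)
    expect_equal(tracer_binding_shift(1e12 * kb, trx, kb, al),
                 100 * (d + kd) / (d + kd / al), tolerance = 1e-10)
  }
  # worked point: x = K_B, [D] = K_D, alpha = 0.5 -> 6/7 of control
  trq <- tracer_params(1e-9, 1e-9)
  expect_equal(tracer_binding_shift(5e-7, trq, 5e-7, 0.5), 600 / 7)
})

test_that("fixed-agonist tracer model reduces to the agonist-free one", {
  set.seed(32)
  tr <- tracer_params(1e-9, 5e-10)
  b <- c(0, 10^seq(-8, -4, 0.5))
  for (i in 1:20) {
    kb <- 10^runif(1, -8, -5); ka <- 10^runif(1, -8, -5)
    a1 <- 10^runif(1, -1, 1); a2 <- 10^runif(1, -1, 1)
    expect_equal(tracer_binding_shift_with_agonist(b, 0, tr, ka, kb, a1, a2),
                 tracer_binding_shift(b, tr, kb, a1), tolerance = 1e-12)
  }
  # no modulator: classical competitive occupancy by the agonist
  a <- 2e-6; ka <- 1e-6
  expect_equal(tracer_binding_shift_with_agonist(0, a, tr, ka, 1e-6, 0.5, 2),
               100 * (1e-9 + 5e-10) / (1e-9 + 5e-10 * (1 + a / ka)))
})

test_that("competition fits recover truth and pick the right site model", {
  x <- 10^seq(-10.5, -3.5, 0.25)
  y2 <- two_site_competition(x, 1e-8, 1e-6, 40)
  f2 <- fit_binding_competition(x, y2)
  expect_identical(f2$model_choice, "two_site")
  expect_equal(unname(coef(f2)[["ic50_high"]]), 1e-8, tolerance = 1e-6)
  expect_equal(unname(coef(f2)[["ic50_low"]]), 1e-6, tolerance = 1e-6)
  expect_equal(unname(coef(f2)[["f_low"]]), 40, tolerance = 1e-6)

  y1 <- two_site_competition(x, 3e-8, 3e-8, 0)
  f1 <- fit_binding_competition(x, y1)
  expect_identical(f1$model_choice, "one_site")
  expect_equal(unname(coef(f1)[["ic50"]]), 3e-8, tolerance = 1e-8)
})

test_that("allosteric binding fits recover the shift parameters", {
  tr <- tracer_params(1e-9, 5e-10)
  b <- c(0, 10^seq(-8.5, -3.5, 0.25))
  y <- tracer_binding_shift(b, tr, 5e-7, 0.3)
  f <- fit_binding_allosteric(b, y, tr)
  expect_true(f$converged)
  expect_equal(unname(coef(f)[["k_b"]]), 5e-7, tolerance = 1e-6)
  expect_equal(unname(coef(f)[["alpha_tracer"]]), 0.3, tolerance = 1e-6)

  ya <- tracer_binding_shift_with_agonist(b, 1e-6, tr, 3e-7, 5e-7, 0.3, 4)
  fa <- fit_binding_allosteric_agonist(b, ya, 1e-6, tr, 3e-7, 5e-7, 0.3)
  expect_equal(unname(coef(fa)[["alpha_agonist"]]), 4, tolerance = 1e-6)

  fs <- fit_binding_saturation(10^seq(-11, -8, 0.25),
                               saturation_binding(10^seq(-11, -8, 0.25),
                                                  120, 5e-10))
  expect_equal(unname(coef(fs)[["b_max"]]), 120, tolerance = 1e-7)
  expect_equal(unname(coef(fs)[["k_d"]]), 5e-10, tolerance = 1e-7)
})
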