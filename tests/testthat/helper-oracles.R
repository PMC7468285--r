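# Independent numerical oracles: curve descriptors extracted from the
# forward response function itself, without using any closed-form relation.

# upper asymptote of the curve in [A] at fixed [B]: ratio of the leading
# coefficients of the rational function, obtained by evaluation at a
# concentration far above all dissociation constants
numeric_emax_obs <- function(b, sys, ag, mod, a_big = NULL) {
  if (is.null(a_big)) a_big <- 1e10 * max(ag$k_a, mod$k_b, b, 1e-12)
  omam_response(a_big, b, sys, ag, mod) - sys$basal
}

# mid-asymptote agonist concentration by bisection on the monotone curve
numeric_ec50 <- function(b, sys, ag, mod) {
  r0 <- omam_response(0, b, sys, ag, mod)
  rinf <- numeric_emax_obs(b, sys, ag, mod) + sys$basal
  target <- (r0 + rinf) / 2
  f <- function(a) omam_response(a, b, sys, ag, mod) - target
  uniroot(f, lower = ag$k_a * 1e-10, upper = ag$k_a * 1e10,
          tol = ag$k_a * 1e-14)$root
}

# random valid parameter draws used by property-style tests
draw_params <- function() {
  list(sys = system_params(e_max = 10^runif(1, -0.5, 1)),
       ag = agonist_params(k_a = 10^runif(1, -8, -5),
                           tau_a = 10^runif(1, -0.7, 1)),
       mod = modulator_params(k_b = 10^runif(1, -7, -4),
                              alpha = 10^runif(1, -1, 1.5),
                              beta = 10^runif(1, -1, 1),
                              tau_b = runif(1, 0, 3)))
}

# random scenario within the workflow-recovery study bounds
draw_scenario <- function(noise_cv = 0.05, n_replicates = 3) {
  k_b <- 10^runif(1, -7, -5)
  omam_scenario(
    sys = system_params(1),
    ag = agonist_params(k_a = 10^runif(1, -7, -5),
                        tau_a = runif(1, 0.5, 10)),
    mod = modulator_params(k_b = k_b,
                           alpha = 10^runif(1, log10(0.1), log10(30)),
                           beta = 10^runif(1, log10(0.1), log10(10)),
                           tau_b = runif(1, 0, 3)),
    b_grid = k_b * c(0, 1, 10, 100),
    noise_cv = noise_cv, n_replicates = n_replicates)
}
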