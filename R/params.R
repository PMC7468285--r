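#' Parameter containers for operational-model calculations
#'
#' Lightweight validated containers for the constants of the operational
#' model (OM) and its allosteric extension.  All dissociation constants and
#' concentrations are molar; efficacies and cooperativity factors are
#' dimensionless.
#'
#' @param e_max maximal possible response of the system (response units, > 0)
#' @param basal response in the absence of any ligand (response units,
#'   >= 0 and < \code{e_max}); the forward models add it as an additive
#'   offset, default 0
#' @return an object of class \code{"system_params"}
#' @examples
#' sys <- system_params(e_max = 1)
#' ag  <- agonist_params(k_a = 1e-6, tau_a = 3)
#' mod <- modulator_params(k_b = 1e-6, alpha = 10, beta = 1)
#' @seealso [agonist_params()], [modulator_params()], [logistic_params()]
#' @export
system_params <- function(e_max, basal = 0) {
  stopifnot(is.numeric(e_max), length(e_max) == 1L, is.finite(e_max), e_max > 0,
            is.numeric(basal), length(basal) == 1L, is.finite(basal),
            basal >= 0, basal < e_max)
  structure(list(e_max = e_max, basal = basal), class = "system_params")
}

#' @rdname system_params
#' @param k_a equilibrium dissociation constant of the agonist-receptor
#'   complex (molar, > 0)
#' @param tau_a operational efficacy of the orthosteric agonist
#'   (dimensionless, >= 0)
#' @export
agonist_params <- function(k_a, tau_a) {
  stopifnot(is.numeric(k_a), length(k_a) == 1L, is.finite(k_a), k_a > 0,
            is.numeric(tau_a), length(tau_a) == 1L, is.finite(tau_a), tau_a >= 0)
  structure(list(k_a = k_a, tau_a = tau_a), class = "agonist_params")
}

#' @rdname system_params
#' @param k_b equilibrium dissociation constant of the allosteric
#'   ligand-receptor complex (molar, > 0)
#' @param alpha factor of binding cooperativity between orthosteric agonist
#'   and allosteric ligand (> 0; > 1 positive, < 1 negative)
#' @param beta factor of operational cooperativity: fold-change of the
#'   agonist operational efficacy in the ternary complex (>= 0)
#' @param tau_b operational efficacy of the allosteric ligand itself
#'   (>= 0; 0 means a pure modulator without intrinsic activity)
#' @export
modulator_params <- function(k_b, alpha = 1, beta = 1, tau_b = 0) {
  stopifnot(is.numeric(k_b), length(k_b) == 1L, is.finite(k_b), k_b > 0,
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha > 0,
            is.numeric(beta), length(beta) == 1L, is.finite(beta), beta >= 0,
            is.numeric(tau_b), length(tau_b) == 1L, is.finite(tau_b), tau_b >= 0)
  structure(list(k_b = k_b, alpha = alpha, beta = beta, tau_b = tau_b),
            class = "modulator_params")
}

#' @rdname system_params
#' @param e_max_obs upper asymptote of the empirical curve (response units,
#'   > \code{basal})
#' @param ec50 half-efficient concentration (molar, > 0)
#' @param n_h Hill coefficient (> 0)
#' @export
logistic_params <- function(basal, e_max_obs, ec50, n_h = 1) {
  stopifnot(is.numeric(basal), length(basal) == 1L, is.finite(basal),
            is.numeric(e_max_obs), length(e_max_obs) == 1L, is.finite(e_max_obs),
            e_max_obs > basal,
            is.numeric(ec50), length(ec50) == 1L, is.finite(ec50), ec50 > 0,
            is.numeric(n_h), length(n_h) == 1L, is.finite(n_h), n_h > 0)
  structure(list(basal = basal, e_max_obs = e_max_obs, ec50 = ec50, n_h = n_h),
            class = "logistic_params")
}

#' @rdname system_params
#' @param d_conc tracer (radioligand) concentration (molar, > 0)
#' @param k_d tracer equilibrium dissociation constant (molar, > 0)
#' @export
tracer_params <- function(d_conc, k_d) {
  stopifnot(is.numeric(d_conc), length(d_conc) == 1L, is.finite(d_conc), d_conc > 0,
            is.numeric(k_d), length(k_d) == 1L, is.finite(k_d), k_d > 0)
  structure(list(d_conc = d_conc, k_d = k_d), class = "tracer_params")
}

#' @export
print.system_params <- function(x, ...) {
  cat("System: E_MAX =", format(x$e_max), " basal =", format(x$basal), "\n")
  invisible(x)
}

#' @export
print.agonist_params <- function(x, ...) {
  cat("Agonist: K_A =", format(x$k_a), "M (pK_A =",
      format(round(-log10(x$k_a), 3)), ") tau_A =", format(x$tau_a), "\n")
  invisible(x)
}

#' @export
print.modulator_params <- function(x, ...) {
  cat("Allosteric ligand: K_B =", format(x$k_b), "M  alpha =", format(x$alpha),
      " beta =", format(x$beta), " tau_B =", format(x$tau_b), "\n")
  invisible(x)
}

# internal: validate a concentration vector (0 allowed = ligand absent)
check_conc <- function(x, what = "concentration") {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop(sprintf("%s must be finite and non-negative (molar)", what),
         call. = FALSE)
  x
}
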