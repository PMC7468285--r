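#' Forward response functions of the operational model
#'
#' Closed-form concentration-response functions.  \code{om_response()} is the
#' operational model of agonism for a single orthosteric agonist,
#'
#' \deqn{Resp = basal + \frac{[A]\,\tau_A\,E_{MAX}}{[A](\tau_A+1) + K_A}}
#'
#' \code{omam_response()} is the operational model of allosterically-modulated
#' agonism (OMAM) for an orthosteric agonist A in the presence of an
#' allosteric ligand B that changes agonist affinity by the binding
#' cooperativity factor \eqn{\alpha}, changes operational efficacy by the
#' operational cooperativity factor \eqn{\beta}, and may itself activate the
#' receptor with efficacy \eqn{\tau_B}:
#'
#' \deqn{Resp = basal + \frac{E_{MAX}\left(\tau_A [A](K_B+\alpha\beta[B]) +
#'   \tau_B [B] K_A\right)}{[A]K_B + K_A K_B + [B]K_A + \alpha[A][B] +
#'   \tau_A [A](K_B+\alpha\beta[B]) + \tau_B [B] K_A}}
#'
#' Setting \eqn{[B]=0} recovers \code{om_response()}; setting \eqn{[A]=0}
#' recovers \code{allosteric_agonist_response()} (the operational model in B
#' with constants \eqn{K_B, \tau_B}); setting \eqn{\tau_B=0} gives the
#' pure-modulator model.  The models as printed return 0 at zero ligand; the
#' system basal is added as an additive offset (default 0).
#'
#' @param a orthosteric agonist concentration(s), molar (0 allowed)
#' @param b allosteric ligand concentration(s), molar (0 allowed)
#' @param sys a [system_params()] object
#' @param ag an [agonist_params()] object
#' @param mod a [modulator_params()] object
#' @return response in the units of \code{sys$e_max}; vectorized over
#'   concentrations (recycled against each other)
#' @examples
#' sys <- system_params(e_max = 1)
#' ag  <- agonist_params(k_a = 1e-6, tau_a = 3)
#' om_response(1e-6, sys, ag)          # 0.6
#' mod <- modulator_params(k_b = 1e-6, alpha = 10, beta = 1)
#' omam_response(1e-7, 1e-5, sys, ag, mod)
#' @export
om_response <- function(a, sys, ag) {
  a <- check_conc(a, "agonist concentration")
  sys$basal + a * ag$tau_a * sys$e_max / (a * (ag$tau_a + 1) + ag$k_a)
}

#' @rdname om_response
#' @export
omam_response <- function(a, b, sys, ag, mod) {
  a <- check_conc(a, "agonist concentration")
  b <- check_conc(b, "modulator concentration")
  kb_ab <- mod$k_b + mod$alpha * mod$beta * b
  num <- sys$e_max * (ag$tau_a * a * kb_ab + mod$tau_b * b * ag$k_a)
  den <- a * mod$k_b + ag$k_a * mod$k_b + b * ag$k_a + mod$alpha * a * b +
    ag$tau_a * a * kb_ab + mod$tau_b * b * ag$k_a
  sys$basal + num / den
}

#' @rdname om_response
#' @export
allosteric_agonist_response <- function(b, sys, mod) {
  b <- check_conc(b, "allosteric agonist concentration")
  sys$basal + b * mod$tau_b * sys$e_max / (b * (mod$tau_b + 1) + mod$k_b)
}

#' Empirical logistic (four-parameter Hill) concentration-response curve
#'
#' \deqn{y = basal + \frac{(E'_{MAX} - basal)\,x^{n_H}}{x^{n_H} + EC_{50}^{n_H}}}
#'
#' used as the model-agnostic first stage of curve analysis: its inflexion
#' point (EC50) and upper asymptote (E'MAX) are unaffected by the Hill
#' coefficient, so the derived operational-model relations apply to flat or
#' steep curves as well.
#'
#' @param x ligand concentration(s), molar (>= 0)
#' @param p a [logistic_params()] object
#' @return response in the units of \code{p$e_max_obs}
#' @examples
#' p <- logistic_params(basal = 0, e_max_obs = 1, ec50 = 1e-7)
#' logistic_response(1e-7, p)   # 0.5
#' @export
logistic_response <- function(x, p) {
  x <- check_conc(x, "concentration")
  xn <- x^p$n_h
  p$basal + (p$e_max_obs - p$basal) * xn / (xn + p$ec50^p$n_h)
}
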