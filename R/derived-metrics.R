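#' Apparent curve parameters and dose ratios of the operational model
#'
#' Closed-form expressions for the observable descriptors of
#' concentration-response curves under the operational model and its
#' allosteric extension.  Without a modulator,
#' \deqn{EC_{50} = K_A/(\tau_A+1), \qquad E'_{MAX} = \tau_A E_{MAX}/(\tau_A+1).}
#' At a fixed allosteric-ligand concentration \eqn{[B]} the curve in
#' \eqn{[A]} remains a rectangular hyperbola whose mid-asymptote
#' concentration and upper asymptote are
#' \deqn{EC'_{50} = \frac{K_A\,(K_B + [B](1+\tau_B))}
#'   {K_B + \alpha[B] + \tau_A(K_B + \alpha\beta[B])}}
#' \deqn{E'_{MAX} = \frac{(K_B + \alpha\beta[B])\,\tau_A\,E_{MAX}}
#'   {K_B + \alpha[B] + \tau_A(K_B + \alpha\beta[B])}}
#' \eqn{E'_{MAX}} does not depend on \eqn{\tau_B}; an allosteric agonist
#' raises the lower asymptote of the curve, not the upper one.
#' All values are on the response scale above basal (the additive basal
#' offset of the forward models cancels from ratios and is not included).
#'
#' @param ag an [agonist_params()] object
#' @param sys a [system_params()] object
#' @param mod a [modulator_params()] object
#' @param b allosteric ligand concentration(s), molar (0 allowed)
#' @return `om_ec50()`/`omam_ec50()` molar concentrations; `om_emax_obs()`/
#'   `omam_emax_obs()` responses above basal
#' @examples
#' ag <- agonist_params(1e-6, 3); sys <- system_params(1)
#' om_ec50(ag)                     # 2.5e-7
#' om_emax_obs(sys, ag)            # 0.75
#' @export
om_ec50 <- function(ag) ag$k_a / (ag$tau_a + 1)

#' @rdname om_ec50
#' @export
om_emax_obs <- function(sys, ag) ag$tau_a * sys$e_max / (ag$tau_a + 1)

#' @rdname om_ec50
#' @param ec50 observed half-efficient concentration(s), molar; must not
#'   exceed \code{ag$k_a} (EC50 = K_A is the zero-efficacy limit)
#' @details `om_emax_vs_ec50()` is the linear relation
#'   \eqn{E'_{MAX} = E_{MAX} - E_{MAX}\,EC_{50}/K_A} that links the two
#'   observables of a single curve; fitted to a batch of agonists it
#'   determines the system maximum \eqn{E_{MAX}}.
#' @export
om_emax_vs_ec50 <- function(ec50, sys, ag) {
  if (any(ec50 > ag$k_a))
    stop("ec50 exceeds k_a: would imply negative apparent maximal response",
         call. = FALSE)
  sys$e_max - sys$e_max * ec50 / ag$k_a
}

#' @rdname om_ec50
#' @export
omam_ec50 <- function(b, ag, mod) {
  b <- check_conc(b, "modulator concentration")
  ag$k_a * (mod$k_b + b * (1 + mod$tau_b)) /
    (mod$k_b + mod$alpha * b + ag$tau_a * (mod$k_b + mod$alpha * mod$beta * b))
}

#' @rdname om_ec50
#' @export
omam_emax_obs <- function(b, sys, ag, mod) {
  b <- check_conc(b, "modulator concentration")
  kb_ab <- mod$k_b + mod$alpha * mod$beta * b
  kb_ab * ag$tau_a * sys$e_max /
    (mod$k_b + mod$alpha * b + ag$tau_a * kb_ab)
}

#' Dose ratios under allosteric modulation
#'
#' The dose ratio \eqn{EC_{50}/EC'_{50}} quantifies the potency shift of an
#' orthosteric agonist produced by an allosteric ligand at concentration
#' \eqn{[B]}; values above 1 denote increased potency.  In closed form
#' \deqn{\frac{EC_{50}}{EC'_{50}} =
#'   \frac{\alpha\beta[B]\tau_A + \alpha[B] + K_B\tau_A + K_B}
#'        {(\tau_A+1)\,([B]\tau_B + [B] + K_B)}}
#' with the saturating limit (\eqn{[B] \gg K_B})
#' \deqn{\frac{EC_{50}}{EC'_{50}} \to
#'   \frac{\alpha(\beta\tau_A+1)}{(\tau_A+1)(\tau_B+1)}}
#' which reduces to \eqn{\alpha} for a neutral-efficacy pure modulator
#' (\eqn{\beta=1,\tau_B=0}), to \eqn{(\beta\tau_A+1)/(\tau_A+1)} for
#' \eqn{\alpha=1,\tau_B=0}, to \eqn{1/(\tau_B+1)} for a pure allosteric
#' agonist (\eqn{\alpha=\beta=1}) and to \eqn{\alpha/(\tau_B+1)} for
#' \eqn{\beta=1}.
#'
#' @inheritParams om_ec50
#' @return dimensionless dose ratio(s)
#' @examples
#' ag <- agonist_params(1e-6, 3)
#' mod <- modulator_params(1e-6, alpha = 10, beta = 1)
#' dose_ratio(1e-4, ag, mod)     # ~ alpha
#' dose_ratio_limit(ag, mod)     # exactly alpha
#' @export
dose_ratio <- function(b, ag, mod) {
  b <- check_conc(b, "modulator concentration")
  (mod$alpha * mod$beta * b * ag$tau_a + mod$alpha * b +
     mod$k_b * ag$tau_a + mod$k_b) /
    ((ag$tau_a + 1) * (b * mod$tau_b + b + mod$k_b))
}

#' @rdname dose_ratio
#' @export
dose_ratio_limit <- function(ag, mod) {
  mod$alpha * (mod$beta * ag$tau_a + 1) /
    ((ag$tau_a + 1) * (mod$tau_b + 1))
}

#' @rdname dose_ratio
#' @param e_max_obs observed apparent maximal response (above basal), must
#'   be < \code{sys$e_max}
#' @details `dose_ratio_from_emax()` re-expresses the dose ratio through the
#'   measured \eqn{E'_{MAX}} so that \eqn{\beta} is eliminated:
#'   \deqn{\frac{EC_{50}}{EC'_{50}} = \frac{E_{MAX}(\alpha[B]+K_B)}
#'     {(\tau_A+1)(E_{MAX}-E'_{MAX})([B]\tau_B+[B]+K_B)}}
#'   This is the form inverted by [alpha_from_dose_ratio()] to obtain the
#'   binding cooperativity from measured curve descriptors alone.
#' @export
dose_ratio_from_emax <- function(b, e_max_obs, sys, ag, mod) {
  b <- check_conc(b, "modulator concentration")
  if (any(e_max_obs >= sys$e_max))
    stop("e_max_obs must be below the system e_max", call. = FALSE)
  sys$e_max * (mod$alpha * b + mod$k_b) /
    ((ag$tau_a + 1) * (sys$e_max - e_max_obs) *
       (b * mod$tau_b + b + mod$k_b))
}

#' Analytic inversions used by the staged workflow
#'
#' `beta_from_emax()` recovers the operational cooperativity factor from the
#' apparent maximal response at a saturating modulator concentration,
#' inverting \eqn{E'_{MAX} = \beta\tau_A E_{MAX}/(\beta\tau_A+1)}:
#' \deqn{\beta = \frac{E'_{MAX}}{\tau_A\,(E_{MAX} - E'_{MAX})}}
#' `beta_from_emax_at_b()` is the finite-concentration counterpart (needs
#' \eqn{\alpha}); `alpha_from_dose_ratio()` recovers the binding
#' cooperativity from a measured dose ratio and \eqn{E'_{MAX}} at the same
#' \eqn{[B]}.  All inversions are closed-form; no regression is involved.
#'
#' @param e_max_obs_sat apparent maximal response (above basal) at a
#'   saturating modulator concentration; must lie in (0, e_max)
#' @inheritParams dose_ratio
#' @return the dimensionless cooperativity factor
#' @examples
#' sys <- system_params(1); ag <- agonist_params(1e-6, 3)
#' beta_from_emax(6/7, sys, ag)   # 2
#' @export
beta_from_emax <- function(e_max_obs_sat, sys, ag) {
  if (ag$tau_a <= 0) stop("tau_a must be positive", call. = FALSE)
  if (any(e_max_obs_sat >= sys$e_max))
    stop("e_max_obs_sat must be below the system e_max", call. = FALSE)
  e_max_obs_sat / (ag$tau_a * (sys$e_max - e_max_obs_sat))
}

#' @rdname beta_from_emax
#' @param alpha binding cooperativity factor (predetermined)
#' @param k_b allosteric ligand equilibrium dissociation constant, molar
#' @export
beta_from_emax_at_b <- function(e_max_obs, b, alpha, sys, ag, k_b) {
  if (any(e_max_obs >= sys$e_max))
    stop("e_max_obs must be below the system e_max", call. = FALSE)
  b <- check_conc(b, "modulator concentration")
  out <- (e_max_obs * (k_b + alpha * b) /
            (ag$tau_a * (sys$e_max - e_max_obs)) - k_b) / (alpha * b)
  out[b == 0] <- 1  # 0/0 at [B]=0: no modulation, beta = 1 by continuity
  out
}

#' @rdname beta_from_emax
#' @param dr measured dose ratio EC50/EC'50 at concentration \code{b}
#' @param tau_b operational efficacy of the allosteric ligand
#'   (predetermined; 0 for a pure modulator)
#' @export
alpha_from_dose_ratio <- function(dr, e_max_obs, b, sys, ag, k_b, tau_b = 0) {
  if (any(dr <= 0)) stop("dose ratio must be positive", call. = FALSE)
  if (any(e_max_obs >= sys$e_max))
    stop("e_max_obs must be below the system e_max", call. = FALSE)
  b <- check_conc(b, "modulator concentration")
  out <- (dr * (ag$tau_a + 1) * (sys$e_max - e_max_obs) *
            (b * tau_b + b + k_b) / sys$e_max - k_b) / b
  out[b == 0] <- 1  # 0/0 at [B]=0: alpha = 1 by continuity
  if (any(out <= 0))
    stop("inputs give a non-positive alpha: degenerate dose-ratio inversion",
         call. = FALSE)
  out
}
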