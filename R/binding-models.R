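#' Radioligand-binding models
#'
#' Equilibrium binding curves used to predetermine dissociation constants
#' before functional fitting.  `saturation_binding()` is the one-site
#' hyperbola \eqn{y = B_{MAX} x/(x + K_D)}.  `two_site_competition()` is the
#' two-population competition curve (in per cent of control binding)
#' \deqn{y = 100 - (100 - f_{low})\frac{x}{x + IC_{50high}}
#'       - f_{low}\frac{x}{x + IC_{50low}}}
#' `ki_from_ic50()` applies the Cheng-Prusoff correction
#' \eqn{K_I = IC_{50}/(1 + [D]/K_D)} for a tracer present at concentration
#' \eqn{[D]}.
#'
#' @param x competitor/ligand concentration(s), molar (>= 0)
#' @param b_max maximal binding capacity (counts or fmol/mg)
#' @param k_d tracer equilibrium dissociation constant, molar
#' @return binding in the input units (`saturation_binding`) or per cent of
#'   control (competition and allosteric-shift models)
#' @examples
#' saturation_binding(5e-10, b_max = 100, k_d = 5e-10)  # 50
#' ki_from_ic50(3e-9, tracer_params(d_conc = 1e-9, k_d = 5e-10))  # 1e-9
#' @export
saturation_binding <- function(x, b_max, k_d) {
  x <- check_conc(x, "ligand concentration")
  b_max * x / (x + k_d)
}

#' @rdname saturation_binding
#' @param ic50_high,ic50_low half-inhibition concentrations at the high- and
#'   low-affinity site populations, molar (`ic50_high <= ic50_low`)
#' @param f_low fraction of low-affinity sites, per cent (0..100);
#'   \code{f_low = 0} gives the one-site curve
#' @export
two_site_competition <- function(x, ic50_high, ic50_low, f_low) {
  x <- check_conc(x, "competitor concentration")
  stopifnot(f_low >= 0, f_low <= 100)
  100 - (100 - f_low) * x / (x + ic50_high) - f_low * x / (x + ic50_low)
}

#' @rdname saturation_binding
#' @param ic50 half-inhibition concentration from a competition fit, molar
#' @param tracer a [tracer_params()] object
#' @export
ki_from_ic50 <- function(ic50, tracer) {
  ic50 / (1 + tracer$d_conc / tracer$k_d)
}

#' Allosteric shift of tracer binding
#'
#' Equilibrium binding of an orthosteric tracer in the presence of an
#' allosteric ligand titrated at concentration \eqn{x}:
#' \deqn{y = 100\,\frac{[D] + K_D}{[D] + K_D\,\frac{K_B + x}{K_B + x\,\alpha_1}}}
#' The curve plateaus at \eqn{100([D]+K_D)/([D]+K_D/\alpha_1)} rather than
#' falling to zero -- the incomplete-inhibition signature that distinguishes
#' an allosteric from a competitive interaction.  \eqn{\alpha_1} is the
#' cooperativity between tracer and allosteric ligand (a different quantity
#' from the agonist-modulator \eqn{\alpha} of the functional model).
#'
#' `tracer_binding_shift_with_agonist()` adds an orthosteric agonist at a
#' fixed concentration \eqn{[A]}; \eqn{\alpha_2} is the agonist-modulator
#' cooperativity.  At \eqn{[A]=0} it reduces exactly to the agonist-free
#' curve.
#'
#' @param x,b allosteric ligand concentration(s), molar (>= 0)
#' @param tracer a [tracer_params()] object
#' @param k_b allosteric ligand equilibrium dissociation constant, molar
#' @param alpha_tracer cooperativity \eqn{\alpha_1} between tracer and
#'   allosteric ligand (> 0)
#' @return per cent of control binding (100 at \code{x = 0})
#' @examples
#' tr <- tracer_params(d_conc = 1e-9, k_d = 5e-10)
#' tracer_binding_shift(1e-5, tr, k_b = 5e-7, alpha_tracer = 0.3)
#' @export
tracer_binding_shift <- function(x, tracer, k_b, alpha_tracer) {
  x <- check_conc(x, "modulator concentration")
  stopifnot(alpha_tracer > 0, k_b > 0)
  100 * (tracer$d_conc + tracer$k_d) /
    (tracer$d_conc + tracer$k_d * (k_b + x) / (k_b + x * alpha_tracer))
}

#' @rdname tracer_binding_shift
#' @param a fixed orthosteric agonist concentration, molar
#' @param k_a agonist equilibrium dissociation constant, molar
#' @param alpha_agonist cooperativity \eqn{\alpha_2} between agonist and
#'   allosteric ligand (> 0)
#' @export
tracer_binding_shift_with_agonist <- function(b, a, tracer, k_a, k_b,
                                              alpha_tracer, alpha_agonist) {
  b <- check_conc(b, "modulator concentration")
  a <- check_conc(a, "agonist concentration")
  stopifnot(alpha_tracer > 0, alpha_agonist > 0, k_a > 0, k_b > 0)
  ratio <- (a * (k_b + b * alpha_agonist) + k_a * (k_b + b)) /
    (k_a * (k_b + b * alpha_tracer))
  100 * (tracer$d_conc + tracer$k_d) /
    (tracer$d_conc + tracer$k_d * ratio)
}
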