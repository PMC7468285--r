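#' Synthetic concentration-response scenarios with known ground truth
#'
#' A scenario bundles the true model constants with an experimental design
#' (modulator concentration arm, log-spaced agonist grid, replicate count)
#' and a noise model.  Noise is additive Gaussian with standard deviation
#' \code{noise_floor + noise_cv * |signal|}; the defaults (5% proportional,
#' no floor, 3 replicates) emulate a well-behaved functional assay read out
#' as mean curves from replicate wells.
#'
#' @param sys,ag,mod true [system_params()], [agonist_params()],
#'   [modulator_params()]
#' @param b_grid modulator concentrations, molar; include 0 for the
#'   agonist-alone control curve
#' @param a_grid agonist concentrations, molar; default 9 half-log-spaced
#'   points centred on the agonist-alone EC50, plus a zero point
#' @param noise_cv proportional noise coefficient (SD per unit signal)
#' @param noise_floor additive noise SD in response units
#' @param n_replicates replicate measurements per concentration
#' @param seed integer seed stored with the scenario; generation is
#'   reproducible per seed
#' @param name optional label
#' @return an object of class \code{"omam_scenario"}
#' @examples
#' sc <- omam_scenario(system_params(1), agonist_params(1e-6, 3),
#'                     modulator_params(1e-6, alpha = 10), seed = 1)
#' cs <- simulate_curveset(sc)
#' @export
omam_scenario <- function(sys, ag, mod, b_grid = c(0, 1e-7, 1e-6, 1e-5),
                          a_grid = NULL, noise_cv = 0.05, noise_floor = 0,
                          n_replicates = 3, seed = NULL, name = NULL) {
  stopifnot(inherits(sys, "system_params"), inherits(ag, "agonist_params"),
            inherits(mod, "modulator_params"),
            noise_cv >= 0, noise_floor >= 0, n_replicates >= 1)
  check_conc(b_grid, "modulator grid")
  if (is.null(a_grid)) {
    ctr <- log10(om_ec50(ag))
    a_grid <- c(0, 10^seq(ctr - 2, ctr + 2, by = 0.5))
  }
  check_conc(a_grid, "agonist grid")
  if (length(a_grid) == 0 || length(b_grid) == 0)
    stop("concentration grids must be non-empty", call. = FALSE)
  structure(list(sys = sys, ag = ag, mod = mod, b_grid = sort(b_grid),
                 a_grid = sort(a_grid), noise_cv = noise_cv,
                 noise_floor = noise_floor,
                 n_replicates = as.integer(n_replicates),
                 seed = seed, name = name),
            class = "omam_scenario")
}

#' @export
print.omam_scenario <- function(x, ...) {
  cat("Scenario", if (!is.null(x$name)) sQuote(x$name) else "", "\n")
  print(x$sys); print(x$ag); print(x$mod)
  cat(sprintf("  %d modulator arm(s), %d agonist concentrations, %d replicate(s), noise_cv = %g\n",
              length(x$b_grid), length(x$a_grid), x$n_replicates, x$noise_cv))
  invisible(x)
}

add_noise <- function(mu, noise_cv, noise_floor) {
  sd <- noise_floor + noise_cv * abs(mu)
  mu + stats::rnorm(length(mu), 0, sd)
}

#' @rdname omam_scenario
#' @param scenario an \code{omam_scenario}
#' @details \code{simulate_curveset()} draws a full curve family (one curve
#'   per modulator concentration) from the allosteric forward model plus
#'   noise; the true scenario is attached as \code{attr(, "truth")}.
#' @export
simulate_curveset <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "omam_scenario"))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (j in seq_along(scenario$b_grid)) {
    bj <- scenario$b_grid[j]
    mu <- omam_response(scenario$a_grid, bj, scenario$sys, scenario$ag,
                        scenario$mod)
    sd_j <- scenario$noise_floor + scenario$noise_cv * abs(mu)
    for (r in seq_len(scenario$n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        curve_id = sprintf("B%02d", j),
        modulator_conc_M = bj,
        agonist_conc_M = scenario$a_grid,
        response = add_noise(mu, scenario$noise_cv, scenario$noise_floor),
        sd = sd_j,
        replicate = r)
    }
  }
  out <- as_curveset(do.call(rbind, rows))
  attr(out, "truth") <- scenario
  out
}

#' @rdname omam_scenario
#' @details \code{simulate_modulator_alone()} titrates the allosteric
#'   ligand with no orthosteric agonist present (the design that determines
#'   its own \code{k_b} and \code{tau_b} functionally).
#' @export
simulate_modulator_alone <- function(scenario, b_grid = NULL,
                                     seed = scenario$seed) {
  stopifnot(inherits(scenario, "omam_scenario"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(b_grid)) {
    ctr <- log10(scenario$mod$k_b)
    b_grid <- c(0, 10^seq(ctr - 2.5, ctr + 2.5, by = 0.5))
  }
  mu <- allosteric_agonist_response(b_grid, scenario$sys, scenario$mod)
  sd_b <- scenario$noise_floor + scenario$noise_cv * abs(mu)
  out <- do.call(rbind, lapply(seq_len(scenario$n_replicates), function(r)
    data.frame(conc = b_grid,
               response = add_noise(mu, scenario$noise_cv,
                                    scenario$noise_floor),
               sd = sd_b,
               replicate = r)))
  attr(out, "truth") <- scenario
  out
}

#' Synthetic radioligand-binding tables
#'
#' Generates noisy binding tables for the designs used to predetermine
#' binding constants: saturation of the tracer, two-site agonist
#' competition, allosteric shift of tracer binding by a titrated modulator
#' (optionally in the presence of a fixed agonist concentration).  The
#' tracer is present at 1 nM by default.  Noise is additive Gaussian as in
#' [simulate_curveset()].
#'
#' @param type design to simulate
#' @param x titrated ligand concentrations, molar
#' @param tracer a [tracer_params()] object
#' @param b_max,k_d saturation parameters (\code{type = "saturation"}
#'   titrates the tracer itself, so \code{x} is tracer concentration)
#' @param ic50_high,ic50_low,f_low two-site competition parameters
#' @param k_b,alpha_tracer allosteric-shift parameters
#' @param a,k_a,alpha_agonist fixed-agonist arm of the allosteric design
#' @param noise_sd additive noise SD, in the output units
#' @param n_replicates replicates per concentration
#' @param seed integer seed
#' @return a binding-table data frame (columns \code{ligand_conc_M},
#'   \code{binding_pct}, \code{replicate}; plus \code{agonist_conc_M} for
#'   the fixed-agonist design) with \code{attr(, "truth")}
#' @export
simulate_binding <- function(type = c("competition", "saturation",
                                      "allosteric", "allosteric_agonist"),
                             x, tracer = tracer_params(1e-9, 5e-10),
                             b_max = 100, k_d = 5e-10,
                             ic50_high = 1e-8, ic50_low = 1e-6, f_low = 50,
                             k_b = 5e-7, alpha_tracer = 0.3,
                             a = 1e-6, k_a = 1e-6, alpha_agonist = 1,
                             noise_sd = 0, n_replicates = 1, seed = NULL) {
  type <- match.arg(type)
  check_conc(x, "ligand concentration")
  if (!is.null(seed)) set.seed(seed)
  mu <- switch(type,
    saturation = saturation_binding(x, b_max, k_d),
    competition = two_site_competition(x, ic50_high, ic50_low, f_low),
    allosteric = tracer_binding_shift(x, tracer, k_b, alpha_tracer),
    allosteric_agonist = tracer_binding_shift_with_agonist(
      x, a, tracer, k_a, k_b, alpha_tracer, alpha_agonist))
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    d <- data.frame(ligand_conc_M = x,
                    binding_pct = mu + stats::rnorm(length(mu), 0, noise_sd),
                    replicate = r)
    if (type == "allosteric_agonist") d$agonist_conc_M <- a
    d
  }))
  attr(out, "truth") <- mget(c("type", "b_max", "k_d", "ic50_high",
                               "ic50_low", "f_low", "k_b", "alpha_tracer",
                               "a", "k_a", "alpha_agonist"))
  out
}

#' Preset modulation scenarios
#'
#' Named scenarios covering the canonical qualitative behaviours of
#' allosteric modulation, all with \code{e_max = 1}, \code{tau_a = 3},
#' \code{k_a = 1e-6} M, \code{k_b = 1e-6} M, and representative
#' cooperativity values (0.1 or 0.3 for negative, 3 or 10 for positive):
#' \describe{
#'   \item{mod_aff_neg / mod_aff_pos}{pure modulator acting on affinity
#'     only (\code{beta = 1}, \code{tau_b = 0}): shifts EC'50, leaves E'MAX}
#'   \item{mod_eff_neg / mod_eff_pos}{pure modulator acting on efficacy
#'     (\code{alpha = 1}, \code{tau_b = 0}): shifts both EC'50 and E'MAX}
#'   \item{mod_pp, mod_pn, mod_np, mod_nn}{combined affinity/efficacy
#'     modulation; first letter is the sign of \code{alpha} cooperativity,
#'     second of \code{beta}}
#'   \item{ago_neutral_low / ago_neutral_high}{pure allosteric agonist
#'     (\code{alpha = beta = 1}) with efficacy below / above the
#'     orthosteric agonist's}
#'   \item{ago_aff_neg / ago_aff_pos}{allosteric agonist (\code{tau_b = 1})
#'     modulating affinity only}
#'   \item{ago_eff_neg / ago_eff_pos}{allosteric agonist modulating
#'     efficacy only}
#'   \item{ago_pp, ago_pn, ago_np, ago_nn}{combined, with intrinsic
#'     activity}
#'   \item{bqca_like}{positive modulator design: arm at 0/30/100/300 uM on
#'     a fold-over-basal response scale}
#'   \item{tbpb_like}{allosteric agonist with negative efficacy
#'     cooperativity: arm at 0/1/3/10 uM, fold-over-basal scale}
#' }
#'
#' @param name preset name; see \code{names(omam_presets())}
#' @return \code{omam_presets()}: named list of [omam_scenario()] objects;
#'   \code{preset_scenario()}: a single scenario
#' @examples
#' names(omam_presets())
#' sc <- preset_scenario("mod_aff_pos")
#' @export
omam_presets <- function() {
  sys1 <- system_params(1)
  ag1 <- agonist_params(k_a = 1e-6, tau_a = 3)
  mk <- function(alpha = 1, beta = 1, tau_b = 0, sys = sys1, ag = ag1,
                 k_b = 1e-6, b_grid = c(0, 1e-7, 1e-6, 1e-5, 1e-4),
                 name = NULL)
    omam_scenario(sys, ag, modulator_params(k_b, alpha, beta, tau_b),
                  b_grid = b_grid, name = name)
  sys98 <- system_params(98, basal = 1)
  list(
    mod_aff_neg = mk(alpha = 0.1, name = "mod_aff_neg"),
    mod_aff_pos = mk(alpha = 10, name = "mod_aff_pos"),
    mod_eff_neg = mk(beta = 0.1, name = "mod_eff_neg"),
    mod_eff_pos = mk(beta = 10, name = "mod_eff_pos"),
    mod_pp = mk(alpha = 10, beta = 3, name = "mod_pp"),
    mod_pn = mk(alpha = 10, beta = 0.3, name = "mod_pn"),
    mod_np = mk(alpha = 0.1, beta = 3, name = "mod_np"),
    mod_nn = mk(alpha = 0.1, beta = 0.3, name = "mod_nn"),
    ago_neutral_low = mk(tau_b = 1, name = "ago_neutral_low"),
    ago_neutral_high = mk(tau_b = 10, name = "ago_neutral_high"),
    ago_aff_neg = mk(alpha = 0.1, tau_b = 1, name = "ago_aff_neg"),
    ago_aff_pos = mk(alpha = 10, tau_b = 1, name = "ago_aff_pos"),
    ago_eff_neg = mk(beta = 0.1, tau_b = 1, name = "ago_eff_neg"),
    ago_eff_pos = mk(beta = 10, tau_b = 1, name = "ago_eff_pos"),
    ago_pp = mk(alpha = 10, beta = 3, tau_b = 1, name = "ago_pp"),
    ago_pn = mk(alpha = 10, beta = 0.3, tau_b = 1, name = "ago_pn"),
    ago_np = mk(alpha = 0.1, beta = 3, tau_b = 1, name = "ago_np"),
    ago_nn = mk(alpha = 0.1, beta = 0.3, tau_b = 1, name = "ago_nn"),
    bqca_like = omam_scenario(
      sys98, agonist_params(k_a = 3.9e-7, tau_a = 10),
      modulator_params(k_b = 5e-5, alpha = 10, beta = 2, tau_b = 0.2),
      b_grid = c(0, 3e-5, 1e-4, 3e-4), name = "bqca_like"),
    tbpb_like = omam_scenario(
      sys98, agonist_params(k_a = 3.9e-7, tau_a = 10),
      modulator_params(k_b = 1.5e-6, alpha = 0.5, beta = 0.3, tau_b = 2),
      b_grid = c(0, 1e-6, 3e-6, 1e-5), name = "tbpb_like"))
}

#' @rdname omam_presets
#' @export
preset_scenario <- function(name) {
  p <- omam_presets()
  if (!name %in% names(p))
    stop("unknown preset ", sQuote(name), "; available: ",
         paste(names(p), collapse = ", "), call. = FALSE)
  p[[name]]
}
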