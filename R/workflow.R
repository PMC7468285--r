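#' Staged estimation of allosteric cooperativity factors
#'
#' Fits the operational model of allosterically-modulated agonism to a
#' family of agonist concentration-response curves (one per fixed
#' allosteric-ligand concentration) while never releasing inter-dependent
#' parameters together.  The stages are:
#' \enumerate{
#'   \item logistic fit of every curve, yielding per-curve EC'50 and E'MAX;
#'   \item determination of the allosteric ligand's own constants
#'     (\code{k_b}, \code{tau_b}) from a ligand-alone titration with
#'     \code{e_max} fixed -- skipped when both are supplied as
#'     predetermined values;
#'   \item operational cooperativity \code{beta} by closed-form inversion
#'     of the apparent-maximum relation: from the saturating-limit form if
#'     the two highest modulator concentrations produce statistically
#'     indistinguishable E'MAX (two-sided z-test, threshold
#'     \code{saturation_p}), otherwise from the finite-concentration form;
#'   \item binding cooperativity \code{alpha} by closed-form inversion of
#'     the dose-ratio relation at each modulator concentration (geometric
#'     mean across concentrations);
#'   \item a global fit of the full forward model across all curves with
#'     \code{e_max}, \code{basal}, \code{k_a}, \code{tau_a}, \code{k_b} and
#'     \code{tau_b} fixed and only \code{alpha} and \code{beta} free,
#'     initialized at the stage-3/4 values, providing standard errors and
#'     confidence intervals.
#' }
#' The final fit refuses to run with more than \code{max_free} free forward
#' -model parameters (default 2) unless overridden: releasing the
#' inter-dependent constants is precisely the failure mode the staging
#' avoids.
#'
#' @param curves a [as_curveset()] data frame: the agonist titrations at
#'   each fixed modulator concentration, including a modulator-free curve
#' @param sys predetermined [system_params()] (system maximum and basal,
#'   e.g. from [fit_om_two_step()])
#' @param ag predetermined [agonist_params()] for the orthosteric agonist
#' @param k_b,tau_b predetermined allosteric-ligand constants; leave
#'   \code{NULL} to estimate them from \code{modulator_curve}
#' @param modulator_curve optional data frame (\code{conc},
#'   \code{response}) of the allosteric ligand titrated alone; required
#'   when \code{k_b} or \code{tau_b} is not supplied
#' @param saturation_p p-value threshold of the saturation z-test
#'   (stage 3); larger values make the saturating-limit inversion easier to
#'   accept
#' @param fix_n_h fix the Hill coefficient of stage-1 logistic fits
#'   (default 1; \code{NULL} fits it freely)
#' @param also_free character vector of normally-fixed parameters to
#'   release in stage 5 in addition to the cooperativity factors; the call
#'   is refused (see \code{max_free}) unless the tolerance is raised
#'   explicitly, because the released constants are inter-dependent with
#'   them
#' @param max_free maximum number of free parameters tolerated in stage 5
#' @return an object of class \code{"omam_workflow"}; key elements:
#'   \code{estimates} (alpha, beta with standard errors),
#'   \code{stage1} (per-curve logistic summaries), \code{stage2} (ligand
#'   fit, if run), \code{beta_init}, \code{alpha_init}, \code{saturated},
#'   \code{final} (the stage-5 \code{global_fit}), \code{provenance}
#'   (origin of every parameter)
#' @examples
#' sc <- preset_scenario("mod_aff_pos"); sc$noise_cv <- 0.02
#' cs <- simulate_curveset(sc, seed = 42)
#' wf <- run_omam_workflow(cs, sys = sc$sys, ag = sc$ag,
#'                         k_b = sc$mod$k_b, tau_b = 0)
#' coef(wf)[c("alpha", "beta")]
#' @export
run_omam_workflow <- function(curves, sys, ag, k_b = NULL, tau_b = NULL,
                              modulator_curve = NULL, saturation_p = 0.05,
                              fix_n_h = 1, also_free = character(0),
                              max_free = 2) {
  stopifnot(inherits(sys, "system_params"), inherits(ag, "agonist_params"))
  curves <- as_curveset(as.data.frame(curves))
  parts <- split_curves(curves)
  b_conc <- vapply(parts, function(d) d$modulator_conc_M[1], 0)
  if (!any(b_conc == 0))
    stop("a modulator-free control curve (modulator_conc_M = 0) is required",
         call. = FALSE)
  if (sum(b_conc > 0) < 1L)
    stop("at least one curve with modulator present is required",
         call. = FALSE)

  provenance <- list(
    e_max = "fixed-from-config", basal = "fixed-from-config",
    k_a = "fixed-from-config", tau_a = "fixed-from-config")

  # stage 1: logistic fit per curve
  wts <- function(d) if ("sd" %in% names(d)) sd_weights(d$sd) else NULL
  lfits <- lapply(parts, function(d)
    fit_logistic(d$agonist_conc_M, d$response, weights = wts(d),
                 fix_n_h = fix_n_h))
  ok <- vapply(lfits, function(f) f$converged && f$identifiable, TRUE)
  if (!ok[[which(b_conc == 0)[1]]])
    stop("stage 1: logistic fit failed for the modulator-free control curve",
         call. = FALSE)
  # a modulator-present curve flattened into the noise (e.g. a strong
  # allosteric agonist with negative operational cooperativity) carries no
  # usable EC'50; it is dropped from the closed-form stages but still
  # contributes its raw points to the stage-5 global fit
  if (!all(ok))
    warning("stage 1: curve(s) ", paste(names(parts)[!ok], collapse = ", "),
            " too flat for logistic description; excluded from the ",
            "closed-form stages", call. = FALSE)

  g1 <- function(fn) vapply(lfits, function(f)
    if (f$converged && f$identifiable) fn(f) else NA_real_, 0)
  stage1 <- data.frame(
    curve_id = names(parts), b_conc = b_conc, usable = ok,
    ec50 = g1(function(f) unname(f$estimates[["ec50"]])),
    ec50_se = g1(function(f) unname(f$std_errors[["ec50"]])),
    # upper asymptote above the SYSTEM basal: the fitted curve baseline is
    # left free to absorb the allosteric ligand's own activity and must not
    # be subtracted here
    e_max_obs = g1(function(f)
      unname(f$estimates[["e_max_obs"]]) - sys$basal),
    e_max_obs_se = g1(function(f) unname(f$std_errors[["e_max_obs"]])),
    row.names = NULL)

  # stage 2: allosteric ligand's own constants
  stage2 <- NULL
  if (is.null(k_b) || is.null(tau_b)) {
    if (is.null(modulator_curve))
      stop("k_b/tau_b not supplied: provide a modulator_curve ",
           "(ligand-alone titration) to determine them", call. = FALSE)
    stage2 <- fit_allosteric_agonist(modulator_curve$conc,
                                     modulator_curve$response, sys,
                                     weights = wts(modulator_curve))
    if (!stage2$converged)
      stop("stage 2: ligand-alone fit did not converge; a flat trace has ",
           "no k_b information -- supply k_b (e.g. from binding) and ",
           "tau_b = 0 instead", call. = FALSE)
    if (is.null(k_b)) {
      k_b <- unname(stage2$estimates[["k_b"]])
      provenance$k_b <- "fixed-from-functional"
    } else provenance$k_b <- "fixed-from-config"
    if (is.null(tau_b)) {
      tau_b <- unname(stage2$estimates[["tau_b"]])
      provenance$tau_b <- "fixed-from-functional"
    } else provenance$tau_b <- "fixed-from-config"
  } else {
    provenance$k_b <- "fixed-from-config"
    provenance$tau_b <- "fixed-from-config"
  }

  base_i <- which(b_conc == 0)[1]
  mod_i <- which(b_conc > 0 & ok)
  top2 <- mod_i[order(b_conc[mod_i], decreasing = TRUE)][seq_len(min(2, length(mod_i)))]

  # stage 3: saturation test, then beta by closed-form inversion
  saturated <- TRUE
  if (length(top2) == 2L) {
    d_e <- stage1$e_max_obs[top2[1]] - stage1$e_max_obs[top2[2]]
    se_e <- sqrt(sum(stage1$e_max_obs_se[top2]^2))
    z <- if (se_e > 0) abs(d_e) / se_e else Inf
    saturated <- 2 * stats::pnorm(-z) > saturation_p
  }

  if (length(mod_i) == 0L) {
    # no modulator-present curve survived stage 1: neutral starting values
    alpha_j <- NA_real_
    alpha_init <- 1
    beta_init <- 1
  } else {
    top_i <- top2[1]
    e_top <- min(stage1$e_max_obs[top_i], sys$e_max * 0.999)

    # stage 4 prerequisite inputs: dose ratios from stage 1; inversion is
    # attempted per concentration -- noise can push an individual low-[B]
    # point outside the invertible domain without spoiling the rest
    dr <- stage1$ec50[base_i] / stage1$ec50[mod_i]
    e_mod <- pmin(stage1$e_max_obs[mod_i], sys$e_max * 0.999)
    alpha_j <- vapply(seq_along(mod_i), function(j)
      tryCatch(alpha_from_dose_ratio(dr[j], e_mod[j], stage1$b_conc[mod_i][j],
                                     sys, ag, k_b = k_b, tau_b = tau_b),
               error = function(e) NA_real_), 0)
    alpha_init <- if (all(is.na(alpha_j))) 1 else exp(mean(log(alpha_j),
                                                           na.rm = TRUE))

    beta_init <- if (saturated) {
      beta_from_emax(e_top, sys, ag)
    } else {
      tryCatch(beta_from_emax_at_b(e_top, stage1$b_conc[top_i], alpha_init,
                                   sys, ag, k_b = k_b),
               error = function(e) NA_real_)
    }
    if (!is.finite(beta_init) || beta_init <= 0) beta_init <- 1
  }

  # stage 5: global fit, alpha and beta free only
  fixed <- list(e_max = sys$e_max, basal = sys$basal, k_a = ag$k_a,
                tau_a = ag$tau_a, k_b = k_b, tau_b = tau_b)
  start_extra <- fixed[intersect(also_free, names(fixed))]
  fixed <- fixed[setdiff(names(fixed), also_free)]
  n_free <- 8L - length(fixed)
  if (n_free > max_free)
    stop(sprintf(paste0("stage 5 would have %d free parameters (> max_free",
                        " = %d): the inter-dependent constants must be ",
                        "predetermined"), n_free, max_free), call. = FALSE)
  # small deterministic multistart: the closed-form initial pair plus
  # neutral fallbacks, keeping the best identifiable fit (ties by RSS)
  starts <- unique(list(
    list(alpha = alpha_init, beta = beta_init),
    list(alpha = 1, beta = 1),
    list(alpha = alpha_init, beta = 1),
    list(alpha = 1, beta = beta_init)))
  final <- NULL
  for (s in starts) {
    cand <- fit_global(curves, model = "omam", fixed = fixed,
                       start = c(s, start_extra))
    if (is.null(final) ||
        (cand$identifiable && !final$identifiable) ||
        (cand$identifiable == final$identifiable && cand$rss < final$rss))
      final <- cand
  }
  provenance$alpha <- "fitted-stage5"
  provenance$beta <- "fitted-stage5"

  est <- data.frame(
    parameter = c("alpha", "beta"),
    initial = c(alpha_init, beta_init),
    estimate = unname(final$estimates[c("alpha", "beta")]),
    std_error = unname(final$std_errors[c("alpha", "beta")]),
    row.names = NULL)

  structure(list(estimates = est, stage1 = stage1, stage2 = stage2,
                 saturated = saturated, alpha_init = alpha_init,
                 beta_init = beta_init, alpha_by_conc = alpha_j,
                 final = final, logistic_fits = lfits,
                 sys = sys, ag = ag, k_b = k_b, tau_b = tau_b,
                 provenance = data.frame(
                   parameter = names(provenance),
                   source = unlist(provenance), row.names = NULL)),
            class = "omam_workflow")
}

#' @export
print.omam_workflow <- function(x, ...) {
  cat("Staged allosteric-modulation workflow\n")
  cat(sprintf("  %d curves; saturation of modulator effect: %s\n",
              nrow(x$stage1), if (x$saturated) "yes" else "no"))
  cat(sprintf("  alpha = %.4g (SE %.3g, init %.4g)\n",
              x$estimates$estimate[1], x$estimates$std_error[1],
              x$estimates$initial[1]))
  cat(sprintf("  beta  = %.4g (SE %.3g, init %.4g)\n",
              x$estimates$estimate[2], x$estimates$std_error[2],
              x$estimates$initial[2]))
  cat(sprintf("  final global fit: RSS = %.4g, identifiable = %s\n",
              x$final$rss, x$final$identifiable))
  invisible(x)
}

#' @export
summary.omam_workflow <- function(object, ...) {
  cat("Per-curve logistic stage:\n")
  print(object$stage1, digits = 4)
  if (!is.null(object$stage2)) {
    cat("\nAllosteric ligand alone (k_b, tau_b):\n")
    print(object$stage2)
  }
  cat("\nParameter provenance:\n")
  print(object$provenance)
  cat("\n")
  print(object)
  invisible(object)
}

#' @export
coef.omam_workflow <- function(object, ...) {
  coef(object$final)
}

#' @export
confint.omam_workflow <- function(object, parm, level = 0.95, ...) {
  if (missing(parm)) confint(object$final, level = level)
  else confint(object$final, parm = parm, level = level)
}

#' @export
plot.omam_workflow <- function(x, ...) {
  plot(x$final, ...)
}
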