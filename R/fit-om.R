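#' Fit the operational model to a single agonist curve
#'
#' Fits the operational-model hyperbola (with additive basal) to one
#' concentration-response curve.  Because the three operational-model
#' constants are inter-dependent (a hyperbola exposes only two observable
#' quantities, EC50 and E'MAX), \code{e_max} must be fixed -- it is passed in
#' through \code{sys} as a predetermined value.  With \code{e_max} fixed the
#' remaining pair (\code{k_a}, \code{tau_a}) is exactly identifiable.
#' Initial values come from a logistic pre-fit via the closed-form
#' inversions \eqn{\tau_A = E'_{MAX}/(E_{MAX}-E'_{MAX})},
#' \eqn{K_A = EC_{50}(\tau_A+1)}.
#'
#' @param conc agonist concentrations, molar
#' @param response measured responses
#' @param sys a [system_params()] object; \code{e_max} (and \code{basal})
#'   are held fixed
#' @param fix_k_a fix the dissociation constant to this molar value (e.g.
#'   predetermined from binding) instead of fitting it
#' @param weights optional per-point weights
#' @return an \code{"om_fit"}/\code{"ls_fit"} object; \code{estimates}
#'   contains \code{k_a} and \code{tau_a}
#' @examples
#' sys <- system_params(1); ag <- agonist_params(1e-6, 3)
#' a <- c(0, 10^seq(-9, -4, 0.5))
#' fit <- fit_om(a, om_response(a, sys, ag), sys)
#' coef(fit)[c("k_a", "tau_a")]
#' @export
fit_om <- function(conc, response, sys, fix_k_a = NULL, weights = NULL) {
  conc <- check_conc(conc, "agonist concentration")
  stopifnot(length(conc) == length(response))

  pre <- fit_logistic(conc, response, weights = weights, fix_n_h = 1,
                      fix_basal = sys$basal)
  if (!pre$converged)
    stop("logistic pre-fit failed: cannot initialize the operational model",
         call. = FALSE)
  e_obs <- unname(pre$estimates[["e_max_obs"]] - sys$basal)
  e_obs <- min(e_obs, sys$e_max * 0.999)
  tau0 <- max(e_obs / (sys$e_max - e_obs), 1e-3)
  k0 <- unname(pre$estimates[["ec50"]]) * (tau0 + 1)

  pars <- list(
    e_max = par_def(sys$e_max, TRUE, "log10"),
    basal = par_def(sys$basal, TRUE, "natural"),
    k_a = if (is.null(fix_k_a)) par_def(k0, FALSE, "log10")
    else par_def(fix_k_a, TRUE, "log10"),
    tau_a = par_def(tau0, FALSE, "log10"))

  predict_fn <- function(v) {
    v[["basal"]] + conc * v[["tau_a"]] * v[["e_max"]] /
      (conc * (v[["tau_a"]] + 1) + v[["k_a"]])
  }

  res <- ls_engine(predict_fn, pars, response, weights)
  class(res) <- c("om_fit", class(res))
  res$data <- data.frame(conc = conc, response = response)
  res$logistic <- pre
  res
}

#' @rdname fit_om
#' @details \code{fit_allosteric_agonist()} fits the same functional form to
#'   the response elicited by an allosteric agonist on its own, yielding its
#'   dissociation constant \code{k_b} and intrinsic operational efficacy
#'   \code{tau_b}.
#' @export
fit_allosteric_agonist <- function(conc, response, sys, weights = NULL) {
  res <- fit_om(conc, response, sys, weights = weights)
  nm <- names(res$estimates)
  nm[nm == "k_a"] <- "k_b"; nm[nm == "tau_a"] <- "tau_b"
  names(res$estimates) <- nm
  res$free <- sub("^k_a$", "k_b", sub("^tau_a$", "tau_b", res$free))
  names(res$std_errors) <- sub("^k_a$", "k_b",
                               sub("^tau_a$", "tau_b", names(res$std_errors)))
  dimnames(res$covariance) <- list(res$free, res$free)
  names(res$scales) <- nm
  class(res) <- c("allosteric_agonist_fit", class(res))
  res
}

#' Two-step determination of operational-model parameters from an agonist
#' batch
#'
#' Implements the staged procedure that avoids fitting the three
#' inter-dependent operational-model constants simultaneously:
#' \enumerate{
#'   \item a logistic curve is fitted to each agonist's data, giving the
#'     observable pair (EC50, E'MAX) per agonist;
#'   \item the linear relation \eqn{E'_{MAX} = E_{MAX}(1 - EC_{50}/K_A)} is
#'     fitted across the batch to determine the system maximum
#'     \eqn{E_{MAX}};
#'   \item each curve is refitted with the operational model holding
#'     \eqn{E_{MAX}} fixed, yielding per-agonist \eqn{K_A} and
#'     \eqn{\tau_A} (an exactly identifiable pair once \eqn{E_{MAX}} is
#'     known).
#' }
#' Step 2 has two modes.  If per-agonist dissociation constants are supplied
#' (\code{k_a}, e.g. inhibition constants from competition binding), they
#' are held fixed and \eqn{E_{MAX}} is the single free parameter --
#' identifiable for any batch.  Without them the relation is fitted with a
#' common \eqn{K_A} (intercept \eqn{E_{MAX}}, slope \eqn{-E_{MAX}/K_A});
#' this is exact only when the batch shares one affinity and is otherwise an
#' approximation, so supplying \code{k_a} is preferred.  A batch must span a
#' range of efficacies: at least 3 agonists are required.
#'
#' @param data data frame with columns \code{agonist}, \code{conc}
#'   (molar) and \code{response} (optional \code{sd})
#' @param k_a optional named numeric vector of predetermined molar
#'   dissociation constants, one per agonist
#' @param basal system basal response (fixed), default 0
#' @param refit_k_a logical; keep \code{k_a} free in step 3 (initialized at
#'   the predetermined value) so the functional estimate can be compared
#'   with the binding value.  Default \code{TRUE}.
#' @return an object of class \code{"om_two_step"}: elements
#'   \code{sys} (fitted [system_params()]), \code{emax_se},
#'   \code{params} (per-agonist data frame with \code{k_a}, \code{tau_a}
#'   and standard errors), \code{logistic_fits}, \code{om_fits},
#'   \code{emax_fit}
#' @examples
#' sys <- system_params(1)
#' ags <- list(w = agonist_params(1e-6, 0.5), m = agonist_params(3e-7, 2),
#'             s = agonist_params(1e-7, 8))
#' a <- c(0, 10^seq(-9.5, -4.5, 0.5))
#' d <- do.call(rbind, lapply(names(ags), function(n)
#'   data.frame(agonist = n, conc = a, response = om_response(a, sys, ags[[n]]))))
#' ts <- fit_om_two_step(d, k_a = sapply(ags, `[[`, "k_a"))
#' ts$sys$e_max   # ~ 1
#' @export
fit_om_two_step <- function(data, k_a = NULL, basal = 0, refit_k_a = TRUE) {
  stopifnot(all(c("agonist", "conc", "response") %in% names(data)))
  agonists <- unique(as.character(data$agonist))
  if (length(agonists) < 3L)
    stop("need at least 3 agonists spanning a range of efficacies: ",
         "the apparent-maximum/EC50 relation is not identifiable from fewer",
         call. = FALSE)
  if (!is.null(k_a)) {
    miss <- setdiff(agonists, names(k_a))
    if (length(miss))
      stop("k_a missing for agonist(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }

  wts <- function(d) if ("sd" %in% names(d)) sd_weights(d$sd) else NULL

  # step 1: logistic fit per agonist
  lfits <- lapply(agonists, function(ai) {
    d <- data[data$agonist == ai, ]
    fit_logistic(d$conc, d$response, weights = wts(d), fix_n_h = 1,
                 fix_basal = basal)
  })
  names(lfits) <- agonists
  bad <- agonists[!vapply(lfits, `[[`, TRUE, "converged")]
  if (length(bad))
    stop("logistic fit failed for agonist(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  ec50 <- vapply(lfits, function(f) unname(f$estimates[["ec50"]]), 0)
  e_obs <- vapply(lfits, function(f)
    unname(f$estimates[["e_max_obs"]]) - basal, 0)

  # step 2: E_MAX from the E'MAX-vs-EC50 relation
  if (!is.null(k_a)) {
    ka_fix <- k_a[agonists]
    pars <- list(e_max = par_def(max(e_obs) * 1.2, FALSE, "log10",
                                 lower = max(e_obs)))
    predict_fn <- function(v) v[["e_max"]] * (1 - ec50 / ka_fix)
    efit <- ls_engine(predict_fn, pars, e_obs)
  } else {
    pars <- list(e_max = par_def(max(e_obs) * 1.2, FALSE, "log10",
                                 lower = max(e_obs)),
                 k_a_common = par_def(max(ec50) * 2, FALSE, "log10"))
    predict_fn <- function(v) v[["e_max"]] * (1 - ec50 / v[["k_a_common"]])
    efit <- ls_engine(predict_fn, pars, e_obs)
  }
  if (!efit$converged)
    stop("step-2 fit of the apparent-maximum/EC50 relation did not converge",
         call. = FALSE)
  e_max_hat <- unname(efit$estimates[["e_max"]])
  sys_hat <- system_params(e_max = e_max_hat, basal = basal)

  # step 3: per-agonist refit with E_MAX fixed
  ofits <- lapply(agonists, function(ai) {
    d <- data[data$agonist == ai, ]
    fk <- if (!refit_k_a && !is.null(k_a)) unname(k_a[ai]) else NULL
    fit_om(d$conc, d$response, sys_hat, fix_k_a = fk, weights = wts(d))
  })
  names(ofits) <- agonists

  params <- data.frame(
    agonist = agonists,
    ec50 = ec50, e_max_obs = e_obs,
    k_a = vapply(ofits, function(f) unname(f$estimates[["k_a"]]), 0),
    k_a_se = vapply(ofits, function(f)
      if ("k_a" %in% f$free) unname(f$std_errors[["k_a"]]) else NA_real_, 0),
    tau_a = vapply(ofits, function(f) unname(f$estimates[["tau_a"]]), 0),
    tau_a_se = vapply(ofits, function(f)
      unname(f$std_errors[["tau_a"]]), 0),
    row.names = NULL)

  structure(list(sys = sys_hat,
                 emax_se = unname(efit$std_errors[["e_max"]]),
                 params = params,
                 logistic_fits = lfits, om_fits = ofits, emax_fit = efit),
            class = "om_two_step")
}

#' @export
print.om_two_step <- function(x, ...) {
  cat("Two-step operational-model fit\n")
  cat(sprintf("  E_MAX = %.4g (SE %.3g), basal = %.4g\n",
              x$sys$e_max, x$emax_se, x$sys$basal))
  print(x$params, digits = 4)
  invisible(x)
}

#' @export
coef.om_two_step <- function(object, ...) {
  c(e_max = object$sys$e_max,
    setNames(object$params$tau_a, paste0("tau_a.", object$params$agonist)),
    setNames(object$params$k_a, paste0("k_a.", object$params$agonist)))
}
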