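#' Fit the empirical logistic curve to one concentration-response dataset
#'
#' First stage of all curve analysis: a four-parameter logistic
#' (basal, E'MAX, EC50, Hill coefficient) is fitted by weighted nonlinear
#' least squares.  EC50 and the Hill coefficient are fitted on the log10
#' scale.  Initial values are the geometric mean of the tested
#' concentrations (EC50), the maximal observed response (E'MAX), the minimal
#' observed response (basal) and 1 (Hill coefficient).
#'
#' @param conc ligand concentrations, molar; a zero concentration is allowed
#'   and anchors the basal level
#' @param response measured responses, same length as \code{conc}
#' @param weights optional per-point weights (e.g. 1/SD^2); default
#'   unweighted
#' @param fix_n_h fix the Hill coefficient to this value (commonly 1)
#'   instead of fitting it; \code{NULL} (default) fits it
#' @param fix_basal fix the lower asymptote instead of fitting it;
#'   \code{NULL} fits it
#' @return an object of classes \code{"logistic_fit"} and \code{"ls_fit"}
#'   with elements \code{estimates} (basal, e_max_obs, ec50, n_h),
#'   \code{std_errors}, \code{rss}, \code{converged}, \code{identifiable}.
#'   A degenerate (flat) dataset returns \code{converged = FALSE} rather
#'   than an error.
#' @examples
#' ag <- agonist_params(1e-6, 3); sys <- system_params(1)
#' a <- c(0, 10^seq(-9, -4, 0.5))
#' fit <- fit_logistic(a, om_response(a, sys, ag))
#' coef(fit)[["ec50"]]   # ~ om_ec50(ag) = 2.5e-7
#' @export
fit_logistic <- function(conc, response, weights = NULL,
                         fix_n_h = NULL, fix_basal = NULL) {
  conc <- check_conc(conc, "concentration")
  stopifnot(length(conc) == length(response), is.numeric(response))
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)

  if (diff(range(response)) == 0) {
    pars <- list(basal = par_def(response[1], TRUE, "natural"),
                 e_max_obs = par_def(response[1], TRUE, "natural"),
                 ec50 = par_def(NA_real_, TRUE, "log10"),
                 n_h = par_def(1, TRUE, "log10"))
    res <- ls_result(c(basal = response[1], e_max_obs = response[1],
                       ec50 = NA_real_, n_h = 1),
                     character(0), setNames(numeric(0), character(0)),
                     matrix(0, 0, 0), 0, length(response),
                     FALSE, FALSE, Inf, "flat data: EC50 unidentifiable",
                     c(basal = "natural", e_max_obs = "natural",
                       ec50 = "log10", n_h = "log10"))
    class(res) <- c("logistic_fit", class(res))
    res$data <- data.frame(conc = conc, response = response)
    return(res)
  }

  pos <- conc[conc > 0]
  start_ec50 <- exp(mean(log(pos)))
  start_emax <- max(response)
  start_basal <- min(response)
  if (start_emax <= start_basal) start_emax <- start_basal + 1e-8

  pars <- list(
    basal = if (is.null(fix_basal))
      par_def(start_basal, FALSE, "natural")
    else par_def(fix_basal, TRUE, "natural"),
    e_max_obs = par_def(start_emax, FALSE, "natural"),
    ec50 = par_def(start_ec50, FALSE, "log10"),
    n_h = if (is.null(fix_n_h)) par_def(1, FALSE, "log10",
                                        lower = 0.1, upper = 10)
    else par_def(fix_n_h, TRUE, "log10"))

  predict_fn <- function(v) {
    xn <- conc^v[["n_h"]]
    v[["basal"]] + (v[["e_max_obs"]] - v[["basal"]]) * xn /
      (xn + v[["ec50"]]^v[["n_h"]])
  }

  res <- ls_engine(predict_fn, pars, response, weights)
  class(res) <- c("logistic_fit", class(res))
  res$data <- data.frame(conc = conc, response = response)
  res
}

#' @export
predict.logistic_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else check_conc(newdata)
  v <- object$estimates
  xn <- conc^v[["n_h"]]
  v[["basal"]] + (v[["e_max_obs"]] - v[["basal"]]) * xn /
    (xn + v[["ec50"]]^v[["n_h"]])
}

#' @export
residuals.logistic_fit <- function(object, ...) {
  object$data$response - predict(object)
}

#' @export
plot.logistic_fit <- function(x, ...) {
  d <- x$data
  pos <- d$conc > 0
  plot(log10(d$conc[pos]), d$response[pos],
       xlab = "log10 [ligand] (M)", ylab = "response", ...)
  if (x$converged) {
    grid_l <- seq(min(log10(d$conc[pos])) - 0.5,
                  max(log10(d$conc[pos])) + 0.5, length.out = 200)
    lines(grid_l, predict(x, 10^grid_l))
  }
  invisible(x)
}
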