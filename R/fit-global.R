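#' Global nonlinear fit of a response model across a curve family
#'
#' Weighted least squares of a forward response model over all points of a
#' curve set, with any subset of parameters held fixed.  This is the engine
#' behind the final stage of the staged workflow (where only the two
#' cooperativity factors remain free) and also the tool for demonstrating
#' why that staging is necessary: releasing the inter-dependent
#' operational-model constants together yields an ill-conditioned fit, which
#' is reported through the \code{identifiable} flag (condition number of the
#' normal matrix > 1e8 or any standard error exceeding 10 times its
#' estimate) instead of being silently returned as converged.
#'
#' Model parameters: \code{e_max}, \code{basal}, \code{k_a}, \code{tau_a},
#' \code{k_b}, \code{alpha}, \code{beta}, \code{tau_b} (the allosteric
#' model), or the subset \code{e_max}, \code{basal}, \code{k_a},
#' \code{tau_a} (single-agonist model, \code{modulator_conc_M} ignored).
#' All positive parameters are fitted on the log10 scale; \code{basal} on
#' the natural scale.
#'
#' @param curves a [as_curveset()] data frame
#' @param model \code{"omam"} (agonist + allosteric ligand) or \code{"om"}
#' @param fixed named list of parameters to hold fixed at the given values
#' @param start named list of starting values for free parameters; defaults
#'   are derived from the data (and are deliberately naive -- the staged
#'   workflow exists to provide good ones)
#' @param weights optional per-point weights aligned with \code{curves}
#'   rows; if absent and an \code{sd} column is present, \code{1/sd^2} is
#'   used
#' @return a \code{"global_fit"}/\code{"ls_fit"} object
#' @examples
#' sys <- system_params(1); ag <- agonist_params(1e-6, 3)
#' mod <- modulator_params(1e-6, alpha = 10, beta = 2, tau_b = 0)
#' sc <- omam_scenario(sys, ag, mod, b_grid = c(0, 1e-6, 1e-5),
#'                     noise_cv = 0, n_replicates = 1, seed = 1)
#' cs <- simulate_curveset(sc)
#' f <- fit_global(cs, fixed = list(e_max = 1, basal = 0, k_a = 1e-6,
#'                                  tau_a = 3, k_b = 1e-6, tau_b = 0),
#'                 start = list(alpha = 3, beta = 1))
#' coef(f)[c("alpha", "beta")]
#' @export
fit_global <- function(curves, model = c("omam", "om"), fixed = list(),
                       start = list(), weights = NULL) {
  model <- match.arg(model)
  curves <- as_curveset(as.data.frame(curves))
  a <- curves$agonist_conc_M
  b <- curves$modulator_conc_M
  y <- curves$response
  if (is.null(weights) && "sd" %in% names(curves))
    weights <- sd_weights(curves$sd)

  par_names <- if (model == "omam")
    c("e_max", "basal", "k_a", "tau_a", "k_b", "alpha", "beta", "tau_b")
  else c("e_max", "basal", "k_a", "tau_a")
  bad <- setdiff(names(fixed), par_names)
  if (length(bad))
    stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  # naive data-driven defaults for free parameters without explicit starts
  pos_a <- a[a > 0]
  defaults <- list(
    e_max = max(y) * 1.5, basal = min(y),
    k_a = exp(mean(log(pos_a))), tau_a = 2,
    k_b = if (any(b > 0)) exp(mean(log(b[b > 0]))) else 1e-6,
    alpha = 1, beta = 1, tau_b = 0.1)

  pars <- lapply(par_names, function(nm) {
    if (nm %in% names(fixed))
      par_def(fixed[[nm]], TRUE, if (nm == "basal") "natural" else "log10")
    else {
      v <- if (nm %in% names(start)) start[[nm]] else defaults[[nm]]
      par_def(v, FALSE, if (nm == "basal") "natural" else "log10")
    }
  })
  names(pars) <- par_names

  predict_fn <- if (model == "omam") {
    function(v) {
      kb_ab <- v[["k_b"]] + v[["alpha"]] * v[["beta"]] * b
      num <- v[["e_max"]] * (v[["tau_a"]] * a * kb_ab +
                               v[["tau_b"]] * b * v[["k_a"]])
      den <- a * v[["k_b"]] + v[["k_a"]] * v[["k_b"]] + b * v[["k_a"]] +
        v[["alpha"]] * a * b + v[["tau_a"]] * a * kb_ab +
        v[["tau_b"]] * b * v[["k_a"]]
      v[["basal"]] + num / den
    }
  } else {
    function(v) {
      v[["basal"]] + a * v[["tau_a"]] * v[["e_max"]] /
        (a * (v[["tau_a"]] + 1) + v[["k_a"]])
    }
  }

  res <- ls_engine(predict_fn, pars, y, weights)
  class(res) <- c("global_fit", class(res))
  res$model <- model
  res$data <- curves
  res
}

#' @export
predict.global_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data else newdata
  v <- object$estimates
  a <- d$agonist_conc_M
  if (object$model == "omam") {
    b <- d$modulator_conc_M
    kb_ab <- v[["k_b"]] + v[["alpha"]] * v[["beta"]] * b
    num <- v[["e_max"]] * (v[["tau_a"]] * a * kb_ab +
                             v[["tau_b"]] * b * v[["k_a"]])
    den <- a * v[["k_b"]] + v[["k_a"]] * v[["k_b"]] + b * v[["k_a"]] +
      v[["alpha"]] * a * b + v[["tau_a"]] * a * kb_ab +
      v[["tau_b"]] * b * v[["k_a"]]
    v[["basal"]] + num / den
  } else {
    v[["basal"]] + a * v[["tau_a"]] * v[["e_max"]] /
      (a * (v[["tau_a"]] + 1) + v[["k_a"]])
  }
}

#' @export
residuals.global_fit <- function(object, ...) {
  object$data$response - predict(object)
}

#' @export
confint.global_fit <- function(object, parm, level = 0.95, ...) {
  ci <- ls_confint(object, level)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
plot.global_fit <- function(x, ...) {
  d <- x$data
  pos <- d$agonist_conc_M > 0
  ids <- unique(d$curve_id)
  cols <- seq_along(ids)
  names(cols) <- ids
  plot(log10(d$agonist_conc_M[pos]), d$response[pos],
       col = cols[as.character(d$curve_id[pos])],
       xlab = "log10 [agonist] (M)", ylab = "response", ...)
  la <- seq(min(log10(d$agonist_conc_M[pos])) - 0.5,
            max(log10(d$agonist_conc_M[pos])) + 0.5, length.out = 120)
  for (id in ids) {
    bvals <- unique(d$modulator_conc_M[d$curve_id == id])
    nd <- data.frame(agonist_conc_M = 10^la, modulator_conc_M = bvals[1])
    lines(la, predict(x, nd), col = cols[id])
  }
  legend("topleft", legend = ids, col = cols, lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
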