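#' Fit radioligand-binding models
#'
#' Nonlinear least-squares fits of the equilibrium binding curves, used to
#' predetermine dissociation constants before any functional fitting.
#' `fit_binding_competition()` fits the competition curve and, with
#' \code{model = "auto"}, chooses between the one-site and two-site forms by
#' corrected AIC: the two-site model is kept only if it improves AICc by at
#' least \code{aicc_margin}.  `fit_binding_saturation()` fits the one-site
#' saturation hyperbola.  `fit_binding_allosteric()` fits the allosteric
#' tracer-shift curve for \code{k_b} and the tracer-modulator cooperativity;
#' `fit_binding_allosteric_agonist()` fits the fixed-agonist arm for the
#' agonist-modulator cooperativity with \code{k_b} and the tracer
#' cooperativity held at values predetermined from the agonist-free arm.
#'
#' @param x titrated ligand concentrations, molar
#' @param y specific binding, per cent of control (competition/allosteric
#'   models) or raw units (saturation)
#' @param model \code{"auto"}, \code{"one_site"} or \code{"two_site"}
#' @param aicc_margin AICc improvement required to accept the two-site
#'   model over the one-site model (default 2)
#' @param weights optional per-point weights
#' @return a \code{"binding_fit"}/\code{"ls_fit"} object; competition fits
#'   carry \code{$model_choice} and \code{$aicc}
#' @examples
#' x <- 10^seq(-10, -4, 0.5)
#' y <- two_site_competition(x, 1e-8, 1e-6, 40)
#' f <- fit_binding_competition(x, y)
#' f$model_choice   # "two_site"
#' @export
fit_binding_competition <- function(x, y, model = c("auto", "one_site",
                                                    "two_site"),
                                    aicc_margin = 2, weights = NULL) {
  model <- match.arg(model)
  x <- check_conc(x, "competitor concentration")
  pos <- x[x > 0]
  start_ic <- exp(mean(log(pos)))

  fit_one <- function() {
    pars <- list(ic50 = par_def(start_ic, FALSE, "log10"))
    ls_engine(function(v) 100 - 100 * x / (x + v[["ic50"]]), pars, y, weights)
  }
  fit_two <- function() {
    pars <- list(
      ic50_high = par_def(start_ic / 30, FALSE, "log10"),
      ic50_low = par_def(start_ic * 30, FALSE, "log10"),
      f_low = par_def(50, FALSE, "natural", lower = 0, upper = 100))
    ls_engine(function(v)
      100 - (100 - v[["f_low"]]) * x / (x + v[["ic50_high"]]) -
        v[["f_low"]] * x / (x + v[["ic50_low"]]),
      pars, y, weights)
  }

  if (model == "one_site") {
    res <- fit_one(); res$model_choice <- "one_site"
  } else if (model == "two_site") {
    res <- fit_two(); res$model_choice <- "two_site"
  } else {
    f1 <- fit_one(); f2 <- fit_two()
    a1 <- aicc(f1); a2 <- aicc(f2)
    if (f2$converged && is.finite(a2) && a2 + aicc_margin < a1) {
      res <- f2; res$model_choice <- "two_site"
    } else {
      res <- f1; res$model_choice <- "one_site"
    }
    res$aicc <- c(one_site = a1, two_site = a2)
  }
  res$data <- data.frame(conc = x, binding = y)
  class(res) <- c("binding_fit", class(res))
  res
}

# corrected Akaike information criterion from a Gaussian least-squares fit
aicc <- function(fit) {
  n <- fit$n_obs; k <- length(fit$free) + 1  # + residual variance
  if (n - k - 1 <= 0) return(Inf)
  rss <- max(fit$rss, 1e-300)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname fit_binding_competition
#' @export
fit_binding_saturation <- function(x, y, weights = NULL) {
  x <- check_conc(x, "tracer concentration")
  pars <- list(b_max = par_def(max(y) * 1.5, FALSE, "log10"),
               k_d = par_def(exp(mean(log(x[x > 0]))), FALSE, "log10"))
  res <- ls_engine(function(v) v[["b_max"]] * x / (x + v[["k_d"]]),
                   pars, y, weights)
  res$data <- data.frame(conc = x, binding = y)
  class(res) <- c("binding_fit", class(res))
  res
}

#' @rdname fit_binding_competition
#' @param tracer a [tracer_params()] object (concentration and K_D of the
#'   tracer are known from its saturation fit, not re-estimated here)
#' @export
fit_binding_allosteric <- function(x, y, tracer, weights = NULL) {
  x <- check_conc(x, "modulator concentration")
  pars <- list(
    k_b = par_def(exp(mean(log(x[x > 0]))), FALSE, "log10"),
    alpha_tracer = par_def(0.5, FALSE, "log10"))
  res <- ls_engine(function(v)
    100 * (tracer$d_conc + tracer$k_d) /
      (tracer$d_conc + tracer$k_d * (v[["k_b"]] + x) /
         (v[["k_b"]] + x * v[["alpha_tracer"]])),
    pars, y, weights)
  res$data <- data.frame(conc = x, binding = y)
  class(res) <- c("binding_fit", class(res))
  res
}

#' @rdname fit_binding_competition
#' @param b modulator concentrations, molar (titrated variable)
#' @param a fixed agonist concentration, molar
#' @param k_a agonist equilibrium dissociation constant, molar (from
#'   competition binding)
#' @param k_b,alpha_tracer values predetermined by
#'   \code{fit_binding_allosteric()} on the agonist-free arm
#' @export
fit_binding_allosteric_agonist <- function(b, y, a, tracer, k_a, k_b,
                                           alpha_tracer, weights = NULL) {
  b <- check_conc(b, "modulator concentration")
  pars <- list(alpha_agonist = par_def(1, FALSE, "log10"))
  res <- ls_engine(function(v)
    tracer_binding_shift_with_agonist(b, a, tracer, k_a, k_b,
                                      alpha_tracer, v[["alpha_agonist"]]),
    pars, y, weights)
  res$data <- data.frame(conc = b, binding = y)
  class(res) <- c("binding_fit", class(res))
  res
}

#' @export
plot.binding_fit <- function(x, ...) {
  d <- x$data
  pos <- d$conc > 0
  plot(log10(d$conc[pos]), d$binding[pos],
       xlab = "log10 [ligand] (M)", ylab = "binding", ...)
  invisible(x)
}
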