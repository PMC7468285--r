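# Internal weighted least-squares engine.
#
# All fitting in the package funnels through ls_engine(): Levenberg-Marquardt
# (minpack.lm::nls.lm) on transformed parameters.  Strictly positive
# parameters (concentrations, dissociation constants, efficacies,
# cooperativity factors, Hill coefficients) are fitted as log10 values with
# bounds of +/- 8 log units around the start; response-scale parameters
# (basal, maxima) are fitted on the natural scale.  Standard errors come from
# the linearized covariance s^2 (J'WJ)^-1 with delta-method back-transform
# for log-scale parameters.  Ill-conditioning of J'WJ is reported rather
# than hidden: an `identifiable` flag turns off when the condition number
# exceeds 1e8 or any SE exceeds 10x its estimate -- the expected outcome when
# inter-dependent operational-model parameters are left free together.

# weights from reported per-point SDs: 1/SD^2, with zero SDs (e.g. the
# zero-concentration anchor of a proportional-noise model) floored to the
# smallest positive SD; returns NULL when no usable SDs are present
sd_weights <- function(sd) {
  if (is.null(sd) || !any(is.finite(sd) & sd > 0)) return(NULL)
  floor_sd <- min(sd[is.finite(sd) & sd > 0])
  1 / pmax(sd, floor_sd)^2
}

# par_def(): one row of the parameter table.
par_def <- function(value, fixed = FALSE, scale = c("log10", "natural"),
                    lower = NA_real_, upper = NA_real_) {
  scale <- match.arg(scale)
  list(value = value, fixed = fixed, scale = scale, lower = lower, upper = upper)
}

.transform <- function(v, scale) if (scale == "log10") log10(v) else v
.untransform <- function(t, scale) if (scale == "log10") 10^t else t

ls_engine <- function(predict_fn, pars, y, weights = NULL,
                      max_se_ratio = 10, max_condition = 1e8) {
  stopifnot(is.list(pars), length(pars) > 0, is.numeric(y))
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  sw <- sqrt(weights)

  free <- names(pars)[!vapply(pars, `[[`, TRUE, "fixed")]
  fixed_vals <- vapply(pars[setdiff(names(pars), free)], `[[`, 0, "value")

  assemble <- function(tfree) {
    v <- numeric(length(pars)); names(v) <- names(pars)
    for (nm in names(pars)) {
      v[nm] <- if (nm %in% free)
        .untransform(tfree[nm], pars[[nm]]$scale)
      else pars[[nm]]$value
    }
    v
  }

  scales <- vapply(pars, `[[`, "", "scale")

  if (length(free) == 0L) {
    fit <- predict_fn(assemble(numeric(0)))
    return(ls_result(assemble(numeric(0)), free, setNames(numeric(0), free),
                     matrix(0, 0, 0), sum((sw * (y - fit))^2), n, TRUE, TRUE,
                     0, "all parameters fixed", scales))
  }

  t0 <- vapply(free, function(nm) .transform(pars[[nm]]$value, pars[[nm]]$scale), 0)
  names(t0) <- free
  lower <- vapply(free, function(nm) {
    p <- pars[[nm]]
    if (!is.na(p$lower)) .transform(p$lower, p$scale)
    else if (p$scale == "log10") t0[nm] - 8 else -Inf
  }, 0)
  upper <- vapply(free, function(nm) {
    p <- pars[[nm]]
    if (!is.na(p$upper)) .transform(p$upper, p$scale)
    else if (p$scale == "log10") t0[nm] + 8 else Inf
  }, 0)

  resid_fn <- function(tfree) {
    names(tfree) <- free
    r <- sw * (y - predict_fn(assemble(tfree)))
    r[!is.finite(r)] <- 1e10
    r
  }

  out <- minpack.lm::nls.lm(
    par = t0, fn = resid_fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      maxiter = 500, ftol = 1e-15, ptol = 1e-15, gtol = 0))

  est_t <- out$par; names(est_t) <- free
  estimates <- assemble(est_t)
  rss <- sum(out$fvec^2)
  p <- length(free)
  s2 <- if (n > p) rss / (n - p) else NA_real_

  # Jacobian of the residual vector at the solution, central differences on
  # the fitting scale (nls.lm's returned J'J is unreliable at gtol stops)
  J <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    h <- 1e-6 * max(1, abs(est_t[j]))
    tp <- est_t; tp[j] <- tp[j] + h
    tm <- est_t; tm[j] <- tm[j] - h
    J[, j] <- (resid_fn(tp) - resid_fn(tm)) / (2 * h)
  }
  sv <- tryCatch(svd(J)$d, error = function(e) rep(NA_real_, p))
  cond <- if (anyNA(sv) || min(sv) <= 0) Inf else (max(sv) / min(sv))^2
  cov_t <- tryCatch({
    ih <- chol2inv(chol(crossprod(J)))
    if (is.na(s2)) ih * 0 else ih * s2
  }, error = function(e) matrix(NA_real_, p, p))
  dimnames(cov_t) <- list(free, free)

  se_t <- sqrt(diag(cov_t))
  # delta method: d(10^t)/dt = ln(10) * 10^t
  se <- vapply(free, function(nm) {
    if (pars[[nm]]$scale == "log10") se_t[nm] * log(10) * estimates[nm]
    else se_t[nm]
  }, 0)
  names(se) <- free

  converged <- out$info %in% 1:4 && all(is.finite(est_t))
  # relative-SE screen on the log-scale (strictly positive) parameters;
  # natural-scale parameters (e.g. basal) may legitimately sit at zero
  logf <- free[vapply(pars[free], function(p) p$scale == "log10", TRUE)]
  ratio <- if (length(logf)) abs(se[logf] / estimates[logf]) else 0
  identifiable <- converged && is.finite(cond) && cond < max_condition &&
    all(is.finite(se)) && all(ratio <= max_se_ratio)

  ls_result(estimates, free, se, cov_t, rss, n, converged, identifiable,
            cond, out$message, scales)
}

ls_result <- function(estimates, free, se, cov_t, rss, n_obs,
                      converged, identifiable, condition, message, scales) {
  structure(list(
    estimates = estimates, free = free, std_errors = se,
    covariance = cov_t,   # on the transformed (fitting) scale
    rss = rss, n_obs = n_obs, df = n_obs - length(free),
    converged = converged, identifiable = identifiable,
    condition = condition, message = message, scales = scales),
    class = "ls_fit")
}

#' @export
print.ls_fit <- function(x, ...) {
  cat("Least-squares fit:", length(x$free), "free parameter(s),",
      x$n_obs, "observations\n")
  tab <- data.frame(estimate = x$estimates[x$free],
                    std_error = x$std_errors[x$free])
  print(tab, digits = 4)
  fixed <- setdiff(names(x$estimates), x$free)
  if (length(fixed))
    cat("fixed:", paste(sprintf("%s = %.4g", fixed, x$estimates[fixed]),
                        collapse = ", "), "\n")
  cat(sprintf("RSS = %.4g  converged = %s  identifiable = %s\n",
              x$rss, x$converged, x$identifiable))
  invisible(x)
}

#' @export
coef.ls_fit <- function(object, ...) object$estimates

# Wald interval on the fitting scale, returned on the natural scale
# (log-scale parameters get log-symmetric intervals).
ls_confint <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- t(vapply(fit$free, function(nm) {
    se_t <- sqrt(fit$covariance[nm, nm])
    est <- unname(fit$estimates[nm])
    if (is.na(se_t)) return(c(NA_real_, NA_real_))
    if (fit$scales[[nm]] == "log10") {
      10^(log10(est) + c(-1, 1) * z * se_t)
    } else {
      est + c(-1, 1) * z * se_t
    }
  }, c(0, 0)))
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), "%")
  out
}
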