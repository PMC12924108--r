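# S3 methods for fitted case-crossover models.

#' @export
print.cc_fit <- function(x, ...) {
  cat("Conditional quasi-Poisson case-crossover fit (",
      x$config$inference, ")\n", sep = "")
  cat("  exposure: ", x$exposure_type, " cyclone days, lags 0..", x$lag,
      "\n", sep = "")
  cat("  strata: ", x$strata[["total"]], " (", x$strata[["informative"]],
      " informative for exposure)\n", sep = "")
  est <- cbind(`log RR` = x$coefficients, x$cri)
  print(round(est, 4))
  invisible(x)
}

#' @export
coef.cc_fit <- function(object, ...) object$coefficients

#' @export
vcov.cc_fit <- function(object, ...) {
  stats::cov(object$beta_draws)
}

#' @export
confint.cc_fit <- function(object, parm, level = 0.95, ...) {
  a <- (1 - level) / 2
  ci <- t(apply(object$beta_draws, 2L, stats::quantile, probs = c(a, 1 - a)))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Summarize a fitted case-crossover model
#'
#' @param object A `cc_fit`.
#' @param ... Unused.
#' @return A `summary.cc_fit`: per-lag table of posterior mean log rate
#'   ratios, equal-tailed 95% credible intervals, percent change per
#'   exposure day, and effective sample sizes; dispersion and RW2 precision.
#' @export
summary.cc_fit <- function(object, ...) {
  tab <- data.frame(
    lag = 0:object$lag,
    mean = unname(object$coefficients),
    lower95 = unname(object$cri[, "lower95"]),
    upper95 = unname(object$cri[, "upper95"]),
    pct_change = unname(100 * (exp(object$coefficients) - 1)),
    ess = unname(round(object$ess))
  )
  structure(list(table = tab, dispersion = object$dispersion,
                 rw2_precision = object$rw2_precision,
                 strata = object$strata, n_obs = object$n_obs,
                 acceptance_rate = object$acceptance_rate,
                 converged = object$converged,
                 inference = object$config$inference),
            class = "summary.cc_fit")
}

#' @export
print.summary.cc_fit <- function(x, ...) {
  cat("Case-crossover distributed-lag estimates (log RR per exposure day)\n")
  print(transform(x$table,
                  mean = round(mean, 4), lower95 = round(lower95, 4),
                  upper95 = round(upper95, 4),
                  pct_change = round(pct_change, 2)),
        row.names = FALSE)
  cat("Pearson dispersion:", round(x$dispersion, 3), "\n")
  if (!is.null(x$rw2_precision)) {
    cat("RW2 temperature precision (posterior mean):",
        signif(x$rw2_precision[["mean"]], 3), "\n")
  }
  cat("Observations:", x$n_obs, "; strata:", x$strata[["total"]],
      "(", x$strata[["informative"]], "informative )\n")
  if (!is.na(x$acceptance_rate)) {
    cat("MH acceptance rate:", round(x$acceptance_rate, 3), "\n")
  }
  if (!x$converged) cat("WARNING: fit flagged as not converged\n")
  invisible(x)
}

#' Fitted within-stratum expected counts
#'
#' Expected deaths per county-month given the stratum totals
#' (`mu = Y_s * p`), at the posterior mode.
#'
#' @param object A `cc_fit`.
#' @param ... Unused.
#' @export
fitted.cc_fit <- function(object, ...) {
  cc_loglik(object$theta_map, object$data, "grad")$mu
}

#' Residuals of a case-crossover fit
#'
#' @param object A `cc_fit`.
#' @param type `"pearson"` (default) or `"response"`.
#' @param ... Unused.
#' @export
residuals.cc_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  r <- object$data$y - mu
  if (type == "pearson") r <- r / sqrt(pmax(mu, .Machine$double.eps))
  r
}

#' Plot distributed-lag percent changes from a fit
#'
#' Point estimates (posterior means) and 95% credible intervals of the
#' percent change in death rates per additional exposure day by months since
#' exposure.
#'
#' @param x A `cc_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cc_fit <- function(x, ...) {
  pct <- 100 * (exp(x$beta_draws) - 1)
  m <- colMeans(pct)
  ci <- apply(pct, 2L, stats::quantile, probs = c(0.025, 0.975))
  lags <- 0:x$lag
  graphics::plot(lags, m, ylim = range(ci, 0), pch = 16,
                 xlab = "Months after exposure",
                 ylab = "Percent change per exposure day", ...)
  graphics::arrows(lags, ci[1L, ], lags, ci[2L, ], angle = 90, code = 3,
                   length = 0.05)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' @export
as.data.frame.cc_fit <- function(x, ...) {
  summary(x)$table
}
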