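# Sensitivity drivers: alternative lag windows, leave-one-state-out,
# acute vs chronic subcauses, and period restriction. Every run reuses the
# base configuration's seed policy so differences reflect data changes, not
# Monte-Carlo noise.

#' Refit the model over a grid of lag windows
#'
#' One full fit per maximum lag `L`; shared-lag effect estimates are
#' tabulated side by side. Failed cells are flagged and the grid continues.
#'
#' @param panel Panel accepted by [cc_prepare()].
#' @param L_values Integer vector of maximum lags to test.
#' @param config Base [model_config()] (its `lag` is overridden per cell).
#' @param R0 Baseline DPM rate passed to [effect_summary()].
#' @param ... Passed to [cc_prepare()].
#' @return Data frame of effect summaries with columns `L` and `status`
#'   prepended; one row per (L, lag) that fitted, one `status = "failed"` row
#'   per failed cell.
#' @export
run_lag_window_grid <- function(panel, L_values, config = model_config(),
                                R0 = 100, ...) {
  rows <- lapply(L_values, function(L) {
    cfg <- config
    cfg$lag <- as.integer(L)
    res <- tryCatch({
      fit <- fit_casecrossover(panel, cfg, ...)
      cbind(L = L, status = "ok", effect_summary(fit, R0),
            stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(L = L, status = paste("failed:", conditionMessage(e)),
                 group = NA, strength_class = NA, lag = NA, pct_mean = NA,
                 pct_lo = NA, pct_hi = NA, dpm_mean = NA, dpm_lo = NA,
                 dpm_hi = NA, label = NA, stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leave-one-state-out influence analysis
#'
#' Refits the model once per omitted state and flags states whose omission
#' moves any lag's posterior mean by more than `influence_frac` of the main
#' fit's credible-interval half-width. A state containing all the exposure
#' makes the reduced fit unidentifiable; its row is marked degenerate.
#'
#' @param panel Panel accepted by [cc_prepare()].
#' @param config Base [model_config()].
#' @param influence_frac Influence threshold as a fraction of the main CrI
#'   half-width (default 0.5).
#' @param ... Passed to [cc_prepare()].
#' @return List: `main` (the all-states `cc_fit`) and `table` (data frame
#'   `omitted_state`, per-lag posterior means, `max_shift_frac`,
#'   `influential`, `degenerate`).
#' @export
leave_one_state_out <- function(panel, config = model_config(),
                                influence_frac = 0.5, ...) {
  states <- sort(unique(panel$counties$state))
  if (length(states) < 2L) stop("need >= 2 states")
  main <- fit_casecrossover(panel, config, ...)
  half <- (main$cri[, "upper95"] - main$cri[, "lower95"]) / 2
  rows <- lapply(states, function(st) {
    keep <- setdiff(states, st)
    res <- tryCatch({
      fit <- fit_subgroup(panel, config, states = keep, ...)
      shift <- abs(coef(fit) - coef(main)) / half
      data.frame(omitted_state = st,
                 t(stats::setNames(coef(fit), paste0("lag", 0:main$lag))),
                 max_shift_frac = max(shift),
                 influential = max(shift) > influence_frac,
                 degenerate = FALSE, stringsAsFactors = FALSE)
    }, error = function(e) {
      out <- data.frame(omitted_state = st,
                        t(stats::setNames(rep(NA_real_, main$lag + 1L),
                                          paste0("lag", 0:main$lag))),
                        max_shift_frac = NA_real_, influential = NA,
                        degenerate = TRUE, stringsAsFactors = FALSE)
      out
    })
    res
  })
  list(main = main, table = do.call(rbind, rows))
}

#' Acute vs chronic subcause fits
#'
#' Separate fits on the acute (overdose) and chronic (substance-use disorder
#' and alcohol-induced organ disease) outcome panels. An empty subclass is
#' skipped with a warning.
#'
#' @param panel Panel accepted by [cc_prepare()].
#' @param config Base [model_config()].
#' @param R0 Baseline DPM rate for the effect summaries.
#' @param ... Passed to [cc_prepare()].
#' @return List with elements `acute` and `chronic`, each either a list
#'   `(fit, summary)` or `NULL` when skipped.
#' @export
run_subcause <- function(panel, config = model_config(), R0 = 100, ...) {
  one <- function(sc) {
    tryCatch({
      fit <- fit_subgroup(panel, config, subclass = sc, ...)
      list(fit = fit, summary = effect_summary(fit, R0, group = sc))
    }, error = function(e) {
      warning("subclass '", sc, "' skipped: ", conditionMessage(e))
      NULL
    })
  }
  list(acute = one("acute"), chronic = one("chronic"))
}

#' Restrict a panel to a later start year
#'
#' Removes all county-months before January of `start_year` from every
#' component (the later-period analogue of an ICD-10-only analysis). The
#' month index keeps the original origin; lag vectors are rebuilt at fit
#' time, so the first months after restriction become incomplete again.
#'
#' @param panel A `storm_panel`-shaped list.
#' @param start_year First calendar year to retain.
#' @return The restricted panel.
#' @export
restrict_period <- function(panel, start_year) {
  y0 <- panel$origin_year
  cut_idx <- month_index(start_year, 1L, y0)
  if (cut_idx > max(panel$exposure$month_index)) {
    stop("restriction removes every county-month")
  }
  out <- panel
  for (nm in c("exposure", "temperature", "deaths")) {
    out[[nm]] <- out[[nm]][out[[nm]]$month_index >= cut_idx, ]
  }
  out$population <- out$population[out$population$year >= start_year - 1L, ]
  if ("config" %in% names(out)) {
    out$config$year_range[1L] <- max(out$config$year_range[1L], start_year)
  }
  out
}
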