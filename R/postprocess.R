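# Post-processing: turn posterior draws of log rate ratios into the reported
# quantities -- percent change per exposure day, additional monthly deaths
# per million (DPM), credible-interval sign classification, subgroup
# contrasts, and the county disadvantage categories.

#' Percent change per additional exposure day from posterior draws
#'
#' Summarises `100 * (exp(beta) - 1)` with the posterior mean and the
#' equal-tailed 95% credible interval.
#'
#' @param beta_draws Numeric vector of posterior draws of a log rate ratio
#'   (>= 1000 finite draws for reported intervals).
#' @return Named numeric `c(mean, lower95, upper95)`, in percent.
#' @export
percent_change <- function(beta_draws) {
  bad <- sum(!is.finite(beta_draws))
  if (bad) stop(bad, " non-finite draw(s)")
  if (length(beta_draws) < 1000L) {
    warning("fewer than 1000 draws; interval endpoints are noisy")
  }
  pct <- 100 * (exp(beta_draws) - 1)
  c(mean = mean(pct),
    lower95 = unname(stats::quantile(pct, 0.025)),
    upper95 = unname(stats::quantile(pct, 0.975)))
}

#' Additional monthly deaths per million population
#'
#' Scales percent-change draws by a baseline age-standardised monthly death
#' rate `R0` (deaths per 1 000 000 per month): each draw times `R0 / 100`.
#'
#' @param percent_draws Draws of the percent change (see [percent_change()]).
#' @param R0 Baseline monthly death rate per 1 000 000 (> 0).
#' @return Named numeric `c(mean, lower95, upper95)` additional DPM.
#' @export
to_dpm <- function(percent_draws, R0) {
  if (!is.numeric(R0) || length(R0) != 1L || R0 <= 0) {
    stop("config error: baseline rate R0 must be a positive scalar")
  }
  d <- percent_draws * R0 / 100
  c(mean = mean(d),
    lower95 = unname(stats::quantile(d, 0.025)),
    upper95 = unname(stats::quantile(d, 0.975)))
}

#' Classify an association by the sign of its credible interval
#'
#' Positive when the interval is entirely non-negative, negative when
#' entirely non-positive, null otherwise.
#'
#' @param lower95,upper95 Interval endpoints (ordered).
#' @return `"positive"`, `"negative"` or `"null"` (vectorised).
#' @export
classify_association <- function(lower95, upper95) {
  if (any(lower95 > upper95)) stop("interval endpoints out of order")
  ifelse(lower95 >= 0, "positive", ifelse(upper95 <= 0, "negative", "null"))
}

#' Effect summary table for a fitted model
#'
#' Per-lag percent change and additional DPM with 95% credible intervals and
#' the interval-sign classification. The DPM scale is proportional to the
#' percent scale at every summarised point (`dpm = pct / 100 * R0`).
#'
#' @param fit A `cc_fit`.
#' @param R0 Baseline age-standardised monthly death rate per 1 000 000
#'   (see [baseline_dpm()]).
#' @param group Optional label recorded in the table.
#' @return Data frame `group`, `strength_class`, `lag`, `pct_mean`, `pct_lo`,
#'   `pct_hi`, `dpm_mean`, `dpm_lo`, `dpm_hi`, `label`.
#' @export
effect_summary <- function(fit, R0, group = "all") {
  rows <- lapply(0:fit$lag, function(l) {
    pct_draws <- 100 * (exp(fit$beta_draws[, l + 1L]) - 1)
    pct <- c(mean = mean(pct_draws),
             lower95 = unname(stats::quantile(pct_draws, 0.025)),
             upper95 = unname(stats::quantile(pct_draws, 0.975)))
    dpm <- pct * R0 / 100  # proportional at every summarised point
    data.frame(group = group, strength_class = fit$exposure_type, lag = l,
               pct_mean = pct[["mean"]], pct_lo = pct[["lower95"]],
               pct_hi = pct[["upper95"]], dpm_mean = dpm[["mean"]],
               dpm_lo = dpm[["lower95"]], dpm_hi = dpm[["upper95"]],
               label = classify_association(pct[["lower95"]],
                                            pct[["upper95"]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Posterior contrast between two subgroup fits
#'
#' Pairs independent posterior draws from two fits (index-aligned after
#' seeding) and summarises the per-lag difference in log rate ratios
#' `delta = beta_A - beta_B` with its equal-tailed 95% credible interval.
#' Separate subgroup fits share no parameters, so independence of the two
#' posteriors is assumed.
#'
#' @param resultA,resultB `cc_fit` objects over the same lags.
#' @param groupA,groupB Labels for the output.
#' @return Data frame `groupA`, `groupB`, `lag`, `delta_mean`, `delta_lo`,
#'   `delta_hi`, `meaningful` (TRUE when the interval excludes 0).
#' @export
subgroup_difference <- function(resultA, resultB, groupA = "A", groupB = "B") {
  if (resultA$lag != resultB$lag) stop("mismatched lag sets")
  nA <- nrow(resultA$beta_draws)
  nB <- nrow(resultB$beta_draws)
  n <- min(nA, nB)
  d <- resultA$beta_draws[seq_len(n), , drop = FALSE] -
    resultB$beta_draws[seq_len(n), , drop = FALSE]
  ci <- apply(d, 2L, stats::quantile, probs = c(0.025, 0.975))
  data.frame(groupA = groupA, groupB = groupB, lag = 0:resultA$lag,
             delta_mean = unname(colMeans(d)), delta_lo = unname(ci[1L, ]),
             delta_hi = unname(ci[2L, ]),
             meaningful = unname(ci[1L, ] > 0 | ci[2L, ] < 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-classify counties by poverty and minority percentage
#'
#' Dichotomises both covariates at their medians over included counties
#' (ties at the median count as low, i.e. "at or below"), then crosses the
#' two flags into four disadvantage categories. Counties missing either
#' covariate are excluded and counted.
#'
#' @param counties Data frame with `county_id`, `poverty_pct`,
#'   `minority_pct`.
#' @param thresholds Optional `c(poverty, minority)` explicit cutpoints
#'   (e.g. published medians) used instead of the empirical medians.
#' @return List: `categories` (data frame `county_id`, `poverty_flag`,
#'   `minority_flag`, `category`), `thresholds`, `counts` (per category),
#'   `n_excluded`.
#' @export
categorize_disadvantage <- function(counties, thresholds = NULL) {
  if (!all(c("poverty_pct", "minority_pct") %in% names(counties))) {
    stop("counties need poverty_pct and minority_pct")
  }
  ok <- is.finite(counties$poverty_pct) & is.finite(counties$minority_pct)
  n_excluded <- sum(!ok)
  if (n_excluded) {
    message(n_excluded, " county(ies) excluded for missing covariates")
  }
  cc <- counties[ok, ]
  if (is.null(thresholds)) {
    thresholds <- c(poverty = stats::median(cc$poverty_pct),
                    minority = stats::median(cc$minority_pct))
  } else {
    thresholds <- stats::setNames(thresholds, c("poverty", "minority"))
  }
  pov <- ifelse(cc$poverty_pct > thresholds[["poverty"]], "high", "low")
  mino <- ifelse(cc$minority_pct > thresholds[["minority"]], "high", "low")
  cat4 <- paste0(pov, "-", mino)
  lv <- c("low-low", "low-high", "high-low", "high-high")
  counts <- stats::setNames(as.integer(table(factor(cat4, levels = lv))), lv)
  list(categories = data.frame(county_id = cc$county_id, poverty_flag = pov,
                               minority_flag = mino, category = cat4,
                               stringsAsFactors = FALSE),
       thresholds = thresholds, counts = counts, n_excluded = n_excluded)
}

#' Baseline age-standardised monthly death rate per million
#'
#' Helper for the DPM translation: for a reference year, computes each
#' county's age-standardised monthly death rate per 1 000 000 (direct
#' standardisation over 15+ age groups with supplied standard weights) and
#' returns the median across counties.
#'
#' @param panel Panel with `deaths` and annual `population` components.
#' @param year Reference calendar year.
#' @param std_weights Named weights over age groups (default: the panel's
#'   total population age distribution in `year`, ages 15+).
#' @return Median county age-standardised monthly deaths per 1 000 000.
#' @export
baseline_dpm <- function(panel, year, std_weights = NULL) {
  ages <- setdiff(age_group_levels(), "<15")
  y0 <- panel$origin_year
  idx <- month_index(year, 1L, y0):month_index(year, 12L, y0)
  d <- panel$deaths[panel$deaths$month_index %in% idx &
                      panel$deaths$age_group %in% ages, ]
  p <- panel$population[panel$population$year == year &
                          panel$population$age_group %in% ages, ]
  if (!nrow(d) || !nrow(p)) stop("reference year outside the panel")
  pop_ca <- stats::aggregate(population ~ county_id + age_group, data = p,
                             FUN = sum)
  if (is.null(std_weights)) {
    tot <- rowsum(pop_ca$population, pop_ca$age_group)
    std_weights <- stats::setNames(as.vector(tot) / sum(tot), rownames(tot))
  }
  dth_ca <- stats::aggregate(deaths ~ county_id + age_group, data = d,
                             FUN = sum)
  m <- merge(pop_ca, dth_ca, all.x = TRUE)
  m$deaths[is.na(m$deaths)] <- 0
  m$rate <- m$deaths / 12 / m$population * 1e6  # monthly per million
  std <- vapply(split(m, m$county_id), function(mc) {
    sum(std_weights[mc$age_group] * mc$rate)
  }, numeric(1))
  stats::median(std)
}
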