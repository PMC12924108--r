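# Synthetic county-month panel generator. Emulates the statistical structure
# the case-crossover analysis assumes -- sparse May-November cyclone exposure
# peaking in September, overdispersed seasonal death counts, a long-term trend
# with a breakpoint, a smooth temperature effect and planted per-lag exposure
# log rate ratios -- so the whole pipeline is testable without restricted
# mortality data.

#' Configuration for the synthetic panel generator
#'
#' The defaults define the package's reference study conditions: a desk-scale
#' panel of 30 counties over 2010-2019 emulating the high-exposure coastal
#' subset of US counties. Rates and effects are on the log scale unless noted.
#'
#' @param n_counties Number of counties (>= 2).
#' @param n_states Number of states the counties are partitioned into.
#' @param year_range Inclusive calendar year pair.
#' @param baseline_monthly_rate Expected deaths per person-month at covariate
#'   baseline (> 0).
#' @param planted_lag_log_rr Numeric vector length L+1: log rate ratio per
#'   additional exposure day at lags 0..L.
#' @param planted_lag_log_rr_by_sex Optional list with elements `female` and
#'   `male` (each length L+1) overriding `planted_lag_log_rr` per sex.
#' @param trend_breakpoint `c(year, month)` of the trend breakpoint.
#' @param trend_slopes `c(pre, post)` log-rate slopes per year around the
#'   breakpoint.
#' @param seasonal_amplitude Amplitude (log scale) of the calendar-month
#'   seasonal cycle in death rates.
#' @param temp_effect_knots Data frame `temp_c`, `effect`: log-rate offsets at
#'   temperature knots, linearly interpolated between (a smooth mild U-shape
#'   by default).
#' @param overdispersion Negative-binomial overdispersion `alpha >= 0`
#'   (variance = mu + alpha * mu^2; 0 gives Poisson counts).
#' @param exposure_rate Expected exposed county-months per county per year.
#' @param hurricane_day_prob Probability an exposed day is hurricane-force
#'   (>= 64 kt) rather than gale-force.
#' @param day_count_p Success probability of the zero-truncated geometric
#'   distribution of exposure days within an exposed month (median 2 days at
#'   the default, long right tail).
#' @param county_effect_sd SD of county-level log-rate random intercepts.
#' @param pop_growth_sd SD of county annual population growth rates around
#'   0.5\% per year.
#' @param seed Integer master seed; each generator stage draws from its own
#'   deterministic substream.
#' @return Object of class `storm_sim_config` (a validated list).
#' @export
sim_config <- function(n_counties = 30L,
                       n_states = 3L,
                       year_range = c(2010L, 2019L),
                       baseline_monthly_rate = 2e-5,
                       planted_lag_log_rr = c(0.05, 0, 0, 0),
                       planted_lag_log_rr_by_sex = NULL,
                       trend_breakpoint = c(2015L, 12L),
                       trend_slopes = c(0.04, 0.10),
                       seasonal_amplitude = 0.10,
                       temp_effect_knots = data.frame(
                         temp_c = c(-5, 10, 20, 32),
                         effect = c(0.06, 0.00, 0.01, 0.07)),
                       overdispersion = 0.2,
                       exposure_rate = 1.5,
                       hurricane_day_prob = 0.045,
                       day_count_p = 0.45,
                       county_effect_sd = 0.2,
                       pop_growth_sd = 0.003,
                       seed = 1L) {
  if (n_counties < 2L) stop("invalid config: n_counties must be >= 2")
  if (n_states < 1L) stop("invalid config: n_states must be >= 1")
  if (baseline_monthly_rate <= 0) stop("invalid config: baseline_monthly_rate must be > 0")
  if (overdispersion < 0) stop("invalid config: overdispersion must be >= 0")
  if (exposure_rate < 0) stop("invalid config: exposure_rate must be >= 0")
  if (length(year_range) != 2L || year_range[2L] < year_range[1L]) {
    stop("invalid config: year_range must be an inclusive year pair")
  }
  L <- length(planted_lag_log_rr) - 1L
  if (L < 0L) stop("invalid config: planted_lag_log_rr must have length >= 1")
  n_months <- (year_range[2L] - year_range[1L] + 1L) * 12L
  if (n_months < L + 2L) stop("invalid config: year_range too short for the lag span")
  if (!is.null(planted_lag_log_rr_by_sex)) {
    stopifnot(is.list(planted_lag_log_rr_by_sex),
              all(c("female", "male") %in% names(planted_lag_log_rr_by_sex)),
              all(lengths(planted_lag_log_rr_by_sex[c("female", "male")]) == L + 1L))
  }
  cfg <- list(
    n_counties = as.integer(n_counties), n_states = as.integer(n_states),
    year_range = as.integer(year_range),
    baseline_monthly_rate = baseline_monthly_rate,
    planted_lag_log_rr = planted_lag_log_rr,
    planted_lag_log_rr_by_sex = planted_lag_log_rr_by_sex,
    trend_breakpoint = as.integer(trend_breakpoint),
    trend_slopes = trend_slopes,
    seasonal_amplitude = seasonal_amplitude,
    temp_effect_knots = temp_effect_knots,
    overdispersion = overdispersion,
    exposure_rate = exposure_rate,
    hurricane_day_prob = hurricane_day_prob,
    day_count_p = day_count_p,
    county_effect_sd = county_effect_sd,
    pop_growth_sd = pop_growth_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "storm_sim_config"
  cfg
}

# fixed demographic structure of the generator: age-group population shares,
# even sex split, and relative death-rate multipliers by age group and sex
# (normalised so the population-weighted mean multiplier is 1)
generator_demography <- function() {
  age <- age_group_levels()
  age_share <- c(0.19, 0.20, 0.20, 0.19, 0.22)
  names(age_share) <- age
  mult_age <- c(`<15` = 0.01, `15-29` = 0.8, `30-44` = 1.3,
                `45-59` = 1.5, `>=60` = 0.7)
  mult_sex <- c(female = 0.6, male = 1.4)
  w <- outer(age_share, c(female = 0.5, male = 0.5))
  m <- outer(mult_age, mult_sex)
  norm <- sum(w * m)
  list(age_share = age_share, sex_share = c(female = 0.5, male = 0.5),
       mult = m / norm,
       cause_share = c(overdose = 0.58, mental_behavioral = 0.17,
                       alcohol_induced = 0.25))
}

#' Generate synthetic counties with adjacency, disadvantage and population
#'
#' Counties are partitioned into states; the adjacency graph is connected,
#' symmetric and irreflexive (a chain plus random within-state edges).
#' Poverty and minority percentages are drawn from right-skewed distributions
#' so their empirical medians split counties roughly 50/50. Annual populations
#' (by age group and sex) are positive for every year.
#'
#' @param config A [sim_config()] object.
#' @return List with `counties` (data frame: `county_id`, `state`,
#'   `poverty_pct`, `minority_pct`), `adjacency` (0/1 matrix) and
#'   `population` (data frame: `county_id`, `year`, `age_group`, `sex`,
#'   `population`).
#' @export
simulate_counties <- function(config) {
  stopifnot(inherits(config, "storm_sim_config"))
  set.seed(stage_seed(config$seed, 1L))
  n <- config$n_counties
  ids <- sprintf("C%04d", seq_len(n))
  states <- sprintf("S%02d", sort(rep_len(seq_len(config$n_states), n)))
  poverty <- pmin(round(stats::rlnorm(n, log(16), 0.45), 1), 60)
  minority <- pmin(round(stats::rlnorm(n, log(18), 0.60), 1), 95)
  adj <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) adj[i, i + 1L] <- adj[i + 1L, i] <- 1L  # chain
  for (s in unique(states)) {                      # extra within-state edges
    members <- which(states == s)
    if (length(members) >= 3L) {
      k <- max(1L, length(members) %/% 3L)
      for (j in seq_len(k)) {
        e <- sample(members, 2L)
        adj[e[1L], e[2L]] <- adj[e[2L], e[1L]] <- 1L
      }
    }
  }
  years <- seq.int(config$year_range[1L], config$year_range[2L])
  base_pop <- exp(stats::runif(n, log(2e4), log(5e5)))
  growth <- stats::rnorm(n, 0.005, config$pop_growth_sd)
  demo <- generator_demography()
  grid <- expand.grid(county = seq_len(n), year = years,
                      age_group = age_group_levels(),
                      sex = c("female", "male"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tot <- base_pop[grid$county] *
    (1 + growth[grid$county])^(grid$year - years[1L])
  pop <- tot * demo$age_share[grid$age_group] * demo$sex_share[grid$sex]
  population <- data.frame(county_id = ids[grid$county], year = grid$year,
                           age_group = grid$age_group, sex = grid$sex,
                           population = pop, stringsAsFactors = FALSE)
  list(counties = data.frame(county_id = ids, state = states,
                             poverty_pct = poverty, minority_pct = minority,
                             stringsAsFactors = FALSE),
       adjacency = adj,
       population = population)
}

#' Generate a synthetic cyclone exposure panel
#'
#' Exposure-day counts per county-month: exposed months fall only in
#' May-November with September modal; per-month day counts follow a
#' zero-truncated geometric capped at days-in-month (median 2 days, long right
#' tail); each exposed day is hurricane-force with a small probability,
#' gale-force otherwise. Every county gets at least one exposed month.
#'
#' @param counties Result of [simulate_counties()].
#' @param config A [sim_config()] object.
#' @return Data frame over the full county-month grid: `county_id`,
#'   `month_index`, `exposure_days_total`, `exposure_days_gale`,
#'   `exposure_days_hurricane`.
#' @export
simulate_exposure <- function(counties, config) {
  stopifnot(inherits(config, "storm_sim_config"))
  set.seed(stage_seed(config$seed, 2L))
  y0 <- config$year_range[1L]
  years <- seq.int(y0, config$year_range[2L])
  n_months <- length(years) * 12L
  ids <- sort(counties$counties$county_id)
  month_w <- c(0.05, 0.09, 0.15, 0.25, 0.32, 0.10, 0.04)  # May..Nov, Sep modal
  grid <- expand.grid(county_id = ids, month_index = seq_len(n_months) - 1L,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$county_id, grid$month_index), ]
  rownames(grid) <- NULL
  total <- gale <- hurr <- integer(nrow(grid))
  # grid is sorted by county then month, so rows are directly addressable
  row_of <- function(cid, idx) {
    (match(cid, ids) - 1L) * n_months + idx + 1L
  }
  exposed <- list()
  for (cid in ids) {
    months_c <- integer(0)
    for (yr in years) {
      k <- min(stats::rpois(1L, config$exposure_rate), 7L)
      if (k > 0L) {
        mos <- sample(5:11, k, prob = month_w)
        months_c <- c(months_c, month_index(yr, unique(mos), y0))
      }
    }
    if (!length(months_c)) {  # every county experiences >= 1 cyclone
      months_c <- month_index(sample(years, 1L), 9L, y0)
    }
    exposed[[cid]] <- sort(unique(months_c))
  }
  all_rows <- unlist(lapply(ids, function(cid) row_of(cid, exposed[[cid]])))
  n_exp <- length(all_rows)
  dmax <- days_in_month(index_year(grid$month_index[all_rows], y0),
                        index_month(grid$month_index[all_rows]))
  d <- pmin(stats::rgeom(n_exp, config$day_count_p) + 1L, dmax)
  h <- stats::rbinom(n_exp, d, config$hurricane_day_prob)
  total[all_rows] <- d
  hurr[all_rows] <- h
  gale[all_rows] <- d - h
  grid$exposure_days_total <- total
  grid$exposure_days_gale <- gale
  grid$exposure_days_hurricane <- hurr
  grid
}

#' Generate a synthetic county-month temperature series
#'
#' County-specific sinusoid (warmest in July) plus Gaussian noise; only the
#' smoothness of the series matters to the random-walk temperature term.
#'
#' @inheritParams simulate_exposure
#' @return Data frame `county_id`, `month_index`, `temp_c`.
#' @export
simulate_temperature <- function(counties, config) {
  stopifnot(inherits(config, "storm_sim_config"))
  set.seed(stage_seed(config$seed, 3L))
  ids <- counties$counties$county_id
  n_months <- (config$year_range[2L] - config$year_range[1L] + 1L) * 12L
  base <- stats::rnorm(length(ids), 18, 4)
  amp <- pmax(stats::rnorm(length(ids), 10, 1.5), 4)
  grid <- expand.grid(county_id = ids, month_index = seq_len(n_months) - 1L,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$county_id, grid$month_index), ]
  rownames(grid) <- NULL
  ci <- match(grid$county_id, ids)
  mo <- index_month(grid$month_index)
  grid$temp_c <- base[ci] + amp[ci] * cos(2 * pi * (mo - 7) / 12) +
    stats::rnorm(nrow(grid), 0, 1)
  grid
}

# piecewise-linear long-term trend in the log rate, kinked at the breakpoint
trend_log_offset <- function(idx, config, origin_year) {
  bp <- month_index(config$trend_breakpoint[1L], config$trend_breakpoint[2L],
                    origin_year)
  pre <- config$trend_slopes[1L] / 12
  post <- config$trend_slopes[2L] / 12
  ifelse(idx <= bp, pre * (idx - bp), post * (idx - bp))
}

# log-mean surface of the generator, evaluated from planted components;
# used both to sample counts and to audit the truth record
generator_log_mean <- function(counties, exposure, temperature, config,
                               county_effects) {
  y0 <- config$year_range[1L]
  demo <- generator_demography()
  L <- length(config$planted_lag_log_rr) - 1L
  # per-sex distributed-lag contribution per county-month
  betas <- list(female = config$planted_lag_log_rr,
                male = config$planted_lag_log_rr)
  if (!is.null(config$planted_lag_log_rr_by_sex)) {
    betas <- config$planted_lag_log_rr_by_sex[c("female", "male")]
  }
  exp_o <- exposure[order(exposure$county_id, exposure$month_index), ]
  lag_term <- function(beta) {
    unlist(lapply(split(exp_o$exposure_days_total, exp_o$county_id), function(x) {
      out <- numeric(length(x))
      for (l in 0:L) {
        shifted <- c(rep(0, l), x[seq_len(length(x) - l)])
        out <- out + beta[l + 1L] * shifted
      }
      out
    }), use.names = FALSE)
  }
  lag_f <- lag_term(betas$female)
  lag_m <- lag_term(betas$male)
  pop_m <- interpolate_population(counties$population, origin_year = y0)
  key_cm <- paste(exp_o$county_id, exp_o$month_index)
  temp_off <- stats::approx(config$temp_effect_knots$temp_c,
                            config$temp_effect_knots$effect,
                            xout = temperature$temp_c, rule = 2)$y
  temp_off <- temp_off[match(key_cm, paste(temperature$county_id,
                                           temperature$month_index))]
  mo <- index_month(exp_o$month_index)
  seasonal <- config$seasonal_amplitude * cos(2 * pi * (mo - 1) / 12)
  trend <- trend_log_offset(exp_o$month_index, config, y0)
  cm <- data.frame(county_id = exp_o$county_id, month_index = exp_o$month_index,
                   base = log(config$baseline_monthly_rate) +
                     county_effects[exp_o$county_id] + seasonal + trend + temp_off,
                   lag_f = lag_f, lag_m = lag_m, stringsAsFactors = FALSE)
  grid <- expand.grid(cm_row = seq_len(nrow(cm)),
                      age_group = age_group_levels(),
                      sex = c("female", "male"),
                      cause = names(demo$cause_share),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pop_key <- paste(cm$county_id[grid$cm_row], cm$month_index[grid$cm_row],
                   grid$age_group, grid$sex)
  pop <- pop_m$population[match(pop_key, paste(pop_m$county_id,
                                               pop_m$month_index,
                                               pop_m$age_group, pop_m$sex))]
  log_mu <- cm$base[grid$cm_row] +
    ifelse(grid$sex == "female", cm$lag_f[grid$cm_row], cm$lag_m[grid$cm_row]) +
    log(demo$mult[cbind(grid$age_group, grid$sex)]) +
    log(demo$cause_share[grid$cause]) + log(pop)
  data.frame(county_id = cm$county_id[grid$cm_row],
             month_index = cm$month_index[grid$cm_row],
             age_group = grid$age_group, sex = grid$sex, cause = grid$cause,
             log_mu = log_mu, stringsAsFactors = FALSE)
}

#' Generate synthetic death counts
#'
#' Counts per county-month, age group, sex and cause category are drawn from a
#' negative binomial whose log-mean is the sum of a county intercept, a
#' calendar-month seasonal effect, the planted distributed-lag exposure
#' effect, a piecewise long-term trend, a smooth temperature offset, and the
#' log monthly population offset. The truth record stores every planted value
#' and the realised log-mean surface.
#'
#' @param counties,exposure,temperature Results of the corresponding
#'   `simulate_*` stages (aligned on the same county-month index).
#' @param config A [sim_config()] object.
#' @return List: `deaths` (data frame `county_id`, `month_index`, `age_group`,
#'   `sex`, `cause`, `deaths`) and `truth` (planted parameter record).
#' @export
simulate_deaths <- function(counties, exposure, temperature, config) {
  stopifnot(inherits(config, "storm_sim_config"))
  key_e <- paste(exposure$county_id, exposure$month_index)
  key_t <- paste(temperature$county_id, temperature$month_index)
  if (!setequal(key_e, key_t)) {
    off <- utils::head(c(setdiff(key_e, key_t), setdiff(key_t, key_e)), 3L)
    stop("misaligned county-month index between exposure and temperature: ",
         paste(off, collapse = "; "))
  }
  set.seed(stage_seed(config$seed, 4L))
  ids <- counties$counties$county_id
  county_effects <- stats::setNames(
    stats::rnorm(length(ids), 0, config$county_effect_sd), ids)
  lm_df <- generator_log_mean(counties, exposure, temperature, config,
                              county_effects)
  mu <- exp(lm_df$log_mu)
  y <- if (config$overdispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$overdispersion)
  } else {
    stats::rpois(length(mu), mu)
  }
  deaths <- cbind(lm_df[c("county_id", "month_index", "age_group", "sex",
                          "cause")],
                  deaths = as.integer(y))
  truth <- list(
    planted_lag_log_rr = config$planted_lag_log_rr,
    planted_lag_log_rr_by_sex = config$planted_lag_log_rr_by_sex,
    trend_breakpoint = config$trend_breakpoint,
    trend_slopes = config$trend_slopes,
    seasonal_amplitude = config$seasonal_amplitude,
    temp_effect_knots = config$temp_effect_knots,
    overdispersion = config$overdispersion,
    baseline_monthly_rate = config$baseline_monthly_rate,
    county_effects = county_effects,
    log_mean = lm_df
  )
  list(deaths = deaths, truth = truth)
}

#' Generate a complete synthetic study panel
#'
#' Runs all generator stages (counties, exposure, temperature, deaths) from
#' deterministic substreams of the master seed, so the full panel is
#' bit-identical across runs with the same configuration.
#'
#' @param config A [sim_config()] object.
#' @return Object of class `storm_panel`: a list with `counties`, `adjacency`,
#'   `population` (annual, by age group and sex), `exposure`, `temperature`,
#'   `deaths`, `truth`, `config`, `origin_year`.
#' @examples
#' panel <- simulate_panel(sim_config(n_counties = 4, seed = 7))
#' head(panel$deaths)
#' @export
simulate_panel <- function(config = sim_config()) {
  cty <- simulate_counties(config)
  expo <- simulate_exposure(cty, config)
  temp <- simulate_temperature(cty, config)
  dth <- simulate_deaths(cty, expo, temp, config)
  structure(list(counties = cty$counties, adjacency = cty$adjacency,
                 population = cty$population, exposure = expo,
                 temperature = temp, deaths = dth$deaths, truth = dth$truth,
                 config = config, origin_year = config$year_range[1L]),
            class = "storm_panel")
}

#' @export
print.storm_panel <- function(x, ...) {
  yrs <- x$config$year_range
  cat("Synthetic county-month panel:",
      nrow(x$counties), "counties,", yrs[1L], "-", yrs[2L], "\n")
  cat("  exposed county-months:", sum(x$exposure$exposure_days_total > 0),
      " total exposure days:", sum(x$exposure$exposure_days_total), "\n")
  cat("  total deaths:", sum(x$deaths$deaths), "\n")
  cat("  planted lag log RR:",
      paste(signif(x$truth$planted_lag_log_rr, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Recompute the generator's expected log-mean from its truth record
#'
#' Internal-consistency audit: re-evaluates the log-mean surface from the
#' planted parameters stored in the truth record and the panel's exposure,
#' temperature and population series. Matches `panel$truth$log_mean` to
#' floating tolerance.
#'
#' @param panel A `storm_panel`.
#' @return Data frame in the same layout as `panel$truth$log_mean`.
#' @export
expected_log_mean <- function(panel) {
  stopifnot(inherits(panel, "storm_panel"))
  generator_log_mean(list(counties = panel$counties,
                          population = panel$population),
                     panel$exposure, panel$temperature, panel$config,
                     panel$truth$county_effects)
}
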