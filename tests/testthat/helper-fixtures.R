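# Fixtures shared across test files; panels are built once per run and cached.

.fixture_env <- new.env(parent = emptyenv())

# reference synthetic panel at the default study conditions
fixture_panel <- function() {
  if (is.null(.fixture_env$panel)) {
    .fixture_env$panel <- simulate_panel(sim_config(seed = 42))
  }
  .fixture_env$panel
}

# a config with all structural confounding switched off, for tests that need
# exchangeable counts within strata
flat_config <- function(planted_lag_log_rr = c(0, 0, 0, 0), ...) {
  sim_config(planted_lag_log_rr = planted_lag_log_rr,
             seasonal_amplitude = 0, trend_slopes = c(0, 0),
             temp_effect_knots = data.frame(temp_c = c(0, 30),
                                            effect = c(0, 0)),
             county_effect_sd = 0, pop_growth_sd = 0, ...)
}

fast_map_config <- function(...) {
  model_config(inference = "map_laplace", seed = 7, ...)
}

# minimal hand-built panel: one county, one informative stratum with three
# member years (deaths `counts`), a single exposure day in the middle year
tiny_panel <- function(counts = c(2L, 5L, 3L), expose_year = 2001L,
                       month = 7L, years = 2000:2002) {
  y0 <- years[1]
  n_months <- length(years) * 12L
  expo <- data.frame(county_id = "C1", month_index = seq_len(n_months) - 1L,
                     exposure_days_total = 0L, exposure_days_gale = 0L,
                     exposure_days_hurricane = 0L)
  ei <- month_index(expose_year, month, y0)
  expo$exposure_days_total[expo$month_index == ei] <- 1L
  expo$exposure_days_gale[expo$month_index == ei] <- 1L
  deaths <- data.frame(county_id = "C1",
                       month_index = month_index(years, month, y0),
                       deaths = counts)
  list(counties = data.frame(county_id = "C1", state = "S1",
                             poverty_pct = 10, minority_pct = 10),
       population = data.frame(county_id = "C1", year = years,
                               population = 1000),
       exposure = expo,
       temperature = data.frame(county_id = "C1",
                                month_index = seq_len(n_months) - 1L,
                                temp_c = 15),
       deaths = deaths,
       origin_year = y0)
}

# config for the tiny fixture: flat priors, exposure-only design
tiny_config <- function(...) {
  model_config(lag = 0L, trend = FALSE, temp = FALSE, prior_sd = Inf,
               overdispersion = "poisson", inference = "map_laplace",
               seed = 1, ...)
}
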