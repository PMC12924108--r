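test_that("strata are county-calendar-month groups with correct case tagging", {
  years <- 1990:1994
  y0 <- 1990
  expo <- expand.grid(county_id = "C1", month_index = 0:59,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expo$exposure_days_total <- 0L
  expo$exposure_days_total[expo$month_index == month_index(1992, 9, y0)] <- 2L
  mort <- data.frame(county_id = "C1", month_index = 0:59, deaths = 1L)
  lags <- build_lag_matrix(expo, L = 3L)
  st <- build_strata(mort, lags)
  sep <- st[st$calendar_month == 9, ]
  expect_equal(sep$n_members, 5L)
  expect_equal(sep$n_cases, 1L)
  expect_true(sep$informative)
  # strata in months untouched by exposure or its lags are non-informative
  expect_false(any(st$informative[st$calendar_month %in% c(2:8)]))

  # multiple exposed years in the same stratum are all cases
  expo3 <- expo
  expo3$exposure_days_total[expo3$month_index %in%
                              month_index(c(1990, 1992, 1994), 9, y0)] <- 1L
  st3 <- build_strata(mort, build_lag_matrix(expo3, L = 3L))
  expect_equal(st3$n_cases[st3$calendar_month == 9], 3L)
})

test_that("a panel without exposure variation refuses to fit", {
  panel <- tiny_panel()
  panel$exposure$exposure_days_total <- 0L
  expect_error(fit_casecrossover(panel, tiny_config()),
               "not identifiable under conditioning")
})

test_that("map and mcmc inference agree on the lag coefficients", {
  panel <- fixture_panel()
  fmap <- fit_casecrossover(panel, fast_map_config())
  fmc <- suppressWarnings(
    fit_casecrossover(panel, model_config(inference = "mcmc", chains = 2,
                                          draws = 600, warmup = 200,
                                          seed = 7)))
  expect_equal(unname(coef(fmap)), unname(coef(fmc)), tolerance = 0.01)
  expect_gt(fmc$acceptance_rate, 0.5)
  expect_true(all(fmc$ess > 100))
})

test_that("posterior summaries are internally coherent", {
  fit <- fit_casecrossover(fixture_panel(), fast_map_config())
  expect_length(coef(fit), fit$lag + 1L)
  expect_true(all(fit$cri[, "lower95"] <= coef(fit)))
  expect_true(all(coef(fit) <= fit$cri[, "upper95"]))
  expect_true(all(is.finite(fit$beta_draws)))
  expect_gte(nrow(fit$beta_draws), 1000)
  s <- summary(fit)
  expect_s3_class(s, "summary.cc_fit")
  expect_equal(s$table$mean, unname(coef(fit)))
  ci <- confint(fit, level = 0.9)
  expect_true(all(ci[, 1] >= fit$cri[, "lower95"]))
  r <- residuals(fit)
  expect_length(r, fit$n_obs)
})

test_that("recovered lag-0 effect increases with the planted effect", {
  means <- vapply(c(0, 0.05, 0.1), function(b) {
    cfg <- sim_config(n_counties = 20, planted_lag_log_rr = c(b, 0, 0, 0),
                      seed = 55)
    fit <- fit_casecrossover(simulate_panel(cfg), fast_map_config())
    coef(fit)[[1]]
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("doubling every population leaves the fit unchanged (offsets cancel)", {
  panel <- fixture_panel()
  panel2 <- panel
  panel2$population$population <- panel2$population$population * 2
  f1 <- fit_casecrossover(panel, fast_map_config())
  f2 <- fit_casecrossover(panel2, fast_map_config())
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(f1$cri, f2$cri, tolerance = 1e-6)
})

test_that("an unrestricted subgroup fit equals the main fit", {
  panel <- fixture_panel()
  f_main <- fit_casecrossover(panel, fast_map_config())
  f_sub <- fit_subgroup(panel, fast_map_config())
  expect_equal(coef(f_main), coef(f_sub))
  expect_equal(f_main$cri, f_sub$cri)
})

test_that("subgroups with no outcome events refuse to fit", {
  panel <- fixture_panel()
  panel$deaths$deaths[panel$deaths$sex == "female"] <- 0L
  expect_error(fit_subgroup(panel, fast_map_config(), sex = "female"),
               "no outcome events")
})

test_that("planted sex-specific effects are recovered per subgroup", {
  cfg <- sim_config(
    planted_lag_log_rr = c(0.045, 0, 0, 0),
    planted_lag_log_rr_by_sex = list(female = c(0.06, 0, 0, 0),
                                     male = c(0.03, 0, 0, 0)),
    seed = 77)
  panel <- simulate_panel(cfg)
  ff <- fit_subgroup(panel, fast_map_config(), sex = "female")
  fm <- fit_subgroup(panel, fast_map_config(), sex = "male")
  expect_lt(abs(coef(ff)[[1]] - 0.06), 0.045)
  expect_lt(abs(coef(fm)[[1]] - 0.03), 0.045)
  d <- subgroup_difference(ff, fm, "female", "male")
  expect_gt(d$delta_mean[1], 0)
})

test_that("strength-class covariates select the matching exposure columns", {
  panel <- fixture_panel()
  fg <- fit_casecrossover(panel, fast_map_config(), exposure_type = "gale")
  expect_s3_class(fg, "cc_fit")
  expect_equal(fg$exposure_type, "gale")
  # gale days dominate total days, so the gale fit should track the main fit
  fit <- fit_casecrossover(panel, fast_map_config())
  expect_equal(coef(fg)[[1]], coef(fit)[[1]], tolerance = 0.05)
})

test_that("stratum bookkeeping counts incomplete and single-member exclusions", {
  fit <- fit_casecrossover(fixture_panel(), fast_map_config())
  # 3 lag months x 30 counties are incomplete at the series start
  expect_equal(unname(fit$strata[["incomplete_lag_months"]]), 90)
  expect_equal(unname(fit$strata[["total"]]), 360)
  expect_gt(unname(fit$strata[["informative"]]), 0)
})
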