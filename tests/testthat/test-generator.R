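test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(n_counties = 1), "n_counties")
  expect_error(sim_config(baseline_monthly_rate = 0), "baseline_monthly_rate")
  expect_error(sim_config(year_range = c(2010, 2009)), "year_range")
  expect_error(sim_config(overdispersion = -1), "overdispersion")
})

test_that("the full panel is bit-identical under a fixed seed", {
  p1 <- simulate_panel(sim_config(n_counties = 6, seed = 7))
  p2 <- simulate_panel(sim_config(n_counties = 6, seed = 7))
  expect_identical(p1$counties, p2$counties)
  expect_identical(p1$exposure, p2$exposure)
  expect_identical(p1$temperature, p2$temperature)
  expect_identical(p1$deaths, p2$deaths)
  p3 <- simulate_panel(sim_config(n_counties = 6, seed = 8))
  expect_false(identical(p1$deaths, p3$deaths))
})

test_that("generated counties satisfy the structural invariants", {
  cty <- simulate_counties(sim_config(n_counties = 40, n_states = 4, seed = 7))
  A <- cty$adjacency
  expect_identical(A, t(A))                      # symmetric
  expect_true(all(diag(A) == 0))                 # irreflexive
  # connected: breadth-first reach from county 1
  reach <- c(1L)
  frontier <- 1L
  while (length(frontier)) {
    nxt <- setdiff(which(rowSums(A[, frontier, drop = FALSE]) > 0), reach)
    reach <- c(reach, nxt)
    frontier <- nxt
  }
  expect_length(reach, nrow(A))
  # median dichotomisation yields two nonempty groups on both covariates
  for (v in c("poverty_pct", "minority_pct")) {
    med <- median(cty$counties[[v]])
    expect_gt(sum(cty$counties[[v]] > med), 0)
    expect_gt(sum(cty$counties[[v]] <= med), 0)
  }
  expect_true(all(cty$population$population > 0))
  expect_setequal(unique(cty$population$age_group), age_group_levels())
})

test_that("exposure is confined to May-November with September modal", {
  cfg <- sim_config(n_counties = 150, exposure_rate = 4, seed = 13)
  cty <- simulate_counties(cfg)
  expo <- simulate_exposure(cty, cfg)
  exposed <- expo[expo$exposure_days_total > 0, ]
  expect_gt(nrow(exposed), 5000)
  mos <- index_month(exposed$month_index)
  expect_true(all(mos %in% 5:11))
  expect_equal(as.integer(names(which.max(table(mos)))), 9L)
  # day counts bounded by days in month, hurricanes a small minority
  dmax <- days_in_month(index_year(exposed$month_index, 2010),
                        index_month(exposed$month_index))
  expect_true(all(exposed$exposure_days_total <= dmax))
  expect_true(all(exposed$exposure_days_total ==
                    exposed$exposure_days_gale + exposed$exposure_days_hurricane))
  expect_lt(sum(exposed$exposure_days_hurricane) /
              sum(exposed$exposure_days_total), 0.15)
  # every county experiences at least one cyclone
  expect_true(all(tapply(expo$exposure_days_total, expo$county_id, sum) > 0))
})

test_that("zero exposure rate yields an all-zero panel (every county still forced one exposed month)", {
  cfg <- sim_config(n_counties = 5, exposure_rate = 0, seed = 3)
  expo <- simulate_exposure(simulate_counties(cfg), cfg)
  # the forced minimum leaves exactly one exposed month per county
  expect_equal(as.vector(tapply(expo$exposure_days_total > 0,
                                expo$county_id, sum)),
               rep(1L, 5))
})

test_that("null-effect flat generator reproduces the baseline rate", {
  cfg <- flat_config(n_counties = 30, baseline_monthly_rate = 1e-4,
                     overdispersion = 0, seed = 21)
  panel <- simulate_panel(cfg)
  pop_m <- interpolate_population(panel$population,
                                  origin_year = panel$origin_year)
  rate <- sum(panel$deaths$deaths) / sum(pop_m$population)
  expect_equal(rate, 1e-4, tolerance = 0.02)
})

test_that("a planted lag-0 effect is recovered by a direct stratified tally", {
  cfg <- flat_config(n_counties = 150, baseline_monthly_rate = 3e-4,
                     planted_lag_log_rr = c(0.05, 0, 0, 0),
                     exposure_rate = 1.5, seed = 31)
  panel <- simulate_panel(cfg)
  lag <- build_lag_matrix(panel$exposure, L = 0L)
  dth <- rowsum(panel$deaths$deaths,
                paste(panel$deaths$county_id, panel$deaths$month_index))
  key <- paste(lag$county_id, lag$month_index)
  d <- data.frame(county_id = lag$county_id, x0 = lag$x_0,
                  cal = index_month(lag$month_index),
                  deaths = as.vector(dth[match(key, rownames(dth))]))
  # matched comparison within county-calendar-month strata: months with
  # exactly one exposed day vs unexposed months of the same stratum
  skey <- paste(d$county_id, d$cal)
  case <- d$x0 == 1
  ctl <- d$x0 == 0
  strata_with_case <- unique(skey[case])
  use <- skey %in% strata_with_case
  rr <- (sum(d$deaths[use & case]) / sum(use & case)) /
    (sum(d$deaths[use & ctl]) / sum(use & ctl))
  expect_equal(log(rr), 0.05, tolerance = 0.5)  # sign and magnitude
  expect_lt(abs(log(rr) - 0.05), 0.025)
})

test_that("overdispersed counts exceed Poisson variance at fixed covariates", {
  vm_ratio <- function(alpha, seed) {
    cfg <- flat_config(n_counties = 20, baseline_monthly_rate = 3e-4,
                       overdispersion = alpha, exposure_rate = 0, seed = seed)
    panel <- simulate_panel(cfg)
    tot <- rowsum(panel$deaths$deaths,
                  paste(panel$deaths$county_id, panel$deaths$month_index))
    idx <- as.integer(sub(".* ", "", rownames(tot)))
    cid <- sub(" .*", "", rownames(tot))
    # within county-calendar-month cells the mean is constant by construction
    g <- paste(cid, index_month(idx))
    v <- tapply(as.vector(tot), g, var)
    m <- tapply(as.vector(tot), g, mean)
    mean(v / m)
  }
  expect_gt(vm_ratio(0.5, 5), 1.3)
  expect_equal(vm_ratio(0, 5), 1, tolerance = 0.1)
})

test_that("counts are exchangeable across years within strata under the null", {
  cfg <- flat_config(n_counties = 30, baseline_monthly_rate = 3e-4,
                     exposure_rate = 0, seed = 17)
  panel <- simulate_panel(cfg)
  tot <- rowsum(panel$deaths$deaths,
                paste(panel$deaths$county_id, panel$deaths$month_index))
  idx <- as.integer(sub(".* ", "", rownames(tot)))
  cid <- sub(" .*", "", rownames(tot))
  g <- paste(cid, index_month(idx))
  pvals <- vapply(split(seq_along(idx), g), function(ix) {
    suppressWarnings(cor.test(idx[ix], as.vector(tot)[ix],
                              method = "kendall")$p.value)
  }, numeric(1))
  rej <- mean(pvals < 0.05)
  expect_gt(rej, 0.01)   # the test has its nominal level ...
  expect_lt(rej, 0.10)   # ... and no systematic year trend
})

test_that("the truth record's log-mean surface is internally consistent", {
  panel <- simulate_panel(sim_config(n_counties = 5, seed = 9))
  redo <- expected_log_mean(panel)
  expect_equal(redo$log_mu, panel$truth$log_mean$log_mu, tolerance = 1e-12)
})

test_that("panel files round-trip losslessly through the text contract", {
  panel <- simulate_panel(sim_config(n_counties = 4, seed = 7))
  dir <- withr::local_tempdir()
  write_panel(panel, dir)
  back <- read_panel(dir)
  expect_equal(back$deaths, panel$deaths)
  expect_equal(back$exposure, panel$exposure)
  expect_equal(back$counties, panel$counties)
  expect_equal(back$adjacency, panel$adjacency)
  expect_equal(back$population$population, panel$population$population,
               tolerance = 1e-12)
  expect_equal(back$truth$planted_lag_log_rr, panel$truth$planted_lag_log_rr)
  expect_equal(back$truth$county_effects, panel$truth$county_effects,
               tolerance = 1e-9)
})
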