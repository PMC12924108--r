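test_that("percent change transforms log rate ratios exactly on constants", {
  z <- rep(0, 2000)
  expect_equal(unname(percent_change(z)), c(0, 0, 0))
  c1 <- rep(log(1.0384), 2000)
  expect_equal(unname(percent_change(c1)), rep(3.84, 3), tolerance = 1e-9)
  expect_error(percent_change(c(z, NA)), "non-finite")
})

test_that("percent change matches the log-normal closed form on Gaussian draws", {
  set.seed(8)
  draws <- rnorm(2e5, mean = 0.05, sd = 0.01)
  pc <- percent_change(draws)
  expect_equal(pc[["mean"]], 100 * (exp(0.05 + 0.0001 / 2) - 1),
               tolerance = 1e-3)
  expect_equal(pc[["lower95"]], 100 * (exp(qnorm(0.025, 0.05, 0.01)) - 1),
               tolerance = 1e-2)
})

test_that("DPM scaling is proportional to the percent scale", {
  pct <- rep(5, 2000)
  expect_equal(to_dpm(pct, R0 = 100)[["mean"]], 5)
  expect_lt(to_dpm(pct, R0 = 1e-4)[["mean"]], 1e-5)
  expect_error(to_dpm(pct, R0 = 0), "positive")
  # the printed pair (3.84%, 5.37 DPM) implies R0 = 5.37/3.84*100
  R0 <- 5.37 / 3.84 * 100
  expect_equal(round(to_dpm(rep(3.84, 2000), R0)[["mean"]], 2), 5.37)
})

test_that("interval-sign classification follows the CrI rule with boundaries", {
  expect_equal(classify_association(1.83, 5.89), "positive")
  expect_equal(classify_association(-0.78, 15.69), "null")
  expect_equal(classify_association(-5, -1), "negative")
  expect_equal(classify_association(0, 0), "positive")  # boundary: nonnegative
  expect_error(classify_association(2, 1), "order")
  # monotone: shifting an interval upward never moves toward negative
  rank <- c(negative = 1, null = 2, positive = 3)
  set.seed(1)
  for (i in 1:50) {
    lo <- rnorm(1); hi <- lo + abs(rnorm(1)); s <- abs(rnorm(1))
    expect_gte(rank[classify_association(lo + s, hi + s)],
               rank[classify_association(lo, hi)])
  }
})

test_that("effect summaries keep DPM proportional at every summarised point", {
  fit <- fit_casecrossover(fixture_panel(), fast_map_config())
  R0 <- 139.8
  es <- effect_summary(fit, R0)
  expect_equal(es$dpm_mean, es$pct_mean / 100 * R0)
  expect_equal(es$dpm_lo, es$pct_lo / 100 * R0)
  expect_equal(es$dpm_hi, es$pct_hi / 100 * R0)
  expect_equal(es$label,
               unname(classify_association(es$pct_lo, es$pct_hi)))
})

test_that("subgroup contrasts are antisymmetric and widen by sqrt(2)", {
  fit <- fit_casecrossover(fixture_panel(), fast_map_config())
  same <- subgroup_difference(fit, fit)
  expect_equal(same$delta_mean, rep(0, 4))
  expect_equal(same$delta_lo, rep(0, 4))

  fitB <- fit
  set.seed(9)
  fitB$beta_draws <- fit$beta_draws[sample(nrow(fit$beta_draws)), ]
  ab <- subgroup_difference(fit, fitB)
  ba <- subgroup_difference(fitB, fit)
  expect_equal(ab$delta_mean, -ba$delta_mean)

  # independent Gaussian draws: difference mean and sqrt(2)-wider interval
  set.seed(10)
  A <- fit; B <- fit
  A$beta_draws <- matrix(rnorm(4e4, 0.06, 0.01), ncol = 4)
  B$beta_draws <- matrix(rnorm(4e4, 0.03, 0.01), ncol = 4)
  d <- subgroup_difference(A, B)
  expect_equal(d$delta_mean, rep(0.03, 4), tolerance = 0.02)
  width <- d$delta_hi - d$delta_lo
  expect_equal(width, rep(2 * 1.96 * 0.01 * sqrt(2), 4), tolerance = 0.03)

  C <- fit
  C$lag <- 1L
  C$beta_draws <- fit$beta_draws[, 1:2]
  expect_error(subgroup_difference(fit, C), "mismatched lag")
})

test_that("disadvantage categories cross the two median flags", {
  cc <- data.frame(county_id = c("a", "b", "c", "d"),
                   poverty_pct = c(10, 10, 30, 30),
                   minority_pct = c(10, 30, 10, 30))
  out <- categorize_disadvantage(cc)
  expect_equal(unname(out$thresholds), c(20, 20))
  expect_equal(unname(out$counts), rep(1L, 4))
  expect_equal(sum(out$counts), nrow(cc))

  # explicit published thresholds
  one <- categorize_disadvantage(
    data.frame(county_id = "x", poverty_pct = 20, minority_pct = 10,
               stringsAsFactors = FALSE),
    thresholds = c(16, 18))
  expect_equal(one$categories$category, "high-low")

  # degenerate: identical counties all sit at the median, hence "low-low"
  same <- data.frame(county_id = letters[1:5], poverty_pct = 12,
                     minority_pct = 40)
  expect_equal(unname(categorize_disadvantage(same)$counts[["low-low"]]), 5L)

  # missing covariates are excluded and counted
  cc$poverty_pct[2] <- NA
  expect_message(out2 <- categorize_disadvantage(cc), "excluded")
  expect_equal(out2$n_excluded, 1L)
  expect_equal(sum(out2$counts), 3L)
})

test_that("the baseline DPM helper standardises rates over 15+ age groups", {
  panel <- fixture_panel()
  R0 <- baseline_dpm(panel, year = 2019)
  expect_gt(R0, 0)
  # scaling every population down doubles the rate
  panel2 <- panel
  panel2$population$population <- panel2$population$population / 2
  expect_equal(baseline_dpm(panel2, year = 2019), 2 * R0, tolerance = 1e-9)
  expect_error(baseline_dpm(panel, year = 1900), "outside")
})
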