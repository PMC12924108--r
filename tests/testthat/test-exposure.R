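test_that("month-index arithmetic places the trend breakpoint correctly", {
  expect_equal(month_index(1988, 1, 1988), 0L)
  expect_equal(month_index(2015, 12, 1988), 335L)  # default breakpoint
  expect_equal(index_year(335L, 1988), 2015L)
  expect_equal(index_month(335L), 12L)
  expect_equal(days_in_month(c(2000, 1900, 2019), c(2, 2, 9)),
               c(29L, 28L, 30L))
})

test_that("wind thresholds classify days into gale and hurricane counts", {
  w <- data.frame(county_id = "A",
                  date = sprintf("2005-09-%02d", 1:6),
                  wind_kt = c(20, 35, 63, 64, 80, 10))
  p <- count_exposure_days(w)
  expect_equal(p$exposure_days_total, 4L)
  expect_equal(p$exposure_days_gale, 2L)      # 34-63 kt
  expect_equal(p$exposure_days_hurricane, 2L) # >= 64 kt
  expect_equal(p$month_index,
               month_index(2005, 9, 2005))

  calm <- data.frame(county_id = "A", date = w$date, wind_kt = 10)
  expect_true(all(count_exposure_days(calm)$exposure_days_total == 0))

  w_bad <- w
  w_bad$wind_kt[3] <- -1
  expect_error(count_exposure_days(w_bad), "negative")
})

test_that("exposure-day counting conserves qualifying days and ignores record order", {
  set.seed(4)
  w <- data.frame(
    county_id = sample(c("A", "B"), 200, replace = TRUE),
    date = as.character(as.Date("1995-06-01") + sample(0:500, 200, TRUE)),
    wind_kt = round(runif(200, 0, 90)))
  p <- count_exposure_days(w, origin_year = 1995)
  expect_equal(sum(p$exposure_days_total), sum(w$wind_kt >= 34))
  p_shuf <- count_exposure_days(w[sample(nrow(w)), ], origin_year = 1995)
  expect_equal(p, p_shuf, ignore_attr = TRUE)
})

test_that("lag matrices shift exposure backwards and flag incomplete starts", {
  panel <- data.frame(county_id = "A", month_index = 0:4,
                      exposure_days_total = c(0, 0, 3, 0, 0))
  lag <- build_lag_matrix(panel, L = 3L)
  r <- lag[lag$month_index == 4, ]
  expect_equal(unlist(r[paste0("x_", 0:3)], use.names = FALSE), c(0, 0, 3, 0))
  expect_false(any(lag$complete[lag$month_index < 3]))
  expect_true(all(lag$complete[lag$month_index >= 3]))
  # L = 0 is the identity
  lag0 <- build_lag_matrix(panel, L = 0L)
  expect_equal(lag0$x_0, panel$exposure_days_total)
  expect_true(all(lag0$complete))
  # gaps in the month index are an error naming the gap
  gap <- panel[-3, ]
  expect_error(build_lag_matrix(gap, L = 1L), "gap")
})

test_that("population interpolation anchors to June and is linear between", {
  a <- data.frame(county_id = "A", year = c(1990, 1991),
                  population = c(1000, 1300))
  m <- interpolate_population(a, origin_year = 1990)
  expect_equal(m$population[m$month_index == month_index(1990, 6, 1990)], 1000)
  expect_equal(m$population[m$month_index == month_index(1991, 6, 1990)], 1300)
  expect_equal(m$population[m$month_index == month_index(1990, 12, 1990)], 1150)
  # piecewise linearity: zero second differences within the segment
  seg <- m$population[m$month_index %in%
                        month_index(1990, 6, 1990):month_index(1991, 6, 1990)]
  expect_equal(max(abs(diff(seg, differences = 2))), 0, tolerance = 1e-9)

  flat <- data.frame(county_id = "A", year = c(1990, 1991), population = 1200)
  mf <- interpolate_population(flat, origin_year = 1990)
  expect_true(all(mf$population == 1200))
  expect_equal(mf$population[mf$month_index == month_index(1991, 3, 1990)],
               1200)

  bad <- data.frame(county_id = "A", year = c(1990, 1991),
                    population = c(100, 0))
  expect_error(interpolate_population(bad, origin_year = 1990),
               "non-positive")
})

test_that("extrapolation outside the June anchors continues the edge slopes", {
  a <- data.frame(county_id = "A", year = c(1990, 1991),
                  population = c(1000, 1300))
  m <- interpolate_population(a, origin_year = 1990)
  # slope is 25/month; January 1990 is 5 months before the first anchor
  expect_equal(m$population[m$month_index == 0], 1000 - 5 * 25)
  expect_equal(m$population[m$month_index == month_index(1991, 12, 1990)],
               1300 + 6 * 25)
})

test_that("county covariate correlations follow the product-moment formula", {
  expect_equal(correlate_years(1:5, 1:5), 1.0)
  expect_equal(correlate_years(1:5, -(1:5)), -1.0)
  expect_equal(correlate_years(c(1, 2, 3, 4), c(2, 4, 5, 9)), 11 / sqrt(130))
  expect_error(correlate_years(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlate_years(1:4, 1:5), "aligned")
})
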