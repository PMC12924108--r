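# Exposure assembly: daily sustained winds -> monthly exposure-day counts by
# storm strength, distributed-lag matrices, and June-anchored monthly
# population offsets.

GALE_KT <- 34
HURRICANE_KT <- 64

#' Count tropical-cyclone exposure days per county-month
#'
#' A day counts as cyclone-exposed when the county's maximum sustained wind is
#' at least 34 knots; exposed days are split into gale-to-violent storms
#' (34-63 kt) and hurricanes (>= 64 kt).
#'
#' @param daily_winds Data frame with columns `county_id`, `date`
#'   (ISO-8601 string or `Date`), `wind_kt` (non-negative knots; daily maximum
#'   sustained wind at the county population mean center).
#' @param origin_year Year whose January is month index 0. Defaults to the
#'   earliest year present.
#' @return Data frame (one row per county-month that appears in the input)
#'   with columns `county_id`, `month_index`, `exposure_days_total`,
#'   `exposure_days_gale`, `exposure_days_hurricane`.
#' @examples
#' w <- data.frame(county_id = "A",
#'                 date = sprintf("2005-09-%02d", 1:6),
#'                 wind_kt = c(20, 35, 63, 64, 80, 10))
#' count_exposure_days(w)
#' @export
count_exposure_days <- function(daily_winds, origin_year = NULL) {
  req <- c("county_id", "date", "wind_kt")
  if (!all(req %in% names(daily_winds))) {
    stop("daily_winds needs columns: ", paste(req, collapse = ", "))
  }
  d <- daily_winds
  bad <- which(!is.finite(d$wind_kt) | d$wind_kt < 0)
  if (length(bad)) {
    stop("negative or non-finite wind speed at input row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  dt <- as.Date(d$date)
  if (anyNA(dt)) stop("unparseable date at input row(s): ",
                      paste(utils::head(which(is.na(dt)), 5), collapse = ", "))
  yr <- as.integer(format(dt, "%Y"))
  mo <- as.integer(format(dt, "%m"))
  if (is.null(origin_year)) origin_year <- min(yr)
  idx <- month_index(yr, mo, origin_year)
  key <- paste(d$county_id, idx, sep = "\r")
  gale <- d$wind_kt >= GALE_KT & d$wind_kt < HURRICANE_KT
  hurr <- d$wind_kt >= HURRICANE_KT
  agg <- function(v) as.vector(rowsum(as.integer(v), key, reorder = TRUE))
  keys <- sort(unique(key))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    county_id = vapply(parts, `[`, "", 1L),
    month_index = as.integer(vapply(parts, `[`, "", 2L)),
    exposure_days_gale = agg(gale),
    exposure_days_hurricane = agg(hurr),
    stringsAsFactors = FALSE
  )
  out$exposure_days_total <- out$exposure_days_gale + out$exposure_days_hurricane
  attr(out, "origin_year") <- origin_year
  out[order(out$county_id, out$month_index),
      c("county_id", "month_index", "exposure_days_total",
        "exposure_days_gale", "exposure_days_hurricane")]
}

#' Build distributed-lag exposure matrices
#'
#' For every county-month, attaches the exposure-day count of that month and
#' of each of the `L` preceding months (lag columns `x_0 .. x_L`). Lag vectors
#' that would reach before the start of a county's series are flagged
#' incomplete (`NA` lags, `complete = FALSE`); such county-months are retained
#' here but excluded from model fitting.
#'
#' @param panel Exposure panel: data frame with `county_id`, `month_index`,
#'   and the exposure column named by `value_col`. The month index must be
#'   contiguous within each county.
#' @param L Non-negative integer maximum lag (months). Default 3.
#' @param value_col Column holding the exposure-day counts
#'   (default `"exposure_days_total"`).
#' @return Data frame with `county_id`, `month_index`, lag columns
#'   `x_0 .. x_L`, and logical `complete`.
#' @export
build_lag_matrix <- function(panel, L = 3L, value_col = "exposure_days_total") {
  stopifnot(L >= 0L, value_col %in% names(panel))
  p <- panel[order(panel$county_id, panel$month_index), ]
  out <- lapply(split(p, p$county_id), function(pc) {
    idx <- pc$month_index
    if (length(idx) > 1L && any(diff(idx) != 1L)) {
      g <- which(diff(idx) != 1L)[1L]
      stop("month index gap for county ", pc$county_id[1L], " between indices ",
           idx[g], " and ", idx[g + 1L])
    }
    x <- pc[[value_col]]
    n <- length(x)
    lag_m <- vapply(0:L, function(l) {
      c(rep(NA_real_, min(l, n)), x[seq_len(max(n - l, 0L))])
    }, numeric(n))
    lag_m <- matrix(lag_m, nrow = n, ncol = L + 1L,
                    dimnames = list(NULL, paste0("x_", 0:L)))
    cbind(pc[c("county_id", "month_index")], as.data.frame(lag_m),
          complete = !apply(is.na(lag_m), 1L, any))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Interpolate annual population counts to months
#'
#' Annual counts are anchored to June of their year and linearly interpolated
#' between consecutive Junes; months before the first June and after the last
#' June are extrapolated with the adjacent segment's slope, floored at 1
#' person so log-population offsets stay finite.
#'
#' @param annual Data frame with `county_id`, `year`, `population`, and
#'   optionally `age_group` and `sex` (absent columns are treated as a single
#'   "total" subgroup).
#' @param origin_year Year whose January is month index 0.
#' @param month_range Integer vector (min, max) of month indices to emit;
#'   default spans January of the first year to December of the last.
#' @return Data frame `county_id`, (`age_group`, `sex` if supplied),
#'   `month_index`, `population`.
#' @examples
#' a <- data.frame(county_id = "A", year = c(1990, 1991),
#'                 population = c(1000, 1300))
#' m <- interpolate_population(a, origin_year = 1990)
#' m$population[m$month_index == month_index(1990, 12, 1990)]  # 1150
#' @export
interpolate_population <- function(annual, origin_year,
                                   month_range = NULL) {
  stopifnot(all(c("county_id", "year", "population") %in% names(annual)))
  if (any(annual$population <= 0)) {
    stop("non-positive annual population in input")
  }
  grp_cols <- intersect(c("age_group", "sex"), names(annual))
  if (is.null(month_range)) {
    month_range <- c(month_index(min(annual$year), 1L, origin_year),
                     month_index(max(annual$year), 12L, origin_year))
  }
  months <- seq.int(month_range[1L], month_range[2L])
  key <- do.call(paste, c(annual[c("county_id", grp_cols)], sep = "\r"))
  pieces <- lapply(split(annual, key), function(a) {
    a <- a[order(a$year), ]
    if (nrow(a) < 2L) stop("need >= 2 annual values per county-subgroup")
    anchors <- month_index(a$year, 6L, origin_year)
    pop <- linear_anchor_interp(months, anchors, a$population)
    cbind(a[rep(1L, length(months)), c("county_id", grp_cols), drop = FALSE],
          data.frame(month_index = months, population = pop))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# piecewise-linear through (anchors, values); outside the anchor range the
# nearest segment's slope is continued; floored at 1
linear_anchor_interp <- function(x, anchors, values) {
  n <- length(anchors)
  y <- stats::approx(anchors, values, xout = x, rule = 2)$y
  s_first <- (values[2L] - values[1L]) / (anchors[2L] - anchors[1L])
  s_last <- (values[n] - values[n - 1L]) / (anchors[n] - anchors[n - 1L])
  lo <- x < anchors[1L]
  hi <- x > anchors[n]
  y[lo] <- values[1L] + s_first * (x[lo] - anchors[1L])
  y[hi] <- values[n] + s_last * (x[hi] - anchors[n])
  pmax(y, 1)
}

#' Pearson correlation between two county-indexed measures
#'
#' Used to check temporal stability of county covariates (e.g., poverty
#' percentage measured in two different years).
#'
#' @param values_a,values_b Numeric vectors aligned on the same counties
#'   (names, when present, must match), length >= 3, non-zero variance.
#' @return Pearson product-moment correlation in \[-1, 1\].
#' @export
correlate_years <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("vectors not aligned: lengths differ")
  if (!is.null(names(values_a)) && !is.null(names(values_b)) &&
      !identical(names(values_a), names(values_b))) {
    stop("vectors not aligned: county names differ")
  }
  if (length(values_a) < 3L) stop("need at least 3 counties")
  if (stats::var(values_a) == 0 || stats::var(values_b) == 0) {
    stop("undefined correlation: zero variance")
  }
  stats::cor(values_a, values_b)
}

#' Summarize an exposure panel
#'
#' Totals and per-class descriptive statistics mirroring how exposure is
#' reported: total/gale/hurricane exposure days, county-months with exposure,
#' and the median and range of day counts within exposed months.
#'
#' @param panel Exposure panel (see [count_exposure_days()]).
#' @return List with `days` (named totals), `county_months` (named counts of
#'   exposed county-months per class) and `day_distribution` (median and range
#'   of per-month day counts, per class).
#' @export
summarize_exposure <- function(panel) {
  cls <- c(total = "exposure_days_total", gale = "exposure_days_gale",
           hurricane = "exposure_days_hurricane")
  days <- vapply(cls, function(cn) sum(panel[[cn]]), numeric(1))
  cm <- vapply(cls, function(cn) sum(panel[[cn]] > 0), numeric(1))
  dist <- lapply(cls, function(cn) {
    v <- panel[[cn]][panel[[cn]] > 0]
    if (!length(v)) return(c(median = NA_real_, min = NA_real_, max = NA_real_))
    c(median = stats::median(v), min = min(v), max = max(v))
  })
  list(days = days, county_months = cm, day_distribution = dist)
}
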