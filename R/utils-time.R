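# Shared month-index convention: integer months since January of the origin
# year, 0-based. All modules use this; origin_year travels with each panel.

#' Convert calendar year/month to a month index
#'
#' The package-wide time axis is the number of whole months since January of
#' `origin_year` (0-based), so lags and spline bases never do year/month tuple
#' arithmetic.
#'
#' @param year Integer calendar year(s).
#' @param month Integer calendar month(s), 1-12.
#' @param origin_year Integer year whose January is index 0.
#' @return Integer month index (vectorised).
#' @examples
#' month_index(1988, 1, 1988)  # 0
#' month_index(2015, 12, 1988) # 335
#' @export
month_index <- function(year, month, origin_year) {
  stopifnot(all(month >= 1L), all(month <= 12L))
  as.integer((year - origin_year) * 12L + (month - 1L))
}

#' @rdname month_index
#' @param index Integer month index.
#' @export
index_year <- function(index, origin_year) {
  as.integer(origin_year + index %/% 12L)
}

#' @rdname month_index
#' @export
index_month <- function(index) {
  as.integer(index %% 12L + 1L)
}

#' Number of days in a calendar month
#'
#' @param year Integer year (Gregorian leap rule).
#' @param month Integer month 1-12.
#' @return Integer day count (vectorised).
#' @export
days_in_month <- function(year, month) {
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  out <- dm[month]
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | (year %% 400L == 0L)
  out[month == 2L & leap] <- 29L
  as.integer(out)
}

# internal: age in years -> analysis age group
age_to_group <- function(age) {
  breaks <- c(-Inf, 14, 29, 44, 59, Inf)
  labs <- c("<15", "15-29", "30-44", "45-59", ">=60")
  as.character(cut(age, breaks = breaks, labels = labs))
}

age_group_levels <- function() c("<15", "15-29", "30-44", "45-59", ">=60")

# internal: deterministic substream seed for a generator stage
stage_seed <- function(seed, stage) {
  s <- (as.numeric(seed) * 13L + stage * 7L) %% 2147483647
  as.integer(s)
}
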