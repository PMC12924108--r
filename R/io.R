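# Delimited-text panel I/O. The generator writes the same file contract the
# pipeline reads, so synthetic and real inputs flow through identical code.

#' Write a study panel to delimited text files
#'
#' Emits `counties.csv`, `adjacency.csv` (edge list), `population.csv`,
#' `exposure.csv`, `temperature.csv`, `deaths.csv`, a `truth.txt` key=value
#' file with the planted scalar/vector parameters (synthetic panels only) and
#' a `panel.txt` with the time-axis metadata. Writers round-trip losslessly
#' with [read_panel()] up to the in-memory truth surface, which is
#' re-derivable via [expected_log_mean()].
#'
#' @param panel A `storm_panel` (or a list with the same data-frame elements).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  wr(panel$counties, "counties.csv")
  if (!is.null(panel$adjacency)) {
    e <- which(panel$adjacency == 1L & upper.tri(panel$adjacency), arr.ind = TRUE)
    wr(data.frame(from = rownames(panel$adjacency)[e[, 1L]],
                  to = colnames(panel$adjacency)[e[, 2L]]), "adjacency.csv")
  }
  wr(panel$population, "population.csv")
  wr(panel$exposure, "exposure.csv")
  wr(panel$temperature, "temperature.csv")
  wr(panel$deaths, "deaths.csv")
  meta <- c(origin_year = panel$origin_year,
            year_start = panel$config$year_range[1L],
            year_end = panel$config$year_range[2L])
  writeLines(paste0(names(meta), "=", meta), file.path(dir, "panel.txt"))
  if (!is.null(panel$truth)) {
    tr <- panel$truth
    kv <- c(
      planted_lag_log_rr = paste(tr$planted_lag_log_rr, collapse = ","),
      trend_breakpoint = paste(tr$trend_breakpoint, collapse = ","),
      trend_slopes = paste(tr$trend_slopes, collapse = ","),
      seasonal_amplitude = tr$seasonal_amplitude,
      overdispersion = tr$overdispersion,
      baseline_monthly_rate = tr$baseline_monthly_rate,
      county_effects = paste(sprintf("%s:%.10g", names(tr$county_effects),
                                     tr$county_effects), collapse = ","),
      temp_knots_c = paste(tr$temp_effect_knots$temp_c, collapse = ","),
      temp_knots_effect = paste(tr$temp_effect_knots$effect, collapse = ",")
    )
    writeLines(paste0(names(kv), "=", kv), file.path(dir, "truth.txt"))
  }
  invisible(dir)
}

#' Read a study panel from delimited text files
#'
#' Counterpart of [write_panel()]. Real (non-synthetic) inputs can be supplied
#' in the same file layout without `truth.txt`.
#'
#' @param dir Directory written by [write_panel()] or following its contract.
#' @return A list with the panel components (class `storm_panel` when a truth
#'   file is present; plain list otherwise).
#' @export
read_panel <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  meta <- read_kv(file.path(dir, "panel.txt"))
  counties <- rd("counties.csv")
  adjacency <- NULL
  if (file.exists(file.path(dir, "adjacency.csv"))) {
    e <- rd("adjacency.csv")
    ids <- counties$county_id
    adjacency <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
    if (nrow(e)) {
      adjacency[cbind(match(e$from, ids), match(e$to, ids))] <- 1L
      adjacency[cbind(match(e$to, ids), match(e$from, ids))] <- 1L
    }
  }
  out <- list(counties = counties, adjacency = adjacency,
              population = rd("population.csv"), exposure = rd("exposure.csv"),
              temperature = rd("temperature.csv"), deaths = rd("deaths.csv"),
              origin_year = as.integer(meta[["origin_year"]]))
  tf <- file.path(dir, "truth.txt")
  if (file.exists(tf)) {
    kv <- read_kv(tf)
    spl <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1L]])
    ce_parts <- strsplit(strsplit(kv[["county_effects"]], ",")[[1L]], ":")
    out$truth <- list(
      planted_lag_log_rr = spl(kv[["planted_lag_log_rr"]]),
      trend_breakpoint = as.integer(spl(kv[["trend_breakpoint"]])),
      trend_slopes = spl(kv[["trend_slopes"]]),
      seasonal_amplitude = as.numeric(kv[["seasonal_amplitude"]]),
      overdispersion = as.numeric(kv[["overdispersion"]]),
      baseline_monthly_rate = as.numeric(kv[["baseline_monthly_rate"]]),
      county_effects = stats::setNames(
        as.numeric(vapply(ce_parts, `[`, "", 2L)),
        vapply(ce_parts, `[`, "", 1L)),
      temp_effect_knots = data.frame(temp_c = spl(kv[["temp_knots_c"]]),
                                     effect = spl(kv[["temp_knots_effect"]]))
    )
  }
  out
}

read_kv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
}
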