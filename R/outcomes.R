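# Outcome classification: ICD-9/ICD-10 underlying-cause codes -> psychoactive
# drug-related death categories (overdose / mental_behavioral /
# alcohol_induced) with an acute vs chronic subclass, plus aggregation of
# death records to county-month strata.

#' Default ICD code map for psychoactive drug-related deaths
#'
#' Prefix rules mapping underlying-cause codes to the three-part outcome
#' definition: poisoning by noxious substances (overdoses), mental and
#' behavioral disorders due to psychoactive substance use, and alcohol-induced
#' deaths. Based on the NCHS drug-overdose and alcohol-induced cause lists;
#' shipped as an editable CSV (`inst/extdata/icd_codemap_default.csv`) so the
#' lists can be replaced wholesale. Alcohol-poisoning codes (X45/X65/Y15) sit
#' under overdose by default; set `alcohol_poisoning_as_overdose = FALSE` to
#' move them to alcohol_induced.
#'
#' @param alcohol_poisoning_as_overdose Logical; see above.
#' @return Data frame of class `icd_codemap`: `icd_version` (9 or 10),
#'   `prefix` (uppercase, dots stripped; first match wins), `category`,
#'   `subclass`.
#' @export
default_codemap <- function(alcohol_poisoning_as_overdose = TRUE) {
  path <- system.file("extdata", "icd_codemap_default.csv",
                      package = "stormlag", mustWork = TRUE)
  map <- read_codemap(path)
  if (!alcohol_poisoning_as_overdose) {
    alc_pois <- map$prefix %in% c("X45", "X65", "Y15")
    map$category[alc_pois] <- "alcohol_induced"
    map$subclass[alc_pois] <- "chronic"
  }
  map
}

#' Read an ICD code map from delimited text
#'
#' @param path CSV with columns `icd_version`, `prefix`, `category`,
#'   `subclass`; rule order in the file is the match order.
#' @return Data frame of class `icd_codemap`.
#' @export
read_codemap <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(icd_version = "integer",
                                        prefix = "character",
                                        category = "character",
                                        subclass = "character"))
  map$prefix <- normalize_icd(map$prefix)
  ok_cat <- c("overdose", "mental_behavioral", "alcohol_induced", "other")
  if (!all(map$category %in% ok_cat)) stop("unknown category in code map")
  class(map) <- c("icd_codemap", class(map))
  map
}

normalize_icd <- function(code) {
  gsub("[. ]", "", toupper(as.character(code)))
}

#' Classify an ICD underlying-cause code
#'
#' Deterministic and total: codes are uppercased and dot-stripped, compared
#' prefix-wise against the map's rules for the given ICD revision in file
#' order (first match wins); unmatched codes fall through to
#' `("other", "none")`.
#'
#' @param code Character vector of ICD codes (e.g. `"F10.2"`, `"X42"`).
#' @param version Integer vector (9 or 10), recycled to `length(code)`.
#' @param map An `icd_codemap` (default [default_codemap()]).
#' @return Data frame `category`, `subclass`, one row per input code.
#' @examples
#' classify_icd(c("F10.2", "X42", "I21.0"), 10)
#' @export
classify_icd <- function(code, version, map = default_codemap()) {
  if (!length(code)) {
    return(data.frame(category = character(0), subclass = character(0)))
  }
  if (any(!nzchar(code))) stop("empty ICD code")
  if (!all(version %in% c(9L, 10L))) stop("unknown ICD version; must be 9 or 10")
  version <- rep_len(as.integer(version), length(code))
  codes <- normalize_icd(code)
  category <- rep("other", length(codes))
  subclass <- rep("none", length(codes))
  for (v in unique(version)) {
    rules <- map[map$icd_version == v, ]
    sel <- which(version == v)
    unmatched <- rep(TRUE, length(sel))
    for (r in seq_len(nrow(rules))) {
      if (!any(unmatched)) break
      hit <- unmatched & startsWith(codes[sel], rules$prefix[r])
      if (any(hit)) {
        category[sel[hit]] <- rules$category[r]
        subclass[sel[hit]] <- rules$subclass[r]
        unmatched[hit] <- FALSE
      }
    }
  }
  data.frame(category = category, subclass = subclass,
             stringsAsFactors = FALSE)
}

#' Aggregate death records to a county-month mortality panel
#'
#' Counts deaths by county-month, age group, sex and cause category. Records
#' classified `other` are tallied separately and excluded from the outcome
#' panel; records with unparseable age or sex are dropped with a warning.
#' Record conservation holds: classified + other + dropped = input records.
#'
#' @param records Data frame with `county_id`, `year`, `month`, `age_years`,
#'   `sex`, `icd_version`, `icd_code`.
#' @param map An `icd_codemap`.
#' @param origin_year Year whose January is month index 0 (default: earliest
#'   record year).
#' @return List: `panel` (data frame `county_id`, `month_index`, `age_group`,
#'   `sex`, `cause`, `subclass`, `deaths`), `n_classified`, `n_other`,
#'   `n_dropped`.
#' @export
aggregate_deaths <- function(records, map = default_codemap(),
                             origin_year = NULL) {
  empty <- data.frame(county_id = character(0), month_index = integer(0),
                      age_group = character(0), sex = character(0),
                      cause = character(0), subclass = character(0),
                      deaths = integer(0), stringsAsFactors = FALSE)
  if (!nrow(records)) {
    return(list(panel = empty, n_classified = 0L, n_other = 0L, n_dropped = 0L))
  }
  if (is.null(origin_year)) origin_year <- min(records$year)
  sex <- tolower(substr(as.character(records$sex), 1L, 1L))
  sex <- c(f = "female", m = "male")[sex]
  age_ok <- is.finite(records$age_years) & records$age_years >= 0
  keep <- !is.na(sex) & age_ok
  n_dropped <- sum(!keep)
  if (n_dropped) {
    warning(n_dropped, " record(s) dropped for unparseable age or sex")
  }
  r <- records[keep, ]
  sex <- sex[keep]
  cls <- classify_icd(r$icd_code, r$icd_version, map)
  n_other <- sum(cls$category == "other")
  inc <- cls$category != "other"
  r <- r[inc, ]
  if (!nrow(r)) {
    return(list(panel = empty, n_classified = 0L, n_other = n_other,
                n_dropped = n_dropped))
  }
  df <- data.frame(county_id = r$county_id,
                   month_index = month_index(r$year, r$month, origin_year),
                   age_group = age_to_group(r$age_years),
                   sex = sex[inc], cause = cls$category[inc],
                   subclass = cls$subclass[inc], stringsAsFactors = FALSE)
  key <- do.call(paste, c(df, sep = "\r"))
  cnt <- table(key)
  parts <- strsplit(names(cnt), "\r", fixed = TRUE)
  panel <- data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(panel) <- names(df)
  panel$month_index <- as.integer(panel$month_index)
  panel$deaths <- as.integer(cnt)
  panel <- panel[order(panel$county_id, panel$month_index, panel$age_group,
                       panel$sex, panel$cause), ]
  rownames(panel) <- NULL
  list(panel = panel, n_classified = nrow(df), n_other = n_other,
       n_dropped = n_dropped)
}

#' Descriptive summary of a mortality panel
#'
#' Totals and percentage shares (one decimal) by sex, age group and cause
#' label, as reported in descriptive mortality tables.
#'
#' @param panel Mortality panel with at least a `deaths` column and any of
#'   `sex`, `age_group`, `cause`.
#' @return Data frame `dimension`, `level`, `deaths`, `pct`.
#' @export
summarize_panel <- function(panel) {
  if (!nrow(panel) || sum(panel$deaths) == 0) stop("empty mortality panel")
  total <- sum(panel$deaths)
  dims <- intersect(c("sex", "age_group", "cause"), names(panel))
  rows <- lapply(dims, function(d) {
    tab <- rowsum(panel$deaths, panel[[d]])
    data.frame(dimension = d, level = rownames(tab), deaths = as.vector(tab),
               pct = round(100 * as.vector(tab) / total, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(data.frame(dimension = "total", level = "all",
                                          deaths = total, pct = 100.0)),
                          rows))
  rownames(out) <- NULL
  out
}
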