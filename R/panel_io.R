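# Panel data model: a dense (unit x calendar-day) grid of exposures and
# meteorology with weekday-only outcome counts, plus per-unit covariates.

#' Pollutant labels used throughout the package
#'
#' NO2, PM10 and PM2.5 are 24-h means; O3 is the 8-h daily maximum. All are
#' in micrograms per cubic metre.
#' @export
POLLUTANTS <- c("no2", "pm10", "pm25", "o3")

#' Name of the count column for an outcome group and age band
#'
#' Counts are stored in wide format, one column per (outcome group, age
#' band) pair, named `count__<group>__<age>`.
#'
#' @param outcome_group,age_band character labels (must not contain `__`).
#' @return column name string.
#' @export
count_column <- function(outcome_group, age_band) {
  if (any(grepl("__", c(outcome_group, age_band), fixed = TRUE)))
    abort_class("zinbpanel_schema_error",
                "outcome group / age band labels must not contain '__'")
  paste0("count__", outcome_group, "__", age_band)
}

#' Construct a panel dataset
#'
#' The single interchange object between all pipeline stages: a units table
#' (one row per small-area unit with its long-term covariates), a daily
#' table holding the dense exposure/meteorology grid and weekday outcome
#' counts, and the study metadata.
#'
#' @param units data.frame with columns `unit_id`, `pct_elderly`
#'   (percentage of residents aged 65 or over), `deprivation` (unitless
#'   deprivation score, higher = more deprived).
#' @param daily data.frame with columns `unit_id`, `date` (Date),
#'   `no2`, `pm10`, `pm25`, `o3` (ug/m3), `temperature` (degrees C),
#'   `humidity` (%), and one `count__<group>__<age>` column per outcome
#'   cell. Counts must be `NA` on weekend dates and non-negative integers
#'   on weekdays.
#' @param study_start,study_end study period (Date or ISO-8601 string).
#' @param age_bands,outcome_groups character vectors of labels; together
#'   they determine the expected count columns.
#' @param validate run [validate_panel()] (default `TRUE`).
#' @return an object of class `panel_dataset`.
#' @export
panel_dataset <- function(units, daily, study_start, study_end,
                          age_bands, outcome_groups, validate = TRUE) {
  units <- as.data.frame(units)
  daily <- as.data.frame(daily)
  daily$date <- as.Date(daily$date)
  x <- structure(
    list(units = units, daily = daily,
         study_start = as.Date(study_start), study_end = as.Date(study_end),
         age_bands = as.character(age_bands),
         outcome_groups = as.character(outcome_groups)),
    class = "panel_dataset")
  if (validate) validate_panel(x)
  x
}

#' @export
print.panel_dataset <- function(x, ...) {
  nd <- length(calendar_days(x$study_start, x$study_end))
  cat(sprintf(
    "panel_dataset: %d units x %d calendar days (%s..%s)\n  outcomes: %s\n  age bands: %s\n",
    nrow(x$units), nd, format(x$study_start), format(x$study_end),
    paste(x$outcome_groups, collapse = ", "),
    paste(x$age_bands, collapse = ", ")))
  invisible(x)
}

#' Validate a panel dataset against its invariants
#'
#' Checks: unique unit ids, `pct_elderly` in \[0,100\], a dense
#' unit-by-day grid over the study period, non-negative concentrations,
#' humidity in \[0,100\], unit ids consistent between tables, and counts
#' that are missing exactly on weekends and non-negative integers on
#' weekdays.
#'
#' @param x a `panel_dataset`.
#' @return `x`, invisibly; stops with a classed error on violation.
#' @export
validate_panel <- function(x) {
  stopifnot(inherits(x, "panel_dataset"))
  units <- x$units; daily <- x$daily
  need_u <- c("unit_id", "pct_elderly", "deprivation")
  miss <- setdiff(need_u, names(units))
  if (length(miss))
    abort_class("zinbpanel_schema_error",
                paste("units table missing column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(units$unit_id))
    abort_class("zinbpanel_integrity_error", "duplicate unit_id in units table")
  if (nrow(units) < 1L)
    abort_class("zinbpanel_integrity_error", "empty unit table")
  if (any(units$pct_elderly < 0 | units$pct_elderly > 100))
    abort_class("zinbpanel_integrity_error", "pct_elderly outside [0, 100]")

  cnt_cols <- as.vector(outer(x$outcome_groups, x$age_bands, count_column))
  need_d <- c("unit_id", "date", POLLUTANTS, "temperature", "humidity", cnt_cols)
  miss <- setdiff(need_d, names(daily))
  if (length(miss))
    abort_class("zinbpanel_schema_error",
                paste("daily table missing column(s):", paste(miss, collapse = ", ")))

  days <- calendar_days(x$study_start, x$study_end)
  if (nrow(daily) != nrow(units) * length(days))
    abort_class("zinbpanel_integrity_error",
                sprintf("daily table has %d rows; dense grid needs %d units x %d days = %d",
                        nrow(daily), nrow(units), length(days),
                        nrow(units) * length(days)))
  key <- paste(daily$unit_id, daily$date)
  if (anyDuplicated(key))
    abort_class("zinbpanel_integrity_error", "duplicate (unit_id, date) in daily table")
  if (!all(daily$unit_id %in% units$unit_id))
    abort_class("zinbpanel_integrity_error",
                paste("daily table has unit_id values absent from units table:",
                      paste(unique(setdiff(daily$unit_id, units$unit_id)), collapse = ", ")))
  if (!all(daily$date %in% days))
    abort_class("zinbpanel_integrity_error", "daily table has dates outside the study period")

  for (p in POLLUTANTS) {
    v <- daily[[p]]
    if (anyNA(v) || any(v < 0))
      abort_class("zinbpanel_integrity_error",
                  sprintf("%s concentrations must be complete and >= 0", p))
  }
  if (anyNA(daily$temperature))
    abort_class("zinbpanel_integrity_error", "temperature must be complete")
  if (anyNA(daily$humidity) || any(daily$humidity < 0 | daily$humidity > 100))
    abort_class("zinbpanel_integrity_error", "humidity must be complete and within [0, 100]")

  wk <- is_weekday(daily$date)
  for (cc in cnt_cols) {
    v <- daily[[cc]]
    if (any(!is.na(v[!wk])))
      abort_class("zinbpanel_integrity_error",
                  sprintf("%s has counts on weekend dates", cc))
    vw <- v[wk]
    if (anyNA(vw))
      abort_class("zinbpanel_integrity_error",
                  sprintf("%s has missing weekday counts", cc))
    if (any(vw < 0) || any(vw != round(vw)))
      abort_class("zinbpanel_integrity_error",
                  sprintf("%s weekday counts must be non-negative integers", cc))
  }
  invisible(x)
}

#' Number of weekdays in the study period
#'
#' Weekdays are Monday to Friday; public holidays are treated as ordinary
#' weekdays.
#' @param x a `panel_dataset`, or anything coercible by [as.Date()] of
#'   length 2 (start, end).
#' @return integer count of weekdays.
#' @export
n_study_weekdays <- function(x) {
  if (inherits(x, "panel_dataset")) {
    d <- calendar_days(x$study_start, x$study_end)
  } else {
    x <- as.Date(x)
    d <- calendar_days(x[1L], x[2L])
  }
  sum(is_weekday(d))
}

#' Read a panel dataset from its two CSV files
#'
#' Expects the layout written by [write_panel()]: a units CSV
#' (`unit_id,pct_elderly,deprivation`) and a long-format daily CSV with one
#' row per unit-day and wide count columns. Missing counts are encoded as
#' empty cells, never 0. Column names can be remapped through
#' `config$columns` (a named character vector `canonical = file_column`).
#'
#' @param units_path,daily_path CSV file paths.
#' @param config optional list with elements `columns` (name remapping),
#'   `age_bands`, `outcome_groups` (defaults inferred from the count
#'   columns present), and `weekday_only` (default `TRUE`: counts on a
#'   weekend date are an integrity error).
#' @return a validated `panel_dataset`.
#' @export
load_panel <- function(units_path, daily_path, config = NULL) {
  for (p in c(units_path, daily_path))
    if (!file.exists(p))
      abort_class("zinbpanel_io_error", paste("file not found:", p))
  units <- utils::read.csv(units_path, stringsAsFactors = FALSE)
  daily <- utils::read.csv(daily_path, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  remap <- config$columns
  if (!is.null(remap)) {
    for (canon in names(remap)) {
      for (df_name in c("units", "daily")) {
        df <- get(df_name)
        i <- match(remap[[canon]], names(df))
        if (!is.na(i)) { names(df)[i] <- canon; assign(df_name, df) }
      }
    }
  }
  if (!"date" %in% names(daily))
    abort_class("zinbpanel_schema_error", "daily table missing column(s): date")
  daily$date <- as.Date(daily$date)
  if (anyNA(daily$date))
    abort_class("zinbpanel_schema_error", "unparseable dates in daily table")

  cnt_cols <- grep("^count__", names(daily), value = TRUE)
  if (!length(cnt_cols))
    abort_class("zinbpanel_schema_error", "daily table has no count__<group>__<age> columns")
  parts <- strsplit(sub("^count__", "", cnt_cols), "__", fixed = TRUE)
  groups <- config$outcome_groups %||% unique(vapply(parts, `[`, "", 1L))
  ages   <- config$age_bands %||% unique(vapply(parts, `[`, "", 2L))

  panel_dataset(units, daily,
                study_start = config$study_start %||% min(daily$date),
                study_end   = config$study_end %||% max(daily$date),
                age_bands = ages, outcome_groups = groups)
}

#' Write a panel dataset to two CSV files
#'
#' The inverse of [load_panel()]: `load_panel()` on the written files
#' reproduces the dataset (bit-exact for integers, to within 1e-9 for
#' reals). Missing weekend counts are written as empty cells.
#'
#' @param panel a validated `panel_dataset`.
#' @param units_path,daily_path output CSV paths.
#' @return the two paths, invisibly.
#' @export
write_panel <- function(panel, units_path, daily_path) {
  validate_panel(panel)
  daily <- panel$daily
  daily$date <- format(daily$date, "%Y-%m-%d")
  tryCatch({
    utils::write.csv(panel$units, units_path, row.names = FALSE, na = "")
    utils::write.csv(daily, daily_path, row.names = FALSE, na = "")
  }, error = function(e) {
    abort_class("zinbpanel_io_error", paste("cannot write panel:", conditionMessage(e)))
  })
  invisible(c(units_path, daily_path))
}
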