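# Labelled fixed-effect design matrices: natural-spline confounder bases,
# day-of-week dummies, unit-level covariates, and the two exposure terms.

#' Natural cubic spline basis with quantile knots
#'
#' A natural (restricted) cubic spline basis with `df` columns: interior
#' knots at equally spaced quantiles of the observed values, boundary
#' knots at the minimum and maximum, second derivative zero beyond the
#' boundary (linear extrapolation). Thin wrapper over [splines::ns()],
#' which implements exactly this knot rule.
#'
#' @param x numeric vector with at least `df + 1` distinct values.
#' @param df number of basis columns (degrees of freedom).
#' @param label prefix for column names (`<label>_ns1`, ...).
#' @return numeric matrix with `df` labelled columns.
#' @export
natural_spline_basis <- function(x, df, label = "x") {
  if (df < 1L) abort_class("zinbpanel_input_error", "spline df must be >= 1")
  if (length(unique(x)) < df + 1L)
    abort_class("zinbpanel_input_error",
                sprintf("need at least %d distinct values for a %d-df natural spline",
                        df + 1L, df))
  b <- splines::ns(x, df = df)
  m <- unclass(b)
  attributes(m)[c("degree", "knots", "Boundary.knots", "intercept")] <- NULL
  dim(m) <- c(length(x), df)
  colnames(m) <- paste0(label, "_ns", seq_len(df))
  attr(m, "basis") <- b      # keeps knots; supports evaluation at new x
  m
}

#' Evaluate a natural spline basis at new values
#'
#' Uses the knots of a basis built by [natural_spline_basis()]; values
#' beyond the boundary knots are extrapolated linearly (the natural
#' boundary condition).
#'
#' @param basis a matrix from [natural_spline_basis()].
#' @param x new values.
#' @return matrix with the same columns as `basis`.
#' @export
predict_spline_basis <- function(basis, x) {
  b <- attr(basis, "basis")
  if (is.null(b))
    abort_class("zinbpanel_input_error", "not a natural_spline_basis() result")
  m <- stats::predict(b, x)
  colnames(m) <- colnames(basis)
  m
}

#' Day-of-week dummy variables
#'
#' Reference-coded dummies with Monday as the reference day. The dummy set
#' follows the days actually observed: a weekday-only panel yields 4
#' columns (Tue-Fri), a full-week panel yields 6.
#'
#' @param dates Date vector.
#' @param weekday_only if `TRUE` (default), a weekend date is an error.
#' @return numeric matrix with columns `wday_Tue`, ... (one per observed
#'   non-reference day).
#' @export
weekday_dummies <- function(dates, weekday_only = TRUE) {
  dates <- as.Date(dates)
  wd <- as.POSIXlt(dates)$wday            # 0 = Sunday
  if (weekday_only && any(!wd %in% 1:5))
    abort_class("zinbpanel_input_error",
                "weekend date in a weekday-only panel")
  lab <- c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")[wd + 1L]
  lev <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  lev <- lev[lev %in% lab]                 # observed days, Monday first
  f <- factor(lab, levels = lev)
  keep <- setdiff(lev, lev[1L])            # drop the reference level
  if (!length(keep))
    return(matrix(numeric(0), length(dates), 0L))
  m <- matrix(0, length(dates), length(keep),
              dimnames = list(NULL, paste0("wday_", keep)))
  for (d in keep) m[, paste0("wday_", d)] <- as.numeric(f == d)
  m
}

#' Default trend spline df: 6 per study year, at least 1
#' @noRd
default_trend_df <- function(n_days) max(1L, round(6 * n_days / 365.25))

# Shared core: assemble the labelled fixed-effect matrix for a set of
# weekday rows. Used both for fitting (build_design) and for simulating
# counts (so generating coefficients live in the fitted parameterization).
#' @noRd
design_core <- function(panel, dec, lag = "lag0", co = NULL,
                        trend_df = NULL, calendar = TRUE) {
  dates <- calendar_days(panel$study_start, panel$study_end)
  wk_dates <- dates[is_weekday(dates)]
  units <- panel$units$unit_id
  lagdev <- lag_deviation(dec, lag, calendar = calendar)
  jw <- match(format(wk_dates, "%Y-%m-%d"), colnames(lagdev))

  # long format: unit varies fastest within each date
  n_u <- length(units); n_d <- length(wk_dates)
  row_unit <- rep(seq_len(n_u), times = n_d)
  row_date <- rep(seq_len(n_d), each = n_u)
  short <- as.vector(lagdev[, jw, drop = FALSE])
  keep <- !is.na(short)
  row_unit <- row_unit[keep]; row_date <- row_date[keep]; short <- short[keep]

  # daily meteorology (shared across units within a day)
  met <- panel$daily[match(wk_dates, panel$daily$date), c("temperature", "humidity")]
  trend_idx <- as.integer(wk_dates - panel$study_start) + 1L
  if (is.null(trend_df)) trend_df <- default_trend_df(length(dates))

  temp <- met$temperature[row_date]
  hum <- met$humidity[row_date]
  trend <- trend_idx[row_date]
  X <- cbind(
    "(Intercept)" = 1,
    short = short,
    long = dec$unit_mean[row_unit],
    natural_spline_basis(temp, 3L, "temp"),
    natural_spline_basis(hum, 3L, "hum"),
    natural_spline_basis(trend, trend_df, "trend"),
    weekday_dummies(wk_dates[row_date]),
    pct_elderly = panel$units$pct_elderly[row_unit],
    deprivation = panel$units$deprivation[row_unit])
  colnames(X)[2:3] <- paste0(c("short_", "long_"), dec$pollutant)

  if (!is.null(co)) {
    co_lag <- lag_deviation(co, lag, calendar = calendar)
    co_short <- as.vector(co_lag[, jw, drop = FALSE])[keep]
    co_cols <- cbind(co_short, co$unit_mean[row_unit])
    colnames(co_cols) <- paste0(c("short_", "long_"), co$pollutant)
    X <- cbind(X, co_cols)
  }
  list(X = X,
       rows = data.frame(unit_id = units[row_unit],
                         date = wk_dates[row_date]),
       group = factor(units[row_unit], levels = units))
}

#' Build design matrices for the mixed ZINB model
#'
#' One row per (unit, weekday) with complete lag history. Count-part
#' columns: intercept, short-term exposure (lagged deviation), long-term
#' exposure (unit mean), natural splines for same-day temperature (3 df),
#' humidity (3 df) and time trend (6 df per study year by default),
#' day-of-week dummies (Monday reference), `pct_elderly` and
#' `deprivation`. An optional co-pollutant contributes its own short-term
#' (same lag) and long-term columns. The zero part is intercept-only by
#' default; `zero_covariates = TRUE` mirrors the count-part covariates.
#'
#' @param panel a `panel_dataset`.
#' @param decomposed a `decomposed_exposure` for the pollutant of interest.
#' @param lag a lag kind (see [lag_spec()]).
#' @param outcome_group,age_band labels selecting the outcome column.
#' @param co_pollutant optional `decomposed_exposure` for an adjustment
#'   pollutant.
#' @param trend_df trend spline df; default `round(6 * study years)`.
#' @param calendar lag over calendar days (default) or weekday positions.
#' @param zero_covariates mirror count-part covariates in the zero part.
#' @return object of class `design_matrices`: list with `X` (count part),
#'   `Z` (zero part), `y` (response), `group` (unit factor), `rows`
#'   (unit/date per row).
#' @export
build_design <- function(panel, decomposed, lag = "lag0",
                         outcome_group, age_band, co_pollutant = NULL,
                         trend_df = NULL, calendar = TRUE,
                         zero_covariates = FALSE) {
  stopifnot(inherits(panel, "panel_dataset"),
            inherits(decomposed, "decomposed_exposure"))
  cc <- count_column(outcome_group, age_band)
  if (!cc %in% names(panel$daily))
    abort_class("zinbpanel_input_error",
                sprintf("no counts for outcome '%s', age band '%s'",
                        outcome_group, age_band))
  core <- design_core(panel, decomposed, lag = lag, co = co_pollutant,
                      trend_df = trend_df, calendar = calendar)
  key_panel <- paste(panel$daily$unit_id, panel$daily$date)
  y <- panel$daily[[cc]][match(paste(core$rows$unit_id, core$rows$date), key_panel)]
  if (anyNA(y))
    abort_class("zinbpanel_integrity_error", "missing counts on design rows")

  qr_x <- qr(core$X, tol = 1e-8)
  if (qr_x$rank < ncol(core$X)) {
    bad <- colnames(core$X)[qr_x$pivot[(qr_x$rank + 1L):ncol(core$X)]]
    abort_class("zinbpanel_design_error",
                paste("rank-deficient design; dependent column(s):",
                      paste(bad, collapse = ", ")))
  }
  Z <- if (zero_covariates) core$X else
    matrix(1, nrow(core$X), 1L, dimnames = list(NULL, "(Intercept)"))
  structure(list(X = core$X, Z = Z, y = as.integer(y),
                 group = core$group, rows = core$rows,
                 pollutant = decomposed$pollutant, lag = lag,
                 outcome_group = outcome_group, age_band = age_band),
            class = "design_matrices")
}

#' @export
print.design_matrices <- function(x, ...) {
  cat(sprintf("design_matrices: %d rows x %d columns, %d units\n",
              nrow(x$X), ncol(x$X), nlevels(x$group)))
  cat("  columns:", paste(colnames(x$X), collapse = ", "), "\n")
  invisible(x)
}

#' Export a design matrix (with response and grouping) to CSV
#'
#' For external cross-checking of any fit.
#' @param design a `design_matrices`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_design <- function(design, path) {
  df <- data.frame(unit_id = design$rows$unit_id,
                   date = format(design$rows$date, "%Y-%m-%d"),
                   y = design$y, check.names = FALSE)
  df <- cbind(df, as.data.frame(design$X, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
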