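# Exposure decomposition into long-term (spatial) and short-term
# (temporal) components, lag construction, and IQR computation.

#' Decompose a pollutant series into unit means and daily deviations
#'
#' For each unit i the long-term component is the mean concentration over
#' every calendar day of the study period, `unit_mean[i]`; the short-term
#' component is the daily deviation `D[i, t] = X[i, t] - unit_mean[i]`.
#' The two add back to the observed series exactly, and per-unit deviation
#' means are zero to numerical precision. Deviations are kept for all
#' calendar days (weekends included) because lagged exposures of a Monday
#' reach back into the weekend.
#'
#' @param panel a `panel_dataset`.
#' @param pollutant one of `r paste(POLLUTANTS, collapse=", ")`.
#' @return object of class `decomposed_exposure`: list with `pollutant`,
#'   `unit_mean` (named numeric), `deviation` (units x days matrix with
#'   ISO dates as column names), `dates`.
#' @export
decompose_exposure <- function(panel, pollutant) {
  stopifnot(inherits(panel, "panel_dataset"))
  if (!pollutant %in% POLLUTANTS)
    abort_class("zinbpanel_input_error",
                sprintf("unknown pollutant '%s'; valid labels: %s",
                        pollutant, paste(POLLUTANTS, collapse = ", ")))
  dates <- calendar_days(panel$study_start, panel$study_end)
  units <- panel$units$unit_id
  d <- panel$daily
  # dense grid guaranteed by validate_panel(); reshape to units x days
  i <- match(d$unit_id, units)
  j <- match(d$date, dates)
  conc <- matrix(NA_real_, length(units), length(dates),
                 dimnames = list(units, format(dates, "%Y-%m-%d")))
  conc[cbind(i, j)] <- d[[pollutant]]
  um <- rowMeans(conc)
  dev <- conc - um
  structure(list(pollutant = pollutant, unit_mean = um,
                 deviation = dev, dates = dates),
            class = "decomposed_exposure")
}

#' Lag specifications
#'
#' The four exposure timings used in reporting: same day (`lag0`),
#' previous day (`lag1`), two days before (`lag2`), and the mean of the
#' index day and the six preceding calendar days (`week_avg`).
#' @export
LAG_KINDS <- c("lag0", "lag1", "lag2", "week_avg")

#' Validate a lag specification
#' @param kind one of [LAG_KINDS].
#' @return the kind, validated.
#' @export
lag_spec <- function(kind) {
  kind <- match.arg(kind, LAG_KINDS)
  kind
}

#' Apply a lag to one unit's deviation series
#'
#' `lag1`/`lag2` shift the series by 1/2 calendar days; `week_avg` at day t
#' is the mean of the deviations on days t, t-1, ..., t-6. Days with
#' incomplete lag history are returned as `NA`; downstream, the matching
#' weekday outcome rows are dropped from model fitting. By default lags
#' run over calendar days (a Monday lag-1 is Sunday); `calendar = FALSE`
#' shifts within the supplied series positions instead (weekday-only
#' shifting, provided for sensitivity analyses).
#'
#' @param x numeric deviation series for one unit.
#' @param spec a lag kind (see [lag_spec()]).
#' @param dates Date vector aligned with `x`; with `calendar = TRUE` it
#'   must be consecutive calendar days.
#' @param calendar logical; see above.
#' @return numeric vector like `x` with `NA` where history is incomplete.
#' @export
apply_lag <- function(x, spec, dates = NULL, calendar = TRUE) {
  spec <- lag_spec(spec)
  x <- as.numeric(x)
  if (calendar) {
    if (is.null(dates))
      abort_class("zinbpanel_input_error", "apply_lag(): dates required when calendar = TRUE")
    if (length(dates) != length(x))
      abort_class("zinbpanel_input_error", "apply_lag(): dates and series lengths differ")
    if (length(dates) > 1L && any(diff(as.Date(dates)) != 1L))
      abort_class("zinbpanel_input_error",
                  "apply_lag(): date index must be consecutive calendar days")
  }
  n <- length(x)
  shift <- function(k) c(rep(NA_real_, min(k, n)), x[seq_len(max(n - k, 0L))])
  switch(spec,
    lag0 = x,
    lag1 = shift(1L),
    lag2 = shift(2L),
    week_avg = {
      if (n < 7L) rep(NA_real_, n)
      else as.numeric(stats::filter(x, rep(1 / 7, 7L), sides = 1L))
    })
}

#' Lagged deviation matrix for a decomposed exposure
#' @noRd
lag_deviation <- function(dec, spec, calendar = TRUE) {
  m <- t(apply(dec$deviation, 1L, function(r)
    apply_lag(r, spec, dates = dec$dates, calendar = calendar)))
  dimnames(m) <- dimnames(dec$deviation)
  m
}

#' Temporal and spatial IQRs of pollutant concentrations
#'
#' The temporal IQR is the interquartile range of the daily area-average
#' concentration series (unweighted mean over units, one value per
#' calendar day); the spatial IQR is the interquartile range of the
#' per-unit study-period means. Both use the linear-interpolation quantile
#' convention ([iqr_linear()]). The temporal IQR scales short-term
#' effects; the spatial IQR scales long-term effects.
#'
#' @param panel a `panel_dataset`.
#' @param pollutants pollutant labels (default all four).
#' @return data.frame with columns `pollutant`, `temporal_iqr`,
#'   `spatial_iqr`, plus the quartiles each is built from.
#' @export
compute_iqrs <- function(panel, pollutants = POLLUTANTS) {
  rows <- lapply(pollutants, function(p) {
    dec <- decompose_exposure(panel, p)
    conc <- dec$deviation + dec$unit_mean
    day_avg <- colMeans(conc)
    if (length(day_avg) < 4L || length(dec$unit_mean) < 4L)
      abort_class("zinbpanel_input_error",
                  "compute_iqrs(): need at least 4 days and 4 units")
    qt <- stats::quantile(day_avg, c(.25, .5, .75), type = 7, names = FALSE)
    qs <- stats::quantile(dec$unit_mean, c(.25, .5, .75), type = 7, names = FALSE)
    data.frame(pollutant = p,
               temporal_q1 = qt[1], temporal_q3 = qt[3],
               temporal_iqr = qt[3] - qt[1],
               spatial_q1 = qs[1], spatial_q3 = qs[3],
               spatial_iqr = qs[3] - qs[1])
  })
  do.call(rbind, rows)
}
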