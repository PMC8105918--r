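# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
is_weekday <- function(dates) {
  as.POSIXlt(dates)$wday %in% 1:5
}

#' Sequence of calendar days between two dates (inclusive)
#' @noRd
calendar_days <- function(start, end) {
  seq(as.Date(start), as.Date(end), by = "day")
}

#' Row-wise log-sum-exp of a matrix
#' @noRd
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Interquartile range under the linear-interpolation quantile convention
#'
#' Quantiles are computed by linear interpolation between order statistics
#' (type 7). This single definition is used everywhere an IQR appears so
#' that effect scaling, tables and plots share one convention.
#'
#' @param x numeric vector (length >= 4, no missing values).
#' @return `Q3 - Q1` as a single number.
#' @export
iqr_linear <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("iqr_linear(): missing values in input")
  if (length(x) < 4L) stop("iqr_linear(): need at least 4 values")
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2L] - q[1L]
}

#' Stop with a classed error (so callers can distinguish failure modes)
#' @noRd
abort_class <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Check a correlation matrix: symmetric, unit diagonal, PSD
#' @noRd
check_corr_matrix <- function(m, what) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    abort_class("zinbpanel_config_error", sprintf("%s must be a square matrix", what))
  if (max(abs(m - t(m))) > 1e-8)
    abort_class("zinbpanel_config_error", sprintf("%s must be symmetric", what))
  if (max(abs(diag(m) - 1)) > 1e-8)
    abort_class("zinbpanel_config_error", sprintf("%s must have unit diagonal", what))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    abort_class("zinbpanel_config_error",
                sprintf("%s is not positive semi-definite (min eigenvalue %.3g)",
                        what, min(ev)))
  invisible(m)
}
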