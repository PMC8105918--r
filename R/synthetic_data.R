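# Seeded generators for exposure fields, meteorology, unit covariates and
# ZINB counts, composed into a full synthetic study.

# Standardized skew transform: maps a standard Gaussian series G to a
# mean-0, SD-1 series with log-normal right skew `a` (a = 0 passes G
# through unchanged). The transformed series is bounded below by
# -1/sqrt(exp(a^2) - 1), which keeps concentrations positive.
#' @noRd
skew_transform <- function(G, a) {
  if (a == 0) return(G)
  m1 <- exp(a^2 / 2)
  s1 <- m1 * sqrt(exp(a^2) - 1)
  (exp(a * G) - m1) / s1
}

# Stationary AR(1) with standard normal marginals, innovations `Z`.
#' @noRd
ar1_filter <- function(Z, rho) {
  if (rho == 0) return(Z)
  n <- if (is.matrix(Z)) nrow(Z) else length(Z)
  scale <- sqrt(1 - rho^2)
  if (is.matrix(Z)) {
    G <- Z
    for (t in 2:n) G[t, ] <- rho * G[t - 1L, ] + scale * Z[t, ]
    G
  } else {
    as.numeric(stats::filter(c(Z[1L] / scale, Z[-1L]) * scale,
                             rho, method = "recursive"))
  }
}

#' @noRd
seasonal_wave <- function(dates, amplitude, peak_doy) {
  doy <- as.POSIXlt(dates)$yday + 1L
  amplitude * cos(2 * pi * (doy - peak_doy) / 365.25)
}

#' Generate pollutant concentration fields
#'
#' Simulates `X[i, t] = mean + S_i + T_t + eps[i, t]` per pollutant (see
#' [exposure_field_config()]): `S_i` spatially correlated unit effects,
#' `T_t` a seasonal sinusoid plus a cross-pollutant-correlated AR(1)
#' signal passed through a standardized log-normal skew transform, `eps`
#' independent unit-level noise. Negative values are clipped at 0; the
#' clip rate per pollutant is attached as attribute `clip_rate`.
#'
#' @param cfg an [exposure_field_config()].
#' @param n_units number of units.
#' @param dates Date vector of consecutive calendar days.
#' @param seed RNG seed (`NULL` continues the current RNG stream).
#' @return named list of `n_units x length(dates)` matrices, one per
#'   pollutant, with attribute `clip_rate`.
#' @export
generate_exposure_fields <- function(cfg, n_units, dates, seed = NULL) {
  stopifnot(inherits(cfg, "exposure_field_config"))
  if (!is.null(seed)) set.seed(seed)
  pols <- cfg$pollutants
  K <- length(pols); Tn <- length(dates)
  Lt <- chol_psd(cfg$temporal_cor)
  Ls <- chol_psd(cfg$spatial_cor)

  Z <- matrix(stats::rnorm(Tn * K), Tn, K) %*% Lt
  G <- ar1_filter(Z, cfg$ar1)
  S <- matrix(stats::rnorm(n_units * K), n_units, K) %*% Ls
  out <- vector("list", K); names(out) <- pols
  clip <- stats::setNames(numeric(K), pols)
  for (k in seq_len(K)) {
    p <- pols[k]
    amp <- cfg$seasonal_amplitude[p]
    sd_a <- sqrt(max(cfg$temporal_sd[p]^2 - amp^2 / 2, 0))
    Tt <- seasonal_wave(dates, amp, cfg$peak_doy) +
      sd_a * skew_transform(G[, k], cfg$log_skew[p])
    Si <- S[, k] * cfg$spatial_sd[p]
    eps_sd <- cfg$unit_noise_frac * cfg$temporal_sd[p]
    X <- cfg$mean[p] + outer(Si, Tt, `+`) +
      matrix(stats::rnorm(n_units * Tn, sd = eps_sd), n_units, Tn)
    clip[p] <- mean(X < 0)
    X[X < 0] <- 0
    colnames(X) <- format(dates, "%Y-%m-%d")
    out[[p]] <- X
  }
  attr(out, "clip_rate") <- clip
  out
}

# Cholesky factor tolerant of semi-definite matrices.
#' @noRd
chol_psd <- function(m) {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  ev <- eigen(m, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-10)
  chol(ev$vectors %*% (lam * t(ev$vectors)) + diag(1e-10, nrow(m)))
}

#' Generate daily meteorology (shared across units)
#'
#' Temperature and relative humidity as annual sinusoids plus AR(1)
#' noise, humidity clipped to \[0, 100\].
#'
#' @param cfg a [meteorology_config()].
#' @param dates Date vector.
#' @param seed RNG seed (`NULL` continues the current stream).
#' @return data.frame with `date`, `temperature`, `humidity`.
#' @export
generate_meteorology <- function(cfg, dates, seed = NULL) {
  stopifnot(inherits(cfg, "meteorology_config"))
  if (!is.null(seed)) set.seed(seed)
  Tn <- length(dates)
  noise <- function(total_sd, amp, rho) {
    sd_n <- sqrt(max(total_sd^2 - amp^2 / 2, 0))
    sd_n * ar1_filter(stats::rnorm(Tn), rho)
  }
  temp <- cfg$temp_mean +
    seasonal_wave(dates, cfg$temp_amplitude, cfg$peak_doy) +
    noise(cfg$temp_sd, cfg$temp_amplitude, cfg$temp_ar1)
  hum <- cfg$hum_mean +
    seasonal_wave(dates, cfg$hum_amplitude, cfg$peak_doy) +
    noise(cfg$hum_sd, cfg$hum_amplitude, cfg$hum_ar1)
  hum <- pmin(pmax(hum, 0), 100)
  data.frame(date = dates, temperature = temp, humidity = hum)
}

#' Generate per-unit covariates
#'
#' @param cfg a [unit_covariate_config()].
#' @param n_units number of units.
#' @param seed RNG seed (`NULL` continues the current stream).
#' @return data.frame with `unit_id`, `pct_elderly`, `deprivation`.
#' @export
generate_unit_covariates <- function(cfg, n_units, seed = NULL) {
  stopifnot(inherits(cfg, "unit_covariate_config"))
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    unit_id = sprintf("U%03d", seq_len(n_units)),
    pct_elderly = pmin(pmax(stats::rnorm(n_units, cfg$pct_elderly_mean,
                                         cfg$pct_elderly_sd), 0), 100),
    deprivation = pmax(stats::rnorm(n_units, cfg$deprivation_mean,
                                    cfg$deprivation_sd), 1))
}

# Skeleton panel (zero counts) used to assemble the generating design in
# exactly the parameterization build_design() fits.
#' @noRd
panel_skeleton <- function(exposures, meteorology, units, dates,
                           age_bands = "all", outcome_groups = "respiratory") {
  n_u <- nrow(units); Tn <- length(dates)
  wk <- is_weekday(dates)
  daily <- data.frame(
    unit_id = rep(units$unit_id, times = Tn),
    date = rep(dates, each = n_u))
  for (p in names(exposures))
    daily[[p]] <- as.vector(exposures[[p]])        # unit varies fastest
  mi <- rep(seq_len(Tn), each = n_u)
  daily$temperature <- meteorology$temperature[mi]
  daily$humidity <- meteorology$humidity[mi]
  for (g in outcome_groups) for (a in age_bands)
    daily[[count_column(g, a)]] <- ifelse(rep(wk, each = n_u), 0L, NA_integer_)
  panel_dataset(units, daily, min(dates), max(dates),
                age_bands = age_bands, outcome_groups = outcome_groups,
                validate = FALSE)
}

# Assemble the generating coefficient vector in design-column order.
#' @noRd
true_beta_vector <- function(params, labels, pollutant) {
  trend_cols <- grep("^trend_ns", labels, value = TRUE)
  trend <- params$trend %||% rep(0, length(trend_cols))
  if (length(trend) != length(trend_cols))
    abort_class("zinbpanel_config_error",
                sprintf("trend has %d coefficients but the design needs %d",
                        length(trend), length(trend_cols)))
  beta <- stats::setNames(numeric(length(labels)), labels)
  beta["(Intercept)"] <- params$beta0
  beta[paste0("short_", pollutant)] <- params$beta_short
  beta[paste0("long_", pollutant)] <- params$beta_long
  beta[paste0("temp_ns", 1:3)] <- params$temp
  beta[paste0("hum_ns", 1:3)] <- params$humidity
  beta[trend_cols] <- trend
  beta[paste0("wday_", c("Tue", "Wed", "Thu", "Fri"))] <- params$weekday
  beta["pct_elderly"] <- params$pct_elderly
  beta["deprivation"] <- params$deprivation
  beta
}

#' Generate weekday counts from the mixed ZINB model
#'
#' Draws `b_i ~ N(0, sigma_b^2)` once per unit; for each weekday computes
#' `mu_it = exp(beta0 + b_i + beta_S (X_it - Xbar_i) + beta_L Xbar_i +
#' confounder terms)` with confounders in the same spline/dummy
#' parameterization as [build_design()]; emits a structural zero with
#' probability `pi = plogis(gamma0)`, otherwise a draw from
#' `NegBin(mu_it, theta)`. Counts exist only on weekdays.
#'
#' @param exposures list of unit-by-day concentration matrices (from
#'   [generate_exposure_fields()]).
#' @param meteorology data.frame from [generate_meteorology()].
#' @param units data.frame from [generate_unit_covariates()].
#' @param params a [true_model_params()].
#' @param dates the calendar days spanned by `exposures`.
#' @param seed RNG seed (`NULL` continues the current stream).
#' @param trend_df trend spline df (default 6 per study year).
#' @return `n_units x n_weekdays` integer matrix of counts (unit ids as
#'   row names, ISO dates as column names), with the generating
#'   coefficient vector attached as attribute `true_beta`.
#' @export
generate_counts <- function(exposures, meteorology, units, params, dates,
                            seed = NULL, trend_df = NULL) {
  stopifnot(inherits(params, "true_model_params"))
  skel <- panel_skeleton(exposures, meteorology, units, dates)
  dec <- decompose_exposure(skel, params$pollutant)
  core <- design_core(skel, dec, lag = "lag0", trend_df = trend_df)
  sample_counts_from_core(core, units, params, dates, seed = seed)
}

# Count sampling given a prebuilt generating design (shared across
# outcome cells in generate_study).
#' @noRd
sample_counts_from_core <- function(core, units, params, dates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  beta <- true_beta_vector(params, colnames(core$X), params$pollutant)
  b <- stats::rnorm(nrow(units), 0, params$sigma_b)
  eta <- drop(core$X %*% beta) + b[as.integer(core$group)]
  if (max(eta) > 30)
    abort_class("zinbpanel_generation_error",
                sprintf("linear predictor reaches %.1f (> 30); rescale parameters",
                        max(eta)))
  pi0 <- if (is.finite(params$gamma0)) stats::plogis(params$gamma0) else 0
  y <- rzinb(length(eta), mu = exp(eta), theta = params$theta, pi = pi0)
  wk_dates <- dates[is_weekday(dates)]
  cm <- matrix(NA_integer_, nrow(units), length(wk_dates),
               dimnames = list(units$unit_id, format(wk_dates, "%Y-%m-%d")))
  idx <- cbind(as.integer(core$group),
               match(format(core$rows$date, "%Y-%m-%d"), colnames(cm)))
  cm[idx] <- y
  attr(cm, "true_beta") <- beta
  attr(cm, "random_intercepts") <- b
  cm
}

#' Generate a complete synthetic study
#'
#' Composes the exposure, meteorology, unit-covariate and count
#' generators under seeds derived from `cfg$seed`; the same configuration
#' and seed always produce an identical dataset. The generating
#' parameters are attached for recovery testing.
#'
#' @param cfg a [study_config()] (see [desk_config()],
#'   [lambeth_like_config()]).
#' @return a validated `panel_dataset` with attributes `true_params`
#'   (nested list: for each outcome cell, the `true_model_params` plus
#'   the full generating coefficient vector `beta` in design order),
#'   `clip_rate`, and `config`.
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  base <- cfg$seed %% 2000000000L
  dates <- calendar_days(cfg$start, cfg$end)
  exposures <- generate_exposure_fields(cfg$exposure, cfg$n_units, dates,
                                        seed = base + 1L)
  met <- generate_meteorology(cfg$meteorology, dates, seed = base + 2L)
  units <- generate_unit_covariates(cfg$unit_covariates, cfg$n_units,
                                    seed = base + 3L)
  skel <- panel_skeleton(exposures, met, units, dates,
                         age_bands = cfg$age_bands,
                         outcome_groups = cfg$outcome_groups)
  daily <- skel$daily
  wk <- is_weekday(dates)
  cores <- list()          # generating design, cached per causal pollutant
  true_params <- list()
  cell <- 0L
  for (g in cfg$outcome_groups) for (a in cfg$age_bands) {
    cell <- cell + 1L
    pars <- cfg$params[[g]][[a]]
    pol <- pars$pollutant
    if (is.null(cores[[pol]])) {
      cores[[pol]] <- design_core(skel, decompose_exposure(skel, pol),
                                  lag = "lag0")
    }
    cm <- sample_counts_from_core(cores[[pol]], units, pars, dates,
                                  seed = base + 10L + cell)
    col <- rep(NA_integer_, nrow(daily))
    # daily rows: unit varies fastest within date
    widx <- which(rep(wk, each = cfg$n_units))
    col[widx] <- as.vector(cm)
    daily[[count_column(g, a)]] <- col
    true_params[[g]][[a]] <- c(pars,
                               list(beta = attr(cm, "true_beta"),
                                    pi0 = if (is.finite(pars$gamma0))
                                      stats::plogis(pars$gamma0) else 0))
  }
  panel <- panel_dataset(units, daily, cfg$start, cfg$end,
                         age_bands = cfg$age_bands,
                         outcome_groups = cfg$outcome_groups)
  attr(panel, "true_params") <- true_params
  attr(panel, "clip_rate") <- attr(exposures, "clip_rate")
  attr(panel, "config") <- cfg
  panel
}
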