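# Configuration objects for the synthetic study generator, plus the two
# shipped presets (a full-scale borough-like study and a small desk-scale
# study for fast validation runs).

#' Exposure field configuration
#'
#' Controls the generative model for pollutant concentration fields:
#' `X[i, t] = mean + S_i + T_t + eps[i, t]`, where `S_i` are
#' cross-pollutant-correlated unit effects (the spatial component), `T_t`
#' is an area-wide daily signal made of an annual sinusoid plus a
#' skew-transformed AR(1) process correlated across pollutants (the
#' temporal component), and `eps` is independent unit-level noise.
#' Negative concentrations are clipped at 0 and the clip rate is recorded.
#'
#' @param mean,temporal_sd,spatial_sd named numeric vectors (one entry per
#'   pollutant): overall mean, SD of the daily area-average deviations,
#'   and SD of the unit long-term means, all in ug/m3.
#' @param seasonal_amplitude named vector; positive values peak in summer
#'   (day-of-year `peak_doy`), negative in winter. Bounded by
#'   `amplitude^2/2 <= temporal_sd^2`.
#' @param ar1 AR(1) coefficient of the daily signal, in (-1, 1).
#' @param log_skew named vector of log-normal skew parameters (>= 0) for
#'   the non-seasonal daily signal; 0 gives a Gaussian signal, larger
#'   values give the right-skewed, strictly bounded-below marginals of
#'   real concentration series.
#' @param unit_noise_frac unit-level temporal noise SD as a fraction of
#'   the temporal SD (default 0.1).
#' @param temporal_cor,spatial_cor cross-pollutant correlation matrices
#'   (symmetric, unit diagonal, positive semi-definite), in `pollutants`
#'   order.
#' @param pollutants pollutant labels (default the package's four).
#' @param peak_doy day of year where positive seasonal amplitudes peak.
#' @return object of class `exposure_field_config`.
#' @export
exposure_field_config <- function(mean, temporal_sd, spatial_sd,
                                  seasonal_amplitude, ar1 = 0.7,
                                  log_skew = NULL, unit_noise_frac = 0.1,
                                  temporal_cor = diag(length(pollutants)),
                                  spatial_cor = diag(length(pollutants)),
                                  pollutants = POLLUTANTS,
                                  peak_doy = 172) {
  k <- length(pollutants)
  pick <- function(v, what) {
    if (is.null(names(v))) {
      if (length(v) == 1L) v <- rep(v, k) else if (length(v) != k)
        abort_class("zinbpanel_config_error", paste(what, "has wrong length"))
      names(v) <- pollutants
    }
    v <- v[pollutants]
    if (anyNA(v)) abort_class("zinbpanel_config_error",
                              paste(what, "missing for some pollutant"))
    v
  }
  mean <- pick(mean, "mean"); temporal_sd <- pick(temporal_sd, "temporal_sd")
  spatial_sd <- pick(spatial_sd, "spatial_sd")
  seasonal_amplitude <- pick(seasonal_amplitude, "seasonal_amplitude")
  log_skew <- pick(log_skew %||% 0, "log_skew")
  if (any(temporal_sd < 0) || any(spatial_sd < 0))
    abort_class("zinbpanel_config_error", "SDs must be >= 0")
  if (any(log_skew < 0))
    abort_class("zinbpanel_config_error", "log_skew must be >= 0")
  if (abs(ar1) >= 1)
    abort_class("zinbpanel_config_error", "ar1 must be in (-1, 1)")
  if (any(seasonal_amplitude^2 / 2 > temporal_sd^2 + 1e-12))
    abort_class("zinbpanel_config_error",
                "seasonal amplitude exceeds the temporal SD budget")
  temporal_cor <- as.matrix(temporal_cor); spatial_cor <- as.matrix(spatial_cor)
  dimnames(temporal_cor) <- dimnames(spatial_cor) <- list(pollutants, pollutants)
  check_corr_matrix(temporal_cor, "temporal_cor")
  check_corr_matrix(spatial_cor, "spatial_cor")
  structure(list(pollutants = pollutants, mean = mean,
                 temporal_sd = temporal_sd, spatial_sd = spatial_sd,
                 seasonal_amplitude = seasonal_amplitude, ar1 = ar1,
                 log_skew = log_skew, unit_noise_frac = unit_noise_frac,
                 temporal_cor = temporal_cor, spatial_cor = spatial_cor,
                 peak_doy = peak_doy),
            class = "exposure_field_config")
}

#' Meteorology configuration
#'
#' Daily temperature and relative humidity shared across units: an annual
#' sinusoid plus AR(1) noise. The `*_sd` values are the target marginal
#' SDs (sinusoid plus noise combined); humidity is clipped to \[0, 100\].
#'
#' @param temp_mean,temp_sd,temp_amplitude,temp_ar1 temperature (deg C).
#' @param hum_mean,hum_sd,hum_amplitude,hum_ar1 relative humidity (%);
#'   a negative amplitude peaks in winter.
#' @param peak_doy day of year of the positive seasonal peak.
#' @return object of class `meteorology_config`.
#' @export
meteorology_config <- function(temp_mean = 11.0, temp_sd = 5.7,
                               temp_amplitude = 7.0, temp_ar1 = 0.8,
                               hum_mean = 77.2, hum_sd = 10.1,
                               hum_amplitude = -5.0, hum_ar1 = 0.5,
                               peak_doy = 196) {
  if (temp_sd < 0 || hum_sd < 0)
    abort_class("zinbpanel_config_error", "SDs must be >= 0")
  if (temp_amplitude^2 / 2 > temp_sd^2 || hum_amplitude^2 / 2 > hum_sd^2)
    abort_class("zinbpanel_config_error",
                "seasonal amplitude exceeds the SD budget")
  structure(list(temp_mean = temp_mean, temp_sd = temp_sd,
                 temp_amplitude = temp_amplitude, temp_ar1 = temp_ar1,
                 hum_mean = hum_mean, hum_sd = hum_sd,
                 hum_amplitude = hum_amplitude, hum_ar1 = hum_ar1,
                 peak_doy = peak_doy),
            class = "meteorology_config")
}

#' Unit covariate configuration
#'
#' Per-unit percentage of elderly residents (clipped to \[0, 100\]) and a
#' deprivation score (clipped at 0), drawn independently across units.
#' @param pct_elderly_mean,pct_elderly_sd,deprivation_mean,deprivation_sd
#'   normal moments for the two covariates.
#' @return object of class `unit_covariate_config`.
#' @export
unit_covariate_config <- function(pct_elderly_mean = 9, pct_elderly_sd = 4,
                                  deprivation_mean = 25, deprivation_sd = 8) {
  structure(as.list(environment()), class = "unit_covariate_config")
}

#' True model parameters for the count generator
#'
#' Houses every coefficient of the generative mixed ZINB model. The
#' confounder coefficients are expressed in the same natural-spline /
#' dummy parameterization that [build_design()] produces, so the
#' generating coefficients are directly comparable with fitted ones.
#'
#' @param beta0 intercept (log expected count per unit-day at covariates
#'   0).
#' @param beta_short short-term coefficient, per ug/m3 of same-day
#'   deviation from the unit mean.
#' @param beta_long long-term coefficient, per ug/m3 of unit mean.
#' @param pollutant the causal pollutant the two coefficients act on.
#' @param temp,humidity length-3 natural-spline coefficient vectors.
#' @param trend trend-spline coefficients (`NULL` = all zero).
#' @param weekday length-4 coefficients for Tue-Fri (Monday reference).
#' @param pct_elderly,deprivation unit-covariate coefficients.
#' @param gamma0 zero-inflation intercept on the logit scale.
#' @param theta negative binomial dispersion (> 0).
#' @param sigma_b random-intercept SD (>= 0).
#' @return object of class `true_model_params`.
#' @export
true_model_params <- function(beta0, beta_short = 0, beta_long = 0,
                              pollutant = "pm10",
                              temp = c(0, 0, 0), humidity = c(0, 0, 0),
                              trend = NULL, weekday = c(0, 0, 0, 0),
                              pct_elderly = 0, deprivation = 0,
                              gamma0 = -Inf, theta = 1, sigma_b = 0) {
  if (theta <= 0) abort_class("zinbpanel_config_error", "theta must be > 0")
  if (sigma_b < 0) abort_class("zinbpanel_config_error", "sigma_b must be >= 0")
  if (!pollutant %in% POLLUTANTS)
    abort_class("zinbpanel_config_error", paste("unknown pollutant", pollutant))
  if (length(temp) != 3L || length(humidity) != 3L)
    abort_class("zinbpanel_config_error", "temp/humidity need 3 spline coefficients")
  if (length(weekday) != 4L)
    abort_class("zinbpanel_config_error", "weekday needs 4 coefficients (Tue-Fri)")
  structure(as.list(environment()), class = "true_model_params")
}

#' Study configuration for the synthetic generator
#'
#' @param n_units number of small-area units (>= 2).
#' @param start,end study period; the span must cover at least 8 weeks so
#'   week-average lags and spline bases are estimable.
#' @param exposure an [exposure_field_config()].
#' @param meteorology a [meteorology_config()].
#' @param unit_covariates a [unit_covariate_config()].
#' @param params either a single [true_model_params()] (applied to every
#'   outcome cell) or a nested list `params[[outcome_group]][[age_band]]`.
#' @param age_bands,outcome_groups cell labels.
#' @param seed base RNG seed; stage seeds are derived from it.
#' @param name preset name (metadata only).
#' @return object of class `study_config`.
#' @export
study_config <- function(n_units, start, end, exposure, meteorology,
                         unit_covariates, params,
                         age_bands = "all", outcome_groups = "respiratory",
                         seed = 1L, name = "custom") {
  start <- as.Date(start); end <- as.Date(end)
  if (n_units < 2L) abort_class("zinbpanel_config_error", "n_units must be >= 2")
  if (as.integer(end - start) + 1L < 56L)
    abort_class("zinbpanel_config_error", "study span must be at least 8 weeks")
  stopifnot(inherits(exposure, "exposure_field_config"),
            inherits(meteorology, "meteorology_config"),
            inherits(unit_covariates, "unit_covariate_config"))
  if (inherits(params, "true_model_params")) {
    params <- stats::setNames(lapply(outcome_groups, function(g)
      stats::setNames(lapply(age_bands, function(a) params), age_bands)),
      outcome_groups)
  }
  for (g in outcome_groups) for (a in age_bands)
    if (!inherits(params[[g]][[a]], "true_model_params"))
      abort_class("zinbpanel_config_error",
                  sprintf("missing true_model_params for (%s, %s)", g, a))
  structure(list(n_units = as.integer(n_units), start = start, end = end,
                 exposure = exposure, meteorology = meteorology,
                 unit_covariates = unit_covariates, params = params,
                 age_bands = age_bands, outcome_groups = outcome_groups,
                 seed = as.integer(seed), name = name),
            class = "study_config")
}

#' Load a study configuration from a YAML preset file
#'
#' See the two shipped presets (`inst/extdata/lambeth_like.yaml`,
#' `inst/extdata/desk.yaml`) for the schema. Intercepts may be given
#' either directly (`beta0`) or via per-cell target mean counts per
#' unit-day (`daily_mean`), in which case
#' `beta0 = log(mean / (1 - pi)) - sigma_b^2 / 2` so the marginal mean
#' count matches the target to first order.
#'
#' @param path YAML file.
#' @param seed optional seed override.
#' @return a `study_config`.
#' @export
load_study_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  pols <- y$exposure$pollutants %||% POLLUTANTS
  unl <- function(x) unlist(x)
  expo <- exposure_field_config(
    mean = unl(y$exposure$mean), temporal_sd = unl(y$exposure$temporal_sd),
    spatial_sd = unl(y$exposure$spatial_sd),
    seasonal_amplitude = unl(y$exposure$seasonal_amplitude),
    ar1 = y$exposure$ar1 %||% 0.7,
    log_skew = unl(y$exposure$log_skew %||% 0),
    unit_noise_frac = y$exposure$unit_noise_frac %||% 0.1,
    temporal_cor = do.call(rbind, y$exposure$temporal_cor),
    spatial_cor = do.call(rbind, y$exposure$spatial_cor),
    pollutants = pols)
  met <- do.call(meteorology_config, y$meteorology %||% list())
  uc <- do.call(unit_covariate_config, y$units %||% list())
  m <- y$model
  gamma0 <- m$gamma0 %||% -Inf
  sigma_b <- m$sigma_b %||% 0
  base <- function(beta0) true_model_params(
    beta0 = beta0, beta_short = m$beta_short %||% 0,
    beta_long = m$beta_long %||% 0, pollutant = m$pollutant %||% "pm10",
    temp = unl(m$temp %||% c(0, 0, 0)),
    humidity = unl(m$humidity %||% c(0, 0, 0)),
    trend = if (!is.null(m$trend)) unl(m$trend),
    weekday = unl(m$weekday %||% c(0, 0, 0, 0)),
    pct_elderly = m$pct_elderly %||% 0, deprivation = m$deprivation %||% 0,
    gamma0 = gamma0, theta = m$theta %||% 1, sigma_b = sigma_b)
  groups <- y$outcome_groups; ages <- y$age_bands
  pi0 <- if (is.finite(gamma0)) stats::plogis(gamma0) else 0
  params <- stats::setNames(lapply(groups, function(g)
    stats::setNames(lapply(ages, function(a) {
      b0 <- if (!is.null(m$daily_mean))
        log(m$daily_mean[[g]][[a]] / (1 - pi0)) - sigma_b^2 / 2
      else m$beta0
      base(b0)
    }), ages)), groups)
  study_config(n_units = y$n_units, start = y$start, end = y$end,
               exposure = expo, meteorology = met, unit_covariates = uc,
               params = params, age_bands = ages, outcome_groups = groups,
               seed = seed %||% y$seed %||% 1L, name = y$name %||% "preset")
}

#' Borough-scale preset: 177 units, 2009-2013
#'
#' Emulates the scale and exposure structure of a 5-year inner-London
#' borough panel: 177 units, 1304 weekdays, temporal variability much
#' larger than spatial for PM and ozone and roughly equal for NO2,
#' negative ozone-NO2 correlation, and low zero-heavy daily counts for
#' four respiratory outcome groups in three age bands.
#'
#' @param seed RNG seed.
#' @return a `study_config`.
#' @export
lambeth_like_config <- function(seed = 1L) {
  load_study_config(system.file("extdata", "lambeth_like.yaml",
                                package = "zinbpanel", mustWork = TRUE),
                    seed = seed)
}

#' Desk-scale preset: 50 units, one year
#'
#' Same exposure structure as [lambeth_like_config()] at a size where the
#' whole pipeline (generation, design, mixed ZINB fit) runs in seconds:
#' 50 units x 1 year, one outcome group, one age band, with known
#' non-zero short- and long-term effects.
#'
#' @param seed RNG seed.
#' @return a `study_config`.
#' @export
desk_config <- function(seed = 1L) {
  load_study_config(system.file("extdata", "desk.yaml",
                                package = "zinbpanel", mustWork = TRUE),
                    seed = seed)
}
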