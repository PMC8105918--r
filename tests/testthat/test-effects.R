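test_that("percent change per IQR follows the log-link closed form", {
  z <- percent_change_per_iqr(0, 0.001, 10)
  expect_equal(z$pct_change, 0)
  # CI symmetric on the log scale around a zero coefficient
  expect_equal(log1p(z$ci_high / 100), -log1p(z$ci_low / 100), tolerance = 1e-12)

  # inverse construction: a coefficient of ln(1.01)/9.1 per ug/m3 is
  # exactly +1% per 9.1 ug/m3 IQR
  z1 <- percent_change_per_iqr(log(1.01) / 9.1, 0.0001, 9.1)
  expect_equal(z1$pct_change, 1.00, tolerance = 1e-12)

  # frozen values from a 25-digit evaluation of the closed form
  z2 <- percent_change_per_iqr(0.001, 0.0005, 22.3)
  expect_equal(z2$pct_change, 2.255050361135011, tolerance = 1e-12)
  expect_equal(z2$ci_low, 0.04460994727877381, tolerance = 1e-10)
  expect_equal(z2$ci_high, 4.514329456313348, tolerance = 1e-10)

  expect_error(percent_change_per_iqr(0.1, 0.1, -1),
               class = "zinbpanel_input_error")
})

test_that("percent change is antisymmetric under coefficient negation", {
  for (b in c(0.0005, 0.002, 0.01)) {
    p <- percent_change_per_iqr(b, 0, 22.3)$pct_change
    m <- percent_change_per_iqr(-b, 0, 22.3)$pct_change
    expect_equal(m, 100 * (1 / (1 + p / 100) - 1), tolerance = 1e-10)
  }
})

test_that("the analysis grid emits one short and one long row per cell", {
  panel <- generate_study(mini_config(seed = 51L))
  est <- run_analysis(panel, pollutants = c("pm10", "no2"),
                      outcome_group = "respiratory", age_band = "all",
                      lags = c("lag0", "lag1"))
  expect_identical(nrow(est), 8L)                 # 2 pollutants x 2 lags x 2 terms
  expect_identical(sum(est$term == "short"), 4L)
  expect_identical(sum(est$term == "long"), 4L)
  expect_true(all(is.na(est$error)))
  expect_true(all(est$ci_low <= est$pct_change & est$pct_change <= est$ci_high))
  # short rows are scaled by the temporal IQR, long rows by the spatial
  iq <- compute_iqrs(panel)
  expect_equal(est$iqr_used[est$pollutant == "pm10" & est$term == "short"],
               rep(iq$temporal_iqr[iq$pollutant == "pm10"], 2))
  expect_equal(est$iqr_used[est$pollutant == "pm10" & est$term == "long"],
               rep(iq$spatial_iqr[iq$pollutant == "pm10"], 2))

  expect_error(run_analysis(panel, "pm10", "respiratory", "all",
                            lags = character(0)),
               "empty lag", class = "zinbpanel_input_error")
  expect_error(run_analysis(panel, "so2", "respiratory", "all"),
               class = "zinbpanel_input_error")
})

test_that("two-pollutant adjustment records the co-pollutant", {
  panel <- generate_study(mini_config(seed = 52L))
  est <- run_analysis(panel, "pm10", "respiratory", "all", lags = "lag0",
                      co_pollutants = c(pm10 = "no2"))
  expect_identical(unique(est$adjusted_for), "no2")
  expect_identical(nrow(est), 2L)
})

test_that("grid failures degrade to per-cell error records", {
  panel <- generate_study(mini_config(seed = 53L, n_units = 4L, weeks = 9L))
  # sabotage one outcome cell: all-zero counts make the fit error out
  panel$daily$count__respiratory__all[
    !is.na(panel$daily$count__respiratory__all)] <- 0L
  est <- run_analysis(panel, "pm10", "respiratory", "all", lags = "lag0")
  expect_identical(nrow(est), 2L)
  expect_true(all(!is.na(est$error)))
  expect_true(all(is.na(est$pct_change)))
})

test_that("the Poisson time-series model recovers a known aggregate effect", {
  # pure Poisson counts with no random effect or zero inflation
  reps <- 8L
  est <- se <- numeric(reps)
  beta_true <- 0.004
  for (r in seq_len(reps)) {
    panel <- generate_study(mini_config(seed = 60L + r, n_units = 10L,
                                        weeks = 26L,
                                        override = list(
                                          beta0 = log(4), beta_short = beta_true,
                                          beta_long = 0, gamma0 = -Inf,
                                          theta = 1e8, sigma_b = 0)))
    row <- fit_poisson_timeseries(panel, "pm10", "lag0", "respiratory", "all")
    est[r] <- row$coef; se[r] <- row$se
  }
  mc_se <- stats::sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - beta_true), 3 * mc_se)

  # the area-average series is exactly the per-day mean over units
  dec <- decompose_exposure(panel, "pm10")
  conc <- dec$deviation + dec$unit_mean
  m <- matrix(panel$daily$pm10, nrow = nrow(panel$units))
  expect_equal(unname(colMeans(conc)), unname(colMeans(m)), tolerance = 1e-12)
})

test_that("the mixed ZINB fit pinned to Poisson matches the Poisson fit", {
  panel <- generate_study(mini_config(seed = 71L, n_units = 10L, weeks = 26L,
                                      override = list(beta0 = log(4),
                                                      gamma0 = -Inf,
                                                      theta = 1e8,
                                                      sigma_b = 0)))
  row <- fit_poisson_timeseries(panel, "pm10", "lag0", "respiratory", "all")

  # rebuild the identical aggregated design and response
  dates <- seq(panel$study_start, panel$study_end, by = "day")
  dec <- decompose_exposure(panel, "pm10")
  day_avg <- colMeans(dec$deviation + dec$unit_mean)
  expo <- apply_lag(day_avg, "lag0", dates = dates)
  wk <- is_weekday_dates(dates)
  y_day <- rowsum(panel$daily$count__respiratory__all,
                  format(panel$daily$date, "%Y-%m-%d"), na.rm = TRUE)[, 1L]
  y_day <- y_day[match(format(dates, "%Y-%m-%d"), names(y_day))]
  met <- panel$daily[match(dates, panel$daily$date),
                     c("temperature", "humidity")]
  X <- cbind("(Intercept)" = 1, exposure = expo[wk],
             natural_spline_basis(met$temperature[wk], 3L, "temp"),
             natural_spline_basis(met$humidity[wk], 3L, "hum"),
             natural_spline_basis(which(wk), 3L, "trend"),
             weekday_dummies(dates[wk]))
  des <- structure(list(X = X, Z = matrix(1, sum(wk), 1),
                        y = as.integer(y_day[wk]),
                        group = factor(rep("area", sum(wk)))),
                   class = "design_matrices")
  fit <- fit_zinb_mixed(zinb_spec(des),
                        fixed = list(gamma0 = -20, log_theta = log(1e8),
                                     log_sigma_b = -Inf))
  ref <- stats::glm.fit(X, des$y, family = stats::poisson())
  expect_equal(unname(fit$beta), unname(ref$coefficients), tolerance = 1e-3)
})

test_that("reports are deterministic and complete", {
  panel <- generate_study(mini_config(seed = 54L))
  est <- run_analysis(panel, "pm10", "respiratory", "all",
                      lags = c("lag0", "lag1"))
  iq <- compute_iqrs(panel)
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  p1 <- render_report(est, iq, td1)
  p2 <- render_report(est, iq, td2)
  got <- utils::read.csv(file.path(td1, "estimates.csv"))
  expect_identical(nrow(got), nrow(est))
  expect_identical(readLines(file.path(td1, "estimates.csv")),
                   readLines(file.path(td2, "estimates.csv")))
  expect_true(file.exists(file.path(td1, "forest_pm10.png")))

  expect_error(render_report(est[0, ], iq, td1), "no estimates",
               class = "zinbpanel_input_error")
})

test_that("a week-distributed effect shows strongest at the week average", {
  # counts driven by the week-average deviation, not the same-day one
  cfg <- mini_config(seed = 55L, n_units = 15L, weeks = 26L,
                     override = list(beta0 = log(3), beta_short = 0,
                                     beta_long = 0, gamma0 = -Inf,
                                     theta = 1e8, sigma_b = 0))
  panel <- generate_study(cfg)
  dec <- decompose_exposure(panel, "pm10")
  desw <- build_design(panel, dec, lag = "week_avg",
                       outcome_group = "respiratory", age_band = "all")
  set.seed(551)
  beta_w <- 0.008
  eta <- log(3) + beta_w * desw$X[, "short_pm10"]
  yw <- stats::rpois(length(eta), exp(eta))
  key <- paste(desw$rows$unit_id, desw$rows$date)
  pk <- paste(panel$daily$unit_id, panel$daily$date)
  cnt <- panel$daily$count__respiratory__all
  # baseline-rate background on the few rows without week history
  cnt[!is.na(cnt)] <- stats::rpois(sum(!is.na(cnt)), 3)
  cnt[match(key, pk)] <- yw
  panel$daily$count__respiratory__all <- cnt

  est <- run_analysis(panel, "pm10", "respiratory", "all",
                      lags = c("lag0", "week_avg"))
  sh <- est[est$term == "short", ]
  expect_gte(sh$pct_change[sh$lag == "week_avg"],
             sh$pct_change[sh$lag == "lag0"])
})
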