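test_that("generation is deterministic given config and seed", {
  cfg <- mini_config(seed = 5L, n_units = 4L, weeks = 9L)
  p1 <- generate_study(cfg)
  p2 <- generate_study(cfg)
  expect_identical(p1$daily, p2$daily)
  expect_identical(p1$units, p2$units)
  p3 <- generate_study(mini_config(seed = 6L, n_units = 4L, weeks = 9L))
  expect_false(identical(p1$daily, p3$daily))
})

test_that("degenerate exposure configs collapse as expected", {
  dates <- seq(as.Date("2009-01-01"), by = "day", length.out = 60)
  base <- desk_config()$exposure

  # no spatial variation, no unit noise: all units share one series
  cfg <- exposure_field_config(
    mean = base$mean, temporal_sd = base$temporal_sd,
    spatial_sd = rep(0, 4), seasonal_amplitude = base$seasonal_amplitude,
    ar1 = base$ar1, log_skew = base$log_skew, unit_noise_frac = 0,
    temporal_cor = base$temporal_cor, spatial_cor = base$spatial_cor)
  f <- generate_exposure_fields(cfg, 5L, dates, seed = 1L)
  expect_equal(f$no2[1, ], f$no2[5, ])

  # no temporal variation, no noise: constant over time per unit
  cfg2 <- exposure_field_config(
    mean = base$mean, temporal_sd = rep(0, 4),
    spatial_sd = base$spatial_sd, seasonal_amplitude = rep(0, 4),
    ar1 = base$ar1, log_skew = base$log_skew, unit_noise_frac = 0,
    temporal_cor = base$temporal_cor, spatial_cor = base$spatial_cor)
  f2 <- generate_exposure_fields(cfg2, 5L, dates, seed = 1L)
  expect_equal(f2$o3[, 1], f2$o3[, 60])

  # non-PSD correlation matrix is rejected
  badcor <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3, 3)
  expect_error(
    exposure_field_config(mean = c(1, 1, 1), temporal_sd = c(1, 1, 1),
                          spatial_sd = c(1, 1, 1),
                          seasonal_amplitude = c(0, 0, 0),
                          temporal_cor = badcor,
                          pollutants = c("no2", "pm10", "o3")),
    "positive semi-definite", class = "zinbpanel_config_error")
})

test_that("exposure moments recover the configured variance partition", {
  cfg <- desk_config()$exposure
  dates <- seq(as.Date("2009-01-01"), as.Date("2011-12-31"), by = "day")
  sp <- tm <- matrix(0, 3, 4)
  cor_neg <- logical(3)
  for (s in 1:3) {
    f <- generate_exposure_fields(cfg, 100L, dates, seed = 100L + s)
    sp[s, ] <- sapply(f, function(m) stats::sd(rowMeans(m)))
    tm[s, ] <- sapply(f, function(m) stats::sd(colMeans(m)))
    cor_neg[s] <- stats::cor(colMeans(f$o3), colMeans(f$no2)) < 0
  }
  # moments pooled over the three seeds
  expect_true(all(abs(colMeans(sp) / cfg$spatial_sd - 1) < 0.15))
  expect_true(all(abs(colMeans(tm) / cfg$temporal_sd - 1) < 0.15))
  expect_true(all(cor_neg))
})

test_that("clipping at zero is rare under the default exposure settings", {
  cfg <- desk_config()$exposure
  dates <- seq(as.Date("2009-01-01"), as.Date("2011-12-31"), by = "day")
  f <- generate_exposure_fields(cfg, 100L, dates, seed = 9L)
  expect_true(all(attr(f, "clip_rate") < 0.01))
  expect_true(all(sapply(f, min) >= 0))
})

test_that("meteorology matches configured moments and bounds", {
  dates <- seq(as.Date("2009-01-01"), as.Date("2011-12-31"), by = "day")
  cfg <- meteorology_config()

  flat <- meteorology_config(temp_amplitude = 0, temp_sd = 0,
                             hum_amplitude = 0, hum_sd = 0)
  m0 <- generate_meteorology(flat, dates, seed = 1L)
  expect_equal(m0$temperature, rep(11.0, length(dates)))

  for (s in 1:3) {
    m <- generate_meteorology(cfg, dates, seed = 20L + s)
    expect_lt(abs(mean(m$temperature) - 11.0), 1)
    expect_lt(abs(stats::sd(m$temperature) / 5.7 - 1), 0.20)
    expect_true(all(m$humidity >= 0 & m$humidity <= 100))
  }
})

test_that("count generator reaches its Poisson and structural-zero limits", {
  cfg <- mini_config(seed = 2L, n_units = 10L, weeks = 20L,
                     override = list(beta0 = log(3), beta_short = 0,
                                     beta_long = 0, weekday = c(0, 0, 0, 0),
                                     temp = c(0, 0, 0),
                                     pct_elderly = 0, deprivation = 0,
                                     gamma0 = -Inf, theta = 1e8,
                                     sigma_b = 0))
  panel <- generate_study(cfg)
  y <- panel$daily$count__respiratory__all
  y <- y[!is.na(y)]
  # Poisson limit: mean ~= exp(beta0) = 3 within Monte-Carlo error
  expect_lt(abs(mean(y) - 3), 4 * sqrt(3 / length(y)))
  expect_lt(abs(stats::var(y) / 3 - 1), 0.1)    # Poisson variance, not ZINB

  # pi = 0.5: at a large mean almost all zeros are structural
  cfg2 <- mini_config(seed = 3L, n_units = 10L, weeks = 20L,
                      override = list(beta0 = log(50), beta_short = 0,
                                      beta_long = 0, weekday = c(0, 0, 0, 0),
                                      temp = c(0, 0, 0), pct_elderly = 0,
                                      deprivation = 0, gamma0 = 0,
                                      theta = 1e6, sigma_b = 0))
  y2 <- generate_study(cfg2)$daily$count__respiratory__all
  expect_gte(mean(y2 == 0, na.rm = TRUE), 0.45)
})

test_that("draws at fixed parameters follow the stated ZINB law", {
  set.seed(202)
  mu <- 2; theta <- 1.5; pi0 <- 0.3; n <- 1e5
  y <- rzinb(n, mu, theta, pi0)
  kmax <- max(y)
  probs <- exp(zinb_log_pmf(0:kmax, mu, theta, pi0))
  probs <- c(probs, 1 - sum(probs))              # tail bin
  obs <- tabulate(y + 1L, nbins = kmax + 1L)
  obs <- c(obs, n - sum(obs))
  keep <- probs * n >= 5
  chi2 <- sum((obs[keep] - n * probs[keep])^2 / (n * probs[keep]))
  pval <- stats::pchisq(chi2, df = sum(keep) - 1L, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("an exploding linear predictor aborts generation with advice", {
  cfg <- mini_config(seed = 4L, n_units = 4L, weeks = 9L,
                     override = list(beta0 = 20, beta_short = 0.5))
  expect_error(generate_study(cfg), "rescale",
               class = "zinbpanel_generation_error")
})

test_that("preset scales are as declared", {
  desk <- desk_config()
  expect_identical(desk$n_units, 50L)
  expect_identical(as.integer(desk$end - desk$start) + 1L, 365L)
  ll <- lambeth_like_config()
  expect_identical(ll$n_units, 177L)
  expect_identical(length(ll$outcome_groups) * length(ll$age_bands), 12L)
})
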