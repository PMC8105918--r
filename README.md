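# zinbpanel

Spatio-temporal analysis of daily small-area health counts against air
pollution. The package targets panels of the kind produced by linking
primary-care event counts (respiratory consultations, inhaler
prescriptions) to modelled pollutant concentrations per small area (e.g.
UK LSOAs): a dense (unit x calendar day) grid of NO2, PM10, PM2.5 and O3
concentrations, daily temperature and humidity, weekday-only outcome
counts, and per-unit covariates.

## The model

Each pollutant series is decomposed into a long-term (spatial) unit mean
`Xbar_i` and short-term (temporal) daily deviations `D_it = X_it - Xbar_i`.
Both enter one mixed-effects zero-inflated negative binomial model with a
random intercept per unit:

```
b_i   ~ N(0, sigma_b^2)
mu_it = exp(beta_0 + b_i + beta_S * D_it(lag) + beta_L * Xbar_i + z_it' gamma)
y_it  ~ pi * delta_0 + (1 - pi) * NegBin(mu_it, theta)
```

with natural-spline confounders (temperature 3 df, humidity 3 df, trend
6 df/year), day-of-week dummies and unit covariates in `z_it`. The random
intercept is marginalized by adaptive Gauss-Hermite quadrature; fitting is
quasi-Newton with analytic gradients. Effects are reported as percent
change per interquartile-range increase in exposure — temporal IQR for
short-term terms, spatial IQR for long-term terms — with Wald 95% CIs,
over lags `lag0`, `lag1`, `lag2` and `week_avg`, optionally adjusted for a
co-pollutant. A Poisson time-series model on area-aggregated counts is
included as the conventional sensitivity check, and a seeded synthetic
generator reproduces the exposure variance partition, cross-pollutant
correlations, seasonal meteorology and zero-heavy counts such analyses
assume.

## Worked example

```r
library(zinbpanel)

panel <- generate_study(desk_config(seed = 42))   # 50 units x 1 year
dec   <- decompose_exposure(panel, "pm10")
des   <- build_design(panel, dec, lag = "lag0",
                      outcome_group = "respiratory", age_band = "all")
fit   <- fit_zinb_mixed(des)
fit
#> Mixed-effects zero-inflated negative binomial fit
#>   13000 obs, 50 units; loglik -31436.405; converged
#>   theta = 1.575, sigma_b = 0.1639, pi0 = 0.1119
#> ...

iq <- compute_iqrs(panel, "pm10")
percent_change_per_iqr(fit$beta[["short_pm10"]],
                       sqrt(fit$vcov["short_pm10", "short_pm10"]),
                       iq$temporal_iqr)
#> $pct_change
#> [1] 1.9417   # % change per temporal-IQR (9.46 ug/m3) PM10 increase
#> $ci_low
#> [1] 0.1647
#> $ci_high
#> [1] 3.7503
```

The desk preset generates counts with a true short-term coefficient of
0.002 per ug/m3, i.e. `100*(exp(0.002*9.46)-1) = 1.91%` per temporal IQR —
the fit above recovers it within its interval. The full grid
(pollutant x lag x adjustment) is one call:

```r
est <- run_analysis(panel, pollutants = "pm10",
                    outcome_group = "respiratory", age_band = "all",
                    lags = c("lag0", "lag1", "lag2", "week_avg"),
                    co_pollutants = c(pm10 = "no2"))
render_report(est, compute_iqrs(panel), "out/")   # CSVs + forest plots
```

A thin command-line wrapper (`inst/cli/zinbpanel.R`) exposes
`simulate` / `fit` / `sensitivity-poisson` / `report` with a manifest
(config hash, seed, package version) written next to every output.

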