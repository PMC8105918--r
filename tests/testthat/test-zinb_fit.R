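test_that("sigma_b = 0 reduces the marginal likelihood to a plain sum", {
  des <- oracle_design()
  pars <- list(beta = c(0.1, 0.3, -0.2), gamma0 = stats::qlogis(0.25),
               log_theta = log(1.3), log_sigma_b = -Inf)
  direct <- sum(zinb_log_pmf(des$y, exp(drop(des$X %*% pars$beta)),
                             1.3, 0.25))
  expect_equal(marginal_loglik(pars, zinb_spec(des)), direct,
               tolerance = 1e-12)
})

test_that("adaptive quadrature matches dense brute-force integration", {
  des <- oracle_design()
  pars <- list(beta = c(0.2, 0.35, -0.25), gamma0 = stats::qlogis(0.2),
               log_theta = log(1.3), log_sigma_b = log(0.4))
  agq <- marginal_loglik(pars, zinb_spec(des, nodes = 15L))
  oracle <- trapezoid_loglik(pars$beta, pars$gamma0, pars$log_theta,
                             pars$log_sigma_b, des)
  expect_lt(abs(agq - oracle), 1e-6)

  # quadrature self-convergence: 7 -> 15 -> 31 nodes
  l7 <- marginal_loglik(pars, zinb_spec(des, nodes = 7L))
  l15 <- marginal_loglik(pars, zinb_spec(des, nodes = 15L))
  l31 <- marginal_loglik(pars, zinb_spec(des, nodes = 31L))
  expect_lt(abs(l15 - l7), 1e-8)
  expect_lt(abs(l31 - l15), 1e-8)
})

test_that("likelihood reductions: Poisson and plain negative binomial", {
  des <- oracle_design(seed = 32L)
  beta <- c(0.3, 0.2, -0.1)
  eta <- drop(des$X %*% beta)
  # pi = 0, sigma_b = 0, theta huge: Poisson log-likelihood
  lp <- marginal_loglik(list(beta = beta, gamma0 = -Inf,
                             log_theta = log(1e8), log_sigma_b = -Inf),
                        zinb_spec(des))
  expect_lt(abs(lp - sum(stats::dpois(des$y, exp(eta), log = TRUE))), 1e-4)
  # pi = 0, sigma_b = 0: plain NB log-likelihood
  lnb <- marginal_loglik(list(beta = beta, gamma0 = -Inf,
                              log_theta = log(1.3), log_sigma_b = -Inf),
                         zinb_spec(des))
  expect_equal(lnb, sum(nb_log_pmf(des$y, exp(eta), 1.3)), tolerance = 1e-10)
})

test_that("rescaling a covariate rescales its coefficient, not the fit", {
  panel <- generate_study(mini_config(seed = 41L))
  des <- mini_design(panel)
  fit <- fit_zinb_mixed(zinb_spec(des))
  expect_true(fit$converged)

  des2 <- des
  des2$X[, "short_pm10"] <- des$X[, "short_pm10"] * 10
  # likelihood invariance at the mapped parameters (exact property)
  mapped <- fit$beta
  mapped[["short_pm10"]] <- mapped[["short_pm10"]] / 10
  pars <- list(beta = unname(fit$beta), gamma0 = fit$gamma0,
               log_theta = fit$log_theta, log_sigma_b = fit$log_sigma_b)
  pars2 <- pars; pars2$beta <- unname(mapped)
  expect_lt(abs(marginal_loglik(pars, zinb_spec(des)) -
                  marginal_loglik(pars2, zinb_spec(des2))), 1e-6)
  # and the refitted coefficient comes back rescaled
  fit2 <- fit_zinb_mixed(zinb_spec(des2))
  expect_equal(fit2$beta[["short_pm10"]], fit$beta[["short_pm10"]] / 10,
               tolerance = 1e-3)
})

test_that("a single fit lands near the generating parameters", {
  panel <- generate_study(mini_config(seed = 42L, n_units = 20L, weeks = 26L))
  des <- mini_design(panel)
  fit <- fit_zinb_mixed(zinb_spec(des))
  tp <- true_pars(panel)
  se <- sqrt(diag(fit$vcov))

  expect_true(fit$converged)
  expect_lt(abs(fit$beta[["short_pm10"]] - tp$beta[["short_pm10"]]),
            4 * se[["short_pm10"]])
  expect_lt(abs(fit$beta[["(Intercept)"]] - tp$beta[["(Intercept)"]]),
            4 * se[["(Intercept)"]])

  # the MLE dominates the truth
  ll_true <- marginal_loglik(list(beta = unname(tp$beta), gamma0 = tp$gamma0,
                                  log_theta = log(tp$theta),
                                  log_sigma_b = log(tp$sigma_b)),
                             zinb_spec(des))
  expect_gte(fit$loglik, ll_true)
})

test_that("a zero random-effect truth collapses to the no-RE fit", {
  panel <- generate_study(mini_config(seed = 43L, n_units = 10L, weeks = 20L,
                                      override = list(sigma_b = 0)))
  des <- mini_design(panel)
  fit <- fit_zinb_mixed(zinb_spec(des))
  expect_lt(fit$sigma_b, 0.05)

  ref <- plain_zinb_fit(des$X, des$y, start_beta = unname(fit$beta))
  expect_equal(unname(fit$beta), unname(ref$beta), tolerance = 1e-3)
  # boundary parameters are flagged and their vcov entries withheld
  if ("log_sigma_b" %in% fit$boundary)
    expect_true(is.na(fit$vcov["log_sigma_b", "log_sigma_b"]))
})

test_that("pinning pi = 0 and sigma_b = 0 reproduces glm.nb", {
  panel <- generate_study(mini_config(seed = 44L, n_units = 10L, weeks = 20L,
                                      override = list(gamma0 = -Inf,
                                                      sigma_b = 0,
                                                      theta = 1.5)))
  des <- mini_design(panel)
  fit <- fit_zinb_mixed(zinb_spec(des),
                        fixed = list(gamma0 = -Inf, log_sigma_b = -Inf))
  ref <- MASS::glm.nb(des$y ~ 0 + des$X)
  expect_equal(unname(fit$beta), unname(stats::coef(ref)), tolerance = 1e-3)
  expect_equal(fit$theta, ref$theta, tolerance = 1e-2)
})

test_that("predicted means behave and calibrate", {
  panel <- generate_study(mini_config(seed = 45L))
  des <- mini_design(panel)
  fit <- fit_zinb_mixed(zinb_spec(des))

  # pi = 0, sigma_b = 0 pinned: prediction is exp(x'beta)
  fit0 <- fit_zinb_mixed(zinb_spec(des),
                         fixed = list(gamma0 = -Inf, log_sigma_b = -Inf))
  pr <- predict_mean(fit0, des)
  expect_equal(pr, exp(drop(des$X %*% fit0$beta)), tolerance = 1e-12)

  # a zero-coefficient covariate does not move predictions
  fitz <- fit0; fitz$beta[["pct_elderly"]] <- 0
  desz <- des; desz$X[, "pct_elderly"] <- des$X[, "pct_elderly"] * 2
  expect_equal(predict_mean(fitz, desz), predict_mean(fitz, des))

  # population-mean calibration on the training data
  expect_lt(abs(mean(predict_mean(fit, des)) / mean(des$y) - 1), 0.05)

  # label mismatch is an error
  bad <- des$X[, c(2:1, 3:ncol(des$X))]
  expect_error(predict_mean(fit, bad), "labels",
               class = "zinbpanel_input_error")
})

test_that("degenerate inputs are rejected up front", {
  des <- oracle_design()
  des$y[] <- 0L
  expect_error(fit_zinb_mixed(zinb_spec(des)), "all counts",
               class = "zinbpanel_input_error")
})
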