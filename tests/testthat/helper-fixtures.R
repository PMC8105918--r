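# Shared fixtures and independent oracles for the test suite.

# --- panel builders --------------------------------------------------

# Dense toy panel with fully specified exposure values. `conc` is either
# a scalar, or a named list of unit x day matrices (one per pollutant
# supplied; the rest default to 10). Counts default to 1 on weekdays.
toy_panel <- function(n_units = 2L, start = "2009-01-05", n_days = 10L,
                      conc = list(), temp = 10, hum = 70, counts = NULL,
                      pct_elderly = NULL, deprivation = NULL) {
  dates <- seq(as.Date(start), by = "day", length.out = n_days)
  ids <- sprintf("U%02d", seq_len(n_units))
  units <- data.frame(unit_id = ids,
                      pct_elderly = pct_elderly %||% seq(5, 15, length.out = n_units),
                      deprivation = deprivation %||% seq(10, 30, length.out = n_units))
  daily <- data.frame(unit_id = rep(ids, times = n_days),
                      date = rep(dates, each = n_units))
  for (p in zinbpanel::POLLUTANTS) {
    m <- conc[[p]]
    if (is.null(m)) m <- matrix(10, n_units, n_days)
    if (length(m) == 1L) m <- matrix(m, n_units, n_days)
    daily[[p]] <- as.vector(m)
  }
  daily$temperature <- rep(rep_len(temp, n_days), each = n_units)
  daily$humidity <- rep(rep_len(hum, n_days), each = n_units)
  wk <- rep(as.POSIXlt(dates)$wday %in% 1:5, each = n_units)
  cc <- counts %||% 1L
  if (length(cc) == 1L) cc <- rep(cc, n_units * n_days)
  cnt <- ifelse(wk, as.integer(cc), NA_integer_)
  daily[["count__respiratory__all"]] <- cnt
  panel_dataset(units, daily, min(dates), max(dates),
                age_bands = "all", outcome_groups = "respiratory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_weekday_dates <- function(d) as.POSIXlt(d)$wday %in% 1:5

# Small study configuration for fast end-to-end fits: reuses the desk
# preset's exposure/meteorology structure at a reduced size.
mini_config <- function(seed = 1L, n_units = 12L, weeks = 16L,
                        start = "2009-03-02", override = list()) {
  base <- desk_config(seed = seed)
  end <- as.Date(start) + weeks * 7L - 1L     # Monday start, Sunday end
  defaults <- list(beta0 = log(2), beta_short = 0.002, beta_long = 0.002,
                   pollutant = "pm10", temp = c(0, 0, 0),
                   humidity = c(0, 0, 0), trend = NULL,
                   weekday = c(0.05, 0.02, 0, -0.03),
                   pct_elderly = 0.005, deprivation = 0.004,
                   gamma0 = stats::qlogis(0.1), theta = 1.5, sigma_b = 0.15)
  tp <- do.call(true_model_params, utils::modifyList(defaults, override))
  study_config(n_units = n_units, start = start, end = end,
               exposure = base$exposure, meteorology = base$meteorology,
               unit_covariates = base$unit_covariates, params = tp,
               age_bands = "all", outcome_groups = "respiratory",
               seed = seed, name = "mini")
}

mini_design <- function(panel, lag = "lag0", pollutant = "pm10", ...) {
  build_design(panel, decompose_exposure(panel, pollutant), lag = lag,
               outcome_group = "respiratory", age_band = "all", ...)
}

true_pars <- function(panel) attr(panel, "true_params")$respiratory$all

# A small hand-built grouped design used for the quadrature oracle tests.
oracle_design <- function(seed = 31L, n_units = 3L, n_per = 5L,
                          mu_scale = 1.2) {
  set.seed(seed)
  n <- n_units * n_per
  X <- cbind("(Intercept)" = 1, x1 = stats::rnorm(n), x2 = stats::runif(n))
  beta <- c(log(mu_scale), 0.4, -0.3)
  g <- factor(rep(sprintf("u%d", seq_len(n_units)), each = n_per))
  b <- stats::rnorm(n_units, 0, 0.4)
  mu <- exp(drop(X %*% beta) + b[as.integer(g)])
  y <- rzinb(n, mu, theta = 1.3, pi = 0.2)
  structure(list(X = X, Z = matrix(1, n, 1), y = y, group = g,
                 rows = NULL), class = "design_matrices")
}

# --- independent oracles ---------------------------------------------

# Brute-force marginal log-likelihood: per-unit trapezoid integration of
# the ZINB likelihood times the normal density over a wide grid in b.
trapezoid_loglik <- function(beta, gamma0, log_theta, log_sigma_b,
                             design, npts = 1e5L, width = 10) {
  theta <- exp(log_theta); sigma <- exp(log_sigma_b)
  pi0 <- if (is.finite(gamma0)) stats::plogis(gamma0) else 0
  eta <- drop(design$X %*% beta)
  b <- seq(-width * sigma, width * sigma, length.out = npts)
  h <- b[2L] - b[1L]
  total <- 0
  for (u in levels(design$group)) {
    idx <- design$group == u
    lf <- vapply(b, function(bb)
      sum(zinb_log_pmf(design$y[idx], exp(eta[idx] + bb), theta, pi0)),
      0) + stats::dnorm(b, 0, sigma, log = TRUE)
    mx <- max(lf)
    f <- exp(lf - mx)
    total <- total + mx + log(h * (sum(f) - (f[1L] + f[npts]) / 2))
  }
  total
}

# Cubic B-spline basis by the de Boor recursion (independent of
# splines::splineDesign), for column-space comparison with ns().
deboor_basis <- function(x, interior, boundary) {
  knots <- c(rep(boundary[1L], 4L), interior, rep(boundary[2L], 4L))
  nb <- length(knots) - 4L
  B <- matrix(0, length(x), nb)
  for (i in seq_len(nb)) B[, i] <- deboor_one(x, knots, i, 3L)
  # right-continuity fix at the last boundary knot
  at_end <- x == boundary[2L]
  if (any(at_end)) B[at_end, nb] <- 1
  B
}

deboor_one <- function(x, t, i, k) {
  if (k == 0L) return(as.numeric(x >= t[i] & x < t[i + 1L]))
  d1 <- t[i + k] - t[i]
  d2 <- t[i + k + 1L] - t[i + 1L]
  a <- if (d1 > 0) (x - t[i]) / d1 * deboor_one(x, t, i, k - 1L) else 0
  b <- if (d2 > 0) (t[i + k + 1L] - x) / d2 * deboor_one(x, t, i + 1L, k - 1L) else 0
  a + b
}

# Direct maximization of the no-random-effect ZINB log-likelihood
# (independent optimizer route; no quadrature machinery).
plain_zinb_fit <- function(X, y, start_beta = NULL) {
  p <- ncol(X)
  # standardize for optimizer conditioning (coefficients mapped back)
  ctr <- c(0, colMeans(X[, -1L, drop = FALSE]))
  scl <- c(1, apply(X[, -1L, drop = FALSE], 2L, stats::sd))
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  nll <- function(par) {
    eta <- drop(Xs %*% par[1:p])
    if (max(eta) > 50) return(1e10)
    mu <- exp(pmax(eta, -300))
    pi0 <- stats::plogis(min(par[p + 1L], 15))
    -sum(zinb_log_pmf(y, mu, exp(par[p + 2L]), pi0))
  }
  bs0 <- start_beta %||% c(log(mean(y) + 0.1), rep(0, p - 1L))
  init_s <- bs0 * scl
  init_s[1L] <- bs0[1L] + sum(bs0[-1L] * ctr[-1L])
  opt <- stats::optim(c(init_s, -2, 0), nll, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
  bs <- opt$par[1:p] / scl
  bs[1L] <- opt$par[1L] - sum(opt$par[2:p] * ctr[-1L] / scl[-1L])
  list(beta = stats::setNames(bs, colnames(X)),
       gamma0 = opt$par[p + 1L], log_theta = opt$par[p + 2L],
       loglik = -opt$value)
}
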