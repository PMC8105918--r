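# Mixed-effects zero-inflated negative binomial model with a per-unit
# random intercept on the log mean. The marginal likelihood integrates the
# random intercept out by adaptive (mode-recentered) Gauss-Hermite
# quadrature; fitting is quasi-Newton (L-BFGS-B) on the quadrature
# objective with analytic gradients, re-adapting the nodes between
# optimizer passes.
#
# Model, for unit i and weekday t:
#   b_i ~ Normal(0, sigma_b^2)
#   mu_it = exp(x_it' beta + b_i)
#   y_it ~ pi * delta_0 + (1 - pi) * NegBin(mu_it, theta),  pi = plogis(gamma0)

#' Quadrature/optimizer specification for the mixed ZINB model
#'
#' @param design a `design_matrices` object.
#' @param nodes number of Gauss-Hermite nodes; odd and >= 5 so one node
#'   sits at the conditional mode. Default 15.
#' @param tol_grad,tol_step optimizer tolerances (projected gradient and
#'   relative step).
#' @param maxit maximum optimizer iterations per adaptation round.
#' @return object of class `zinb_spec`.
#' @export
zinb_spec <- function(design, nodes = 15L, tol_grad = 1e-6,
                      tol_step = 1e-9, maxit = 300L) {
  stopifnot(inherits(design, "design_matrices"))
  nodes <- as.integer(nodes)
  if (nodes < 5L || nodes %% 2L == 0L)
    abort_class("zinbpanel_config_error", "nodes must be odd and >= 5")
  if (tol_grad <= 0 || tol_step <= 0)
    abort_class("zinbpanel_config_error", "tolerances must be > 0")
  structure(list(design = design, nodes = nodes, tol_grad = tol_grad,
                 tol_step = tol_step, maxit = as.integer(maxit)),
            class = "zinb_spec")
}

# Per-design constant pieces, cached in an environment.
#' @noRd
fit_cache <- function(design) {
  y <- design$y
  gi <- as.integer(design$group)
  uy <- sort(unique(y))
  list(X = design$X, y = y, gi = gi, G = nlevels(design$group),
       n = length(y), uy = uy, yi = match(y, uy),
       lfac = lgamma(y + 1), z = y == 0L, nz = y > 0L)
}

# Per-row ZINB log-pmf and eta-derivatives at linear predictor eta.
# Returns lp (always) and, per `what`, d1/d2 (derivatives wrt eta),
# dg0 (wrt gamma0), dlt (wrt log theta).
#' @noRd
zinb_row_terms <- function(eta, cache, pi, theta, what = "lp") {
  mu <- exp(eta)
  y <- cache$y
  ltmu <- log(theta + mu)
  A <- mu / (theta + mu)
  lg_yt <- lgamma(cache$uy + theta)[cache$yi]
  lnb <- lg_yt - lgamma(theta) - cache$lfac +
    theta * (log(theta) - ltmu) + y * (eta - ltmu)
  out <- list()
  z <- cache$z
  if (pi > 0) {
    lp <- log1p(-pi) + lnb
    if (any(z)) {
      a <- log(pi); b <- lp[z]
      mx <- pmax(a, b)
      lp[z] <- mx + log(exp(a - mx) + exp(b - mx))
    }
    w0 <- exp(log1p(-pi) + lnb[z] - lp[z])   # (1-pi) NB(0) / P(0)
  } else {
    lp <- lnb
    w0 <- rep(1, sum(z))
  }
  out$lp <- lp
  if (what == "lp") return(out)

  u1 <- -theta * A[z]                        # d log NB(0) / d eta
  if (what == "newton") {
    d1 <- y - (y + theta) * A
    d2 <- -(y + theta) * A * (1 - A)
    d1[z] <- w0 * u1
    d2[z] <- w0 * (1 - w0) * u1^2 + w0 * (-theta * A[z] * (1 - A[z]))
    out$d1 <- d1; out$d2 <- d2
    return(out)
  }
  # what == "grad": d1, dg0, dlt
  d1 <- y - (y + theta) * A
  d1[z] <- w0 * u1
  out$d1 <- d1
  dg0 <- rep(-pi, cache$n)                   # y > 0 branch
  if (pi > 0 && any(z)) {
    qz <- exp(theta * (log(theta) - ltmu[z]))
    p0 <- pi + (1 - pi) * qz
    dg0[z] <- pi * (1 - pi) * (1 - qz) / p0
  } else if (pi == 0) {
    dg0[] <- 0
  }
  out$dg0 <- dg0
  dig_yt <- digamma(cache$uy + theta)[cache$yi]
  dlt <- theta * (dig_yt - digamma(theta) + log(theta) - ltmu + A -
                    y / (theta + mu))
  dlt[z] <- theta * w0 * (log(theta) - ltmu[z] + A[z])
  out$dlt <- dlt
  out
}

# Newton search for the per-unit conditional mode and curvature of
# log f_i(b) + log phi(b; 0, sigma^2), vectorized across units.
#' @noRd
agq_adapt <- function(eta_fix, cache, pi, theta, sigma, m = NULL) {
  G <- cache$G; gi <- cache$gi
  if (is.null(m)) m <- rep(0, G)
  inv_s2 <- 1 / sigma^2
  for (it in seq_len(40L)) {
    tm <- zinb_row_terms(eta_fix + m[gi], cache, pi, theta, what = "newton")
    g1 <- rowsum(tm$d1, gi)[, 1L] - m * inv_s2
    g2 <- rowsum(tm$d2, gi)[, 1L] - inv_s2
    g2 <- pmin(g2, -1e-8)
    step <- -g1 / g2
    step <- pmax(pmin(step, 2), -2)
    m <- m + step
    if (max(abs(step)) < 1e-11) break
  }
  tm <- zinb_row_terms(eta_fix + m[gi], cache, pi, theta, what = "newton")
  g2 <- pmin(rowsum(tm$d2, gi)[, 1L] - inv_s2, -1e-8)
  list(m = m, s = 1 / sqrt(-g2))
}

# Quadrature objective (and gradient) with nodes held at (m, s).
# Returns loglik; if grad = TRUE also the gradient with respect to
# c(beta, gamma0, log_theta, log_sigma).
#' @noRd
agq_eval <- function(beta, gamma0, ltheta, lsigma, cache, gh, m, s,
                     grad = FALSE) {
  theta <- exp(ltheta); sigma <- exp(lsigma)
  pi <- if (is.finite(gamma0)) stats::plogis(gamma0) else 0
  eta_fix <- drop(cache$X %*% beta)
  if (!all(is.finite(eta_fix)) || max(eta_fix) > 50) {
    bad <- if (all(is.finite(eta_fix))) sum(pmax(eta_fix - 50, 0)) else 1e6
    out <- list(loglik = -1e10 - bad)
    if (grad) out$grad <- rep(0, length(beta) + 3L)
    return(out)
  }
  K <- length(gh$x); G <- cache$G; gi <- cache$gi; n <- cache$n
  sq2 <- sqrt(2)
  B <- outer(m, rep(1, K)) + sq2 * outer(s, gh$x)   # G x K node positions
  C <- matrix(0, G, K)
  if (grad) {
    D1 <- matrix(0, n, K); Dg0 <- matrix(0, n, K); Dlt <- matrix(0, n, K)
  }
  for (k in seq_len(K)) {
    bk <- B[, k][gi]
    tm <- zinb_row_terms(eta_fix + bk, cache, pi, theta,
                         what = if (grad) "grad" else "lp")
    C[, k] <- log(gh$w[k]) + gh$x[k]^2 + log(sq2 * s) +
      rowsum(tm$lp, gi)[, 1L] +
      stats::dnorm(B[, k], 0, sigma, log = TRUE)
    if (grad) { D1[, k] <- tm$d1; Dg0[, k] <- tm$dg0; Dlt[, k] <- tm$dlt }
  }
  lli <- row_logsumexp(C)
  ll <- sum(lli)
  if (!grad) return(list(loglik = ll))
  P <- exp(C - lli)                                  # G x K posterior weights
  Pr <- P[gi, , drop = FALSE]                        # n x K
  r <- rowSums(Pr * D1)
  gbeta <- drop(crossprod(cache$X, r))
  ggamma0 <- sum(Pr * Dg0)
  gltheta <- sum(Pr * Dlt)
  glsigma <- sum(P * (B^2 / sigma^2 - 1))
  list(loglik = ll, grad = c(gbeta, ggamma0, gltheta, glsigma))
}

#' Marginal log-likelihood of the mixed ZINB model
#'
#' For each unit i the random intercept is integrated out:
#' `l = sum_i log integral prod_t P_zinb(y_it | mu_it e^b) phi(b; 0,
#' sigma_b^2) db`, approximated by adaptive Gauss-Hermite quadrature with
#' nodes recentered and rescaled at the per-unit conditional mode and
#' curvature. `sigma_b = 0` is handled analytically (no quadrature).
#'
#' @param params list with `beta` (count-part coefficients in design
#'   column order), `gamma0` (zero-part intercept on the logit scale;
#'   `-Inf` means no zero inflation), `log_theta`, `log_sigma_b`.
#' @param spec a `zinb_spec` (or a `design_matrices`, in which case
#'   default quadrature settings are used).
#' @return the marginal log-likelihood (a single number).
#' @export
marginal_loglik <- function(params, spec) {
  if (inherits(spec, "design_matrices")) spec <- zinb_spec(spec)
  cache <- fit_cache(spec$design)
  beta <- params$beta
  if (length(beta) != ncol(cache$X))
    abort_class("zinbpanel_input_error", "beta length does not match design columns")
  if (!all(is.finite(beta)))
    abort_class("zinbpanel_input_error", "non-finite parameters")
  gamma0 <- params$gamma0; ltheta <- params$log_theta; lsigma <- params$log_sigma_b
  theta <- exp(ltheta)
  pi <- if (is.finite(gamma0)) stats::plogis(gamma0) else 0
  eta <- drop(cache$X %*% beta)
  if (!all(is.finite(eta))) {
    bad <- which(!is.finite(eta))[1L]
    abort_class("zinbpanel_numeric_error",
                sprintf("non-finite linear predictor at row %d", bad))
  }
  sigma <- exp(lsigma)
  if (!is.finite(lsigma) || sigma < 1e-10) {
    return(sum(zinb_log_pmf(cache$y, exp(eta), theta, pi)))
  }
  gh <- pracma::gaussHermite(spec$nodes)
  ad <- agq_adapt(eta, cache, pi, theta, sigma)
  agq_eval(beta, gamma0, ltheta, lsigma, cache, gh, ad$m, ad$s)$loglik
}

#' Fit the mixed-effects zero-inflated negative binomial model
#'
#' Maximizes the adaptive Gauss-Hermite marginal likelihood by L-BFGS-B
#' with analytic gradients, re-adapting the quadrature nodes between
#' optimizer passes until the log-likelihood stabilizes. Initialization:
#' count-part coefficients from a fixed-effects Poisson fit, `log theta =
#' 0`, `gamma0` from the observed excess of zeros over the Poisson fit
#' (floored at 1%), `log sigma_b` from the between-unit spread of residual
#' rates. The covariance matrix comes from the inverse observed
#' information (numeric Hessian of the objective via central differences
#' of the analytic gradient). Failure to meet tolerances within the
#' iteration budget sets `converged = FALSE`; it never throws.
#'
#' `log sigma_b` is box-bounded below at `log(1e-6)` and `gamma0` at -20;
#' parameters that end on a bound are listed in `$boundary` and their
#' covariance entries are set to `NA` (non-interpretable).
#'
#' @param spec a `zinb_spec`, or a `design_matrices` (default settings).
#' @param fixed optional named list pinning any of `gamma0` (may be
#'   `-Inf` for a pure NB model), `log_theta`, `log_sigma_b` at known
#'   values instead of estimating them.
#' @return object of class `zinb_mixed_fit` with elements `beta` (named),
#'   `gamma0`, `log_theta`, `log_sigma_b`, `theta`, `sigma_b`, `pi0`,
#'   `vcov` (free parameters), `loglik`, `converged`, `grad_norm`,
#'   `n_units`, `n_obs`, `boundary`, `fixed`.
#' @export
fit_zinb_mixed <- function(spec, fixed = list()) {
  if (inherits(spec, "design_matrices")) spec <- zinb_spec(spec)
  design <- spec$design
  cache <- fit_cache(design)
  if (all(cache$y == 0L))
    abort_class("zinbpanel_input_error",
                "all counts are zero: zero-inflation intercept is unbounded")
  free_sigma <- !("log_sigma_b" %in% names(fixed))
  if (cache$G < 2L && free_sigma)
    abort_class("zinbpanel_input_error",
                "need >= 2 units to estimate a random-intercept SD")
  p <- ncol(cache$X)

  # Standardize non-intercept columns for optimizer conditioning; the
  # fitted coefficients and covariance are mapped back afterwards.
  has_int <- colnames(cache$X)[1L] == "(Intercept)" &&
    all(cache$X[, 1L] == 1)
  ctr <- rep(0, p); scl <- rep(1, p)
  if (has_int && p > 1L) {
    for (j in 2:p) {
      ctr[j] <- mean(cache$X[, j])
      s <- stats::sd(cache$X[, j])
      scl[j] <- if (is.finite(s) && s > 0) s else 1
    }
    Xs <- cache$X
    Xs[, -1L] <- sweep(sweep(Xs[, -1L, drop = FALSE], 2L, ctr[-1L]),
                       2L, scl[-1L], "/")
    cache$X <- Xs
  }
  # maps scaled-basis coefficients to the original basis
  unscale_beta <- function(bs) {
    b <- bs / scl
    if (has_int) b[1L] <- bs[1L] - sum(bs[-1L] * ctr[-1L] / scl[-1L])
    b
  }

  # --- initialization -------------------------------------------------
  pf <- suppressWarnings(stats::glm.fit(cache$X, cache$y,
                                        family = stats::poisson()))
  beta0 <- pf$coefficients
  beta0[!is.finite(beta0)] <- 0
  fitv <- pmax(pf$fitted.values, 1e-8)
  p0_obs <- mean(cache$y == 0L)
  p0_fit <- mean(exp(-fitv))
  excess <- (p0_obs - p0_fit) / max(1 - p0_fit, 1e-6)
  gamma0_init <- stats::qlogis(min(max(excess, 0.01), 0.9))
  agg_y <- rowsum(cache$y, cache$gi)[, 1L]
  agg_f <- rowsum(fitv, cache$gi)[, 1L]
  lr <- log((agg_y + 0.5) / (agg_f + 0.5))
  lsigma_init <- log(min(max(stats::sd(lr), 0.02), 2))

  nuis_names <- c("gamma0", "log_theta", "log_sigma_b")
  nuis_init <- c(gamma0 = gamma0_init, log_theta = 0, log_sigma_b = lsigma_init)
  nuis_lower <- c(gamma0 = -20, log_theta = -10, log_sigma_b = log(1e-6))
  nuis_upper <- c(gamma0 = 10, log_theta = 25, log_sigma_b = 3)
  fixed_mask <- nuis_names %in% names(fixed)
  names(fixed_mask) <- nuis_names
  nuis_val <- nuis_init
  for (nm in names(fixed)) {
    if (!nm %in% nuis_names)
      abort_class("zinbpanel_input_error",
                  paste("fixed: unknown parameter", nm))
    nuis_val[nm] <- fixed[[nm]]
  }

  pack <- function(beta, nuis) c(beta, nuis[!fixed_mask])
  unpack <- function(par) {
    nuis <- nuis_val
    nuis[!fixed_mask] <- par[-seq_len(p)]
    list(beta = par[seq_len(p)], nuis = nuis)
  }
  par <- pack(beta0, nuis_init)
  lower <- c(rep(-Inf, p), nuis_lower[!fixed_mask])
  upper <- c(rep(Inf, p), nuis_upper[!fixed_mask])

  gh <- pracma::gaussHermite(spec$nodes)
  no_quad <- !free_sigma && exp(nuis_val["log_sigma_b"]) < 1e-10

  eval_fixed_nodes <- function(par, m, s, grad) {
    u <- unpack(par)
    if (no_quad) {
      res <- agq_point_eval(u$beta, u$nuis[["gamma0"]], u$nuis[["log_theta"]],
                            cache, grad)
    } else {
      res <- agq_eval(u$beta, u$nuis[["gamma0"]], u$nuis[["log_theta"]],
                      u$nuis[["log_sigma_b"]], cache, gh, m, s, grad)
    }
    if (grad) res$grad <- res$grad[c(rep(TRUE, p), !fixed_mask)]
    res
  }

  adapt_at <- function(par, m_prev = NULL) {
    if (no_quad) return(list(m = NULL, s = NULL))
    u <- unpack(par)
    pi <- if (is.finite(u$nuis[["gamma0"]])) stats::plogis(u$nuis[["gamma0"]]) else 0
    eta <- drop(cache$X %*% u$beta)
    if (!all(is.finite(eta))) eta <- pmin(eta, 50)
    agq_adapt(eta, cache, pi, exp(u$nuis[["log_theta"]]),
              exp(u$nuis[["log_sigma_b"]]), m = m_prev)
  }

  ll_prev <- -Inf; opt <- NULL; ad <- NULL
  n_outer <- 0L
  for (round in seq_len(10L)) {
    n_outer <- round
    ad <- adapt_at(par, ad$m)
    last <- new.env(parent = emptyenv())
    fn <- function(q) {
      r <- eval_fixed_nodes(q, ad$m, ad$s, grad = TRUE)
      assign("par", q, envir = last); assign("res", r, envir = last)
      -r$loglik
    }
    gr <- function(q) {
      if (!is.null(last$par) && identical(q, last$par)) return(-last$res$grad)
      -eval_fixed_nodes(q, ad$m, ad$s, grad = TRUE)$grad
    }
    opt <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = spec$maxit, factr = 1e4,
                                       pgtol = spec$tol_grad))
    par <- opt$par
    ad <- adapt_at(par, ad$m)
    ll <- eval_fixed_nodes(par, ad$m, ad$s, grad = FALSE)$loglik
    if (abs(ll - ll_prev) < 1e-8 * (1 + abs(ll))) { ll_prev <- ll; break }
    ll_prev <- ll
  }
  ll <- ll_prev
  gfin <- eval_fixed_nodes(par, ad$m, ad$s, grad = TRUE)$grad

  # --- boundary detection --------------------------------------------
  free_names <- c(colnames(cache$X), nuis_names[!fixed_mask])
  at_bound <- abs(par - lower) < 1e-6 | abs(upper - par) < 1e-6
  boundary <- free_names[at_bound]

  # --- observed information ------------------------------------------
  nf <- length(par)
  H <- matrix(NA_real_, nf, nf, dimnames = list(free_names, free_names))
  hstep <- 6e-6 * (1 + abs(par))
  ok <- TRUE
  for (j in seq_len(nf)) {
    e <- rep(0, nf); e[j] <- hstep[j]
    gp <- eval_fixed_nodes(par + e, ad$m, ad$s, grad = TRUE)$grad
    gm <- eval_fixed_nodes(par - e, ad$m, ad$s, grad = TRUE)$grad
    H[, j] <- -(gp - gm) / (2 * hstep[j])
  }
  H <- (H + t(H)) / 2
  vc <- matrix(NA_real_, nf, nf, dimnames = list(free_names, free_names))
  est_idx <- which(!at_bound)
  Hs <- H[est_idx, est_idx, drop = FALSE]
  ev <- eigen(Hs, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-8)             # PSD jitter before inversion
  vci <- ev$vectors %*% (t(ev$vectors) / lam)
  # back-transform the covariance to the unstandardized basis
  A <- diag(nf)
  if (has_int && p > 1L) {
    for (j in 2:p) { A[j, j] <- 1 / scl[j]; A[1L, j] <- -ctr[j] / scl[j] }
  }
  As <- A[est_idx, est_idx, drop = FALSE]
  vci <- As %*% vci %*% t(As)
  vc[est_idx, est_idx] <- vci
  if (any(!is.finite(vci))) ok <- FALSE

  u <- unpack(par)
  nuis <- u$nuis
  beta <- unscale_beta(u$beta); names(beta) <- colnames(cache$X)
  structure(list(
    beta = beta,
    gamma0 = nuis[["gamma0"]], log_theta = nuis[["log_theta"]],
    log_sigma_b = nuis[["log_sigma_b"]],
    theta = exp(nuis[["log_theta"]]), sigma_b = exp(nuis[["log_sigma_b"]]),
    pi0 = if (is.finite(nuis[["gamma0"]])) stats::plogis(nuis[["gamma0"]]) else 0,
    vcov = vc, loglik = ll,
    converged = (opt$convergence == 0L) && ok,
    grad_norm = max(abs(gfin)),
    n_units = cache$G, n_obs = cache$n,
    boundary = boundary, fixed = fixed, nodes = spec$nodes,
    n_outer = n_outer, optim_message = opt$message,
    design_labels = colnames(cache$X)),
    class = "zinb_mixed_fit")
}

# Degenerate evaluation path with sigma_b pinned at (effectively) zero:
# plain sum of ZINB log-pmfs, no quadrature.
#' @noRd
agq_point_eval <- function(beta, gamma0, ltheta, cache, grad = FALSE) {
  theta <- exp(ltheta)
  pi <- if (is.finite(gamma0)) stats::plogis(gamma0) else 0
  eta <- drop(cache$X %*% beta)
  if (!all(is.finite(eta)) || max(eta) > 50) {
    out <- list(loglik = -1e10)
    if (grad) out$grad <- rep(0, length(beta) + 3L)
    return(out)
  }
  tm <- zinb_row_terms(eta, cache, pi, theta, what = if (grad) "grad" else "lp")
  out <- list(loglik = sum(tm$lp))
  if (grad)
    out$grad <- c(drop(crossprod(cache$X, tm$d1)), sum(tm$dg0), sum(tm$dlt), 0)
  out
}

#' @export
print.zinb_mixed_fit <- function(x, ...) {
  cat(sprintf(
    "Mixed-effects zero-inflated negative binomial fit\n  %d obs, %d units; loglik %.3f; %s\n",
    x$n_obs, x$n_units, x$loglik,
    if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  theta = %.4g, sigma_b = %.4g, pi0 = %.4g\n",
              x$theta, x$sigma_b, x$pi0))
  se <- sqrt(diag(x$vcov))[seq_along(x$beta)]
  print(data.frame(estimate = x$beta, se = se))
  if (length(x$boundary))
    cat("  at boundary:", paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.zinb_mixed_fit <- function(object, ...) object$beta

#' @export
vcov.zinb_mixed_fit <- function(object, ...) object$vcov

#' @export
logLik.zinb_mixed_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 3L -
              length(object$fixed), class = "logLik")
}

#' Expected counts from a fitted mixed ZINB model
#'
#' By default returns the population-level mean, marginal over both the
#' random intercept and the zero-inflation:
#' `(1 - pi) * exp(x'beta) * exp(sigma_b^2 / 2)`. With
#' `type = "conditional"` the mean conditional on `b = 0`,
#' `(1 - pi) * exp(x'beta)`, is returned instead.
#'
#' @param fit a `zinb_mixed_fit`.
#' @param X design rows (matrix with the same column labels as the fit, or
#'   a `design_matrices`).
#' @param type `"population"` (default) or `"conditional"`.
#' @return numeric vector of expected counts, one per row.
#' @export
predict_mean <- function(fit, X, type = c("population", "conditional")) {
  type <- match.arg(type)
  if (inherits(X, "design_matrices")) X <- X$X
  if (!identical(colnames(X), fit$design_labels))
    abort_class("zinbpanel_input_error",
                "design column labels do not match the fitted model")
  eta <- drop(X %*% fit$beta)
  f <- (1 - fit$pi0) * exp(eta)
  if (type == "population") f <- f * exp(fit$sigma_b^2 / 2)
  f
}

#' Write a fit report (text) and coefficient table (CSV)
#'
#' @param fit a `zinb_mixed_fit`.
#' @param report_path path for the structured text report.
#' @param csv_path optional path for the coefficient CSV.
#' @return `report_path`, invisibly.
#' @export
write_fit_report <- function(fit, report_path, csv_path = NULL) {
  se <- sqrt(diag(fit$vcov))
  tab <- data.frame(parameter = names(fit$beta),
                    estimate = unname(fit$beta),
                    se = unname(se[seq_along(fit$beta)]))
  lines <- c(
    "mixed-effects zero-inflated negative binomial fit",
    sprintf("n_obs: %d", fit$n_obs),
    sprintf("n_units: %d", fit$n_units),
    sprintf("loglik: %.6f", fit$loglik),
    sprintf("converged: %s", fit$converged),
    sprintf("grad_norm: %.3g", fit$grad_norm),
    sprintf("theta: %.6g", fit$theta),
    sprintf("sigma_b: %.6g", fit$sigma_b),
    sprintf("pi0: %.6g", fit$pi0),
    if (length(fit$boundary))
      sprintf("boundary: %s", paste(fit$boundary, collapse = ",")) else NULL,
    "coefficients:",
    sprintf("  %s = %.8g (se %.3g)", tab$parameter, tab$estimate, tab$se))
  writeLines(lines, report_path)
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  invisible(report_path)
}
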