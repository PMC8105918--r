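# Zero-inflated negative binomial probability functions.
#
# Parameterization: the negative binomial has mean mu and dispersion
# theta, pmf P(y) = Gamma(y+theta) / (Gamma(theta) y!) *
# (theta/(theta+mu))^theta * (mu/(theta+mu))^y, variance mu + mu^2/theta.
# The zero-inflated mixture puts mass pi on a structural zero:
# P(0) = pi + (1-pi) NB(0), P(y>0) = (1-pi) NB(y).

#' Negative binomial log-pmf (mean/dispersion parameterization)
#'
#' Computed through log-gamma so counts up to 1e6 do not overflow.
#' Vectorized over all arguments.
#'
#' @param y non-negative integer counts.
#' @param mu mean, strictly positive.
#' @param theta dispersion, strictly positive; variance is
#'   `mu + mu^2/theta`, so large `theta` approaches the Poisson.
#' @return log probabilities.
#' @export
nb_log_pmf <- function(y, mu, theta) {
  if (any(mu <= 0)) abort_class("zinbpanel_domain_error", "nb_log_pmf(): mu must be > 0")
  if (any(theta <= 0)) abort_class("zinbpanel_domain_error", "nb_log_pmf(): theta must be > 0")
  if (any(y < 0) || any(y != round(y)))
    abort_class("zinbpanel_domain_error", "nb_log_pmf(): y must be non-negative integers")
  lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    theta * (log(theta) - log(theta + mu)) +
    y * (log(mu) - log(theta + mu))
}

#' Zero-inflated negative binomial log-pmf
#'
#' The y = 0 branch is evaluated with log-sum-exp so small mixture
#' probabilities do not cancel catastrophically.
#'
#' @inheritParams nb_log_pmf
#' @param pi zero-inflation probability, in `[0, 1)`.
#' @return log probabilities.
#' @export
zinb_log_pmf <- function(y, mu, theta, pi) {
  if (any(pi < 0 | pi >= 1))
    abort_class("zinbpanel_domain_error", "zinb_log_pmf(): pi must be in [0, 1)")
  lp <- nb_log_pmf(y, mu, theta)
  if (all(pi == 0)) return(lp)
  lp <- log1p(-pi) + lp
  z <- y == 0
  if (any(z)) {
    # log(pi + (1-pi) NB(0)) via log-sum-exp
    a <- log(pi)[if (length(pi) > 1) z else TRUE]
    b <- lp[z]
    mx <- pmax(a, b)
    lp[z] <- mx + log(exp(a - mx) + exp(b - mx))
  }
  lp
}

#' Draw from the zero-inflated negative binomial
#'
#' @param n number of draws.
#' @inheritParams zinb_log_pmf
#' @return integer vector of counts.
#' @export
rzinb <- function(n, mu, theta, pi) {
  if (any(pi < 0 | pi >= 1))
    abort_class("zinbpanel_domain_error", "rzinb(): pi must be in [0, 1)")
  y <- stats::rnbinom(n, size = theta, mu = mu)
  if (any(pi > 0)) {
    z <- stats::runif(n) < pi
    y[z] <- 0L
  }
  as.integer(y)
}
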