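#' Negative binomial (NB2) log probability mass
#'
#' Log pmf of the negative binomial in its NB2 parameterization: mean `mu`
#' and dispersion `omega`, so that `Var(Y) = mu + mu^2 / omega`. Large
#' `omega` approaches the Poisson. This is the observation model used for
#' RNA-Seq counts throughout the package.
#'
#' @param y Vector of non-negative integer counts.
#' @param mu Positive mean(s), recycled against `y`.
#' @param omega Positive dispersion(s), recycled against `y`.
#' @return Numeric vector of log probabilities, same length as `y`.
#' @examples
#' nb2_log_pmf(0:5, mu = 2, omega = 1)
#' @export
nb2_log_pmf <- function(y, mu, omega) {
  if (!is.numeric(y) || any(y < 0) || any(y != floor(y))) {
    abort("`y` must contain non-negative integers.")
  }
  if (any(mu <= 0) || any(!is.finite(mu))) abort("`mu` must be positive and finite.")
  if (any(omega <= 0)) abort("`omega` must be positive.")
  dnbinom(y, size = omega, mu = mu, log = TRUE)
}

#' Draw NB2 counts
#'
#' @param n Number of draws.
#' @param mu Positive mean(s).
#' @param omega Positive dispersion(s).
#' @return Integer vector of counts.
#' @export
rnb2 <- function(n, mu, omega) {
  if (any(mu <= 0) || any(omega <= 0)) abort("`mu` and `omega` must be positive.")
  rnbinom(n, size = omega, mu = mu)
}

#' Monte-Carlo check of the Poisson-Gamma mixture identity
#'
#' The NB2 distribution arises by mixing a Poisson rate over a Gamma:
#' `lambda ~ Gamma(omega, omega / mu)` (shape/rate), `y | lambda ~ Pois(lambda)`.
#' This draws `n_draws` rates, averages the Poisson pmf over them for each
#' count value up to the upper 0.99999 NB2 quantile, and returns the maximum
#' absolute deviation from the closed-form NB2 pmf. Used as a self-test of
#' the augmentation the inference engine relies on.
#'
#' @param mu,omega NB2 mean and dispersion.
#' @param n_draws Number of Monte-Carlo draws (at least 1e4).
#' @param seed Integer seed.
#' @return Maximum absolute pmf deviation, with attributes `se_max` (largest
#'   Monte-Carlo standard error across count values) and `n_draws`.
#' @export
poisson_gamma_mixture_check <- function(mu, omega, n_draws = 1e5, seed = 1L) {
  if (n_draws < 1e4) abort("`n_draws` must be at least 1e4.")
  if (mu <= 0 || omega <= 0) abort("`mu` and `omega` must be positive.")
  y_max <- stats::qnbinom(1 - 1e-5, size = omega, mu = mu)
  ys <- 0:y_max
  lam <- with_seed(seed, rgamma(n_draws, shape = omega, rate = omega / mu))
  dev <- numeric(length(ys))
  se <- numeric(length(ys))
  for (i in seq_along(ys)) {
    p_mc <- dpois(ys[i], lam)
    dev[i] <- abs(mean(p_mc) - exp(nb2_log_pmf(ys[i], mu, omega)))
    se[i] <- sd(p_mc) / sqrt(n_draws)
  }
  structure(max(dev), se_max = max(se), n_draws = n_draws)
}
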