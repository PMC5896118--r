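# Inverse-gamma helpers (shape/scale parameterization). The horseshoe
# hierarchy is a chain of InvGamma(1/2, 1/s) mixtures, and all variational
# factors on the scale parameters are inverse gamma, so these moments are
# used throughout the inference engine.

ig_e_inv <- function(shape, scale) shape / scale

ig_e_log <- function(shape, scale) log(scale) - digamma(shape)

ig_entropy <- function(shape, scale) {
  shape + log(scale) + lgamma(shape) - (1 + shape) * digamma(shape)
}

ig_log_density <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

rinvgamma <- function(n, shape, scale) 1 / rgamma(n, shape = shape, rate = scale)

#' Check the inverse-gamma scale-mixture representation of the half-Cauchy
#'
#' The horseshoe prior puts a half-Cauchy prior on each local scale:
#' `zeta ~ C+(0, tau)`. The inference engine never works with the
#' half-Cauchy directly but with the equivalent chain
#' `zeta^2 | a ~ InvGamma(1/2, 1/a)`, `a ~ InvGamma(1/2, 1/tau^2)`.
#' This draws `zeta^2` through the chain (with `tau` fixed) and returns the
#' Kolmogorov-Smirnov distance between `sqrt(zeta^2)` and the half-Cauchy
#' CDF, as a self-test of the representation.
#'
#' @param tau Half-Cauchy scale.
#' @param n_draws Number of draws (at least 1e4).
#' @param seed Integer seed.
#' @return KS distance (numeric scalar) with attribute `n_draws`.
#' @export
horseshoe_marginal_check <- function(tau, n_draws = 1e5, seed = 1L) {
  if (n_draws < 1e4) abort("`n_draws` must be at least 1e4.")
  if (tau <= 0) abort("`tau` must be positive.")
  zeta <- with_seed(seed, {
    a <- rinvgamma(n_draws, shape = 0.5, scale = 1 / tau^2)
    sqrt(rinvgamma(n_draws, shape = 0.5, scale = 1 / a))
  })
  half_cauchy_cdf <- function(q) 2 / pi * atan(q / tau)
  ks <- suppressWarnings(ks.test(zeta, half_cauchy_cdf))
  structure(unname(ks$statistic), n_draws = n_draws)
}
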