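#' Log joint probability of data and parameters
#'
#' Evaluates the unnormalized log joint of one gene's regression model at a
#' full parameter setting: the NB2 likelihood of the counts given the linear
#' predictor, the normal prior on the intercept, the normal/local-scale
#' priors on the slopes, the gamma prior on the dispersion, and (when the
#' corresponding parameters are supplied) the inverse-gamma chain that
#' represents the half-Cauchy scales of the horseshoe. Prior terms for
#' hierarchy levels whose parameters are `NULL` are omitted, which makes the
#' function directly usable as the integrand of brute-force evidence
#' calculations on fixed-hyperparameter toys.
#'
#' @param problem A [regression_problem()].
#' @param beta Coefficient vector of length W + 1 (intercept last).
#' @param omega Positive dispersion.
#' @param zeta2 Positive local scale variances (length W).
#' @param a,tau2,b,sigma2 Optional deeper levels of the horseshoe hierarchy.
#' @param config A [vb_config()] supplying the intercept prior variance and
#'   the gamma prior on the dispersion.
#' @param include_omega_prior Include the gamma prior term for `omega`?
#' @return Log joint density (numeric scalar).
#' @export
joint_log_prob <- function(problem, beta, omega, zeta2,
                           a = NULL, tau2 = NULL, b = NULL, sigma2 = NULL,
                           config = vb_config(),
                           include_omega_prior = TRUE) {
  stopifnot(inherits(problem, "regression_problem"))
  W <- length(problem$predictors)
  if (length(beta) != W + 1) abort("`beta` must have length W + 1.")
  if (length(zeta2) != W) abort("`zeta2` must have length W.")
  if (omega <= 0 || any(zeta2 <= 0)) abort("`omega` and `zeta2` must be positive.")
  eta <- drop(problem$X %*% beta) + problem$offset
  lp <- sum(nb2_log_pmf(problem$y, exp(eta), omega))
  lp <- lp + dnorm(beta[W + 1], 0, sqrt(config$intercept_var), log = TRUE)
  if (W > 0) lp <- lp + sum(dnorm(beta[seq_len(W)], 0, sqrt(zeta2), log = TRUE))
  if (include_omega_prior) {
    lp <- lp + dgamma(omega, shape = config$omega_prior_shape,
                      rate = config$omega_prior_rate, log = TRUE)
  }
  if (!is.null(a)) {
    if (length(a) != W || any(a <= 0)) abort("`a` must be positive, length W.")
    lp <- lp + sum(ig_log_density(zeta2, 0.5, 1 / a))
    if (!is.null(tau2)) lp <- lp + sum(ig_log_density(a, 0.5, 1 / tau2))
  }
  if (!is.null(tau2) && !is.null(b)) lp <- lp + ig_log_density(tau2, 0.5, 1 / b)
  if (!is.null(b) && !is.null(sigma2)) {
    lp <- lp + ig_log_density(b, 0.5, 1 / sigma2) - log(sigma2)
  }
  lp
}
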