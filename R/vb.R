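# Variational inference engine for one gene's sparse NB regression.
#
# Augmented model: y_t | lambda_t ~ Pois(lambda_t),
# lambda_t | beta, omega ~ Gamma(omega, omega * exp(-eta_t)) with
# eta_t = X_t beta + offset_t, so that marginally y_t is NB2 with mean
# exp(eta_t) and dispersion omega. Mean-field factors:
#   q(lambda_t)  Gamma(shape, rate), one per transition row
#   q(beta)      multivariate normal (mu, Sigma), updated by NCVMP
#   q(omega)     discrete weights on a quadrature grid
#   q(zeta2_w), q(a_w), q(tau2), q(b), q(sigma2)  inverse gamma

#' Initialize a variational state
#'
#' @param problem A [regression_problem()].
#' @param config A [vb_config()].
#' @return A list of class `vb_state` holding all approximating-distribution
#'   parameters, the configuration, and an empty ELBO trace.
#' @export
init_state <- function(problem, config = vb_config()) {
  stopifnot(inherits(problem, "regression_problem"))
  N <- length(problem$y)
  W <- length(problem$predictors)
  grid <- exp(seq(log(config$omega_range[1]), log(config$omega_range[2]),
                  length.out = config$omega_grid_size))
  if (!is.null(config$fixed_omega)) {
    grid <- config$fixed_omega
    omega_w <- 1
  } else {
    lw <- dgamma(grid, shape = config$omega_prior_shape,
                 rate = config$omega_prior_rate, log = TRUE)
    omega_w <- normalize_log_weights(lw)
  }
  mu <- c(rep(0, W), log(mean(problem$y / exp(problem$offset)) + 1e-6))
  state <- structure(list(
    mu = mu,
    Sigma = diag(0.1, W + 1),
    lam_shape = problem$y + 1,
    lam_rate = rep(2, N),
    omega_grid = grid,
    omega_w = omega_w,
    zeta2_shape = 1, zeta2_scale = rep(1, W),
    a_shape = 1, a_scale = rep(1, W),
    tau2_shape = (1 + W) / 2, tau2_scale = 1,
    b_shape = 1, b_scale = 1,
    sigma2_shape = 1 / 2, sigma2_scale = 1,
    n_clipped = 0L,
    iter = 0L,
    elbo_trace = numeric(0),
    converged = NA,
    config = config
  ), class = "vb_state")
  state
}

normalize_log_weights <- function(lw) {
  m <- max(lw)
  if (!is.finite(m)) {
    abort("all quadrature weights underflowed; widen `omega_range`.")
  }
  w <- exp(lw - m)
  w / sum(w)
}

# Moments of q(omega) needed by the updates and the ELBO.
omega_moments <- function(state) {
  g <- state$omega_grid
  w <- state$omega_w
  list(E = sum(w * g),
       Elog = sum(w * log(g)),
       Ewlogw = sum(w * g * log(g)),
       Elgam = sum(w * lgamma(g)))
}

# E[1/zeta2_w], honouring the fixed-zeta2 mode.
e_inv_zeta2 <- function(state) {
  cfg <- state$config
  W <- length(state$zeta2_scale)
  if (!is.null(cfg$fixed_zeta2)) rep(1 / cfg$fixed_zeta2, W)
  else ig_e_inv(state$zeta2_shape, state$zeta2_scale)
}

#' Expected inverse-link of the linear predictor
#'
#' Computes `E_q[exp(-eta_t)] = exp(-X_t mu - offset_t + X_t Sigma X_t' / 2)`
#' for every design row, using the log-normal mean identity for the Gaussian
#' `q(beta)`. Exponents are clipped at the configured bound; the number of
#' clipped rows is recorded in the `n_clipped` attribute.
#'
#' @param state A `vb_state`.
#' @param problem The matching [regression_problem()].
#' @return Numeric vector, one value per design row.
#' @export
neg_linear_predictor_expectation <- function(state, problem) {
  X <- problem$X
  quad <- rowSums((X %*% state$Sigma) * X)
  expo <- -drop(X %*% state$mu) - problem$offset + quad / 2
  clip <- state$config$clip
  n_clip <- sum(abs(expo) > clip)
  structure(exp(pmin(pmax(expo, -clip), clip)), n_clipped = n_clip)
}

#' Update the per-transition Poisson rates q(lambda)
#'
#' Each factor becomes `Gamma(y_t + E[omega], 1 + E[omega] E[exp(-eta_t)])`.
#'
#' @inheritParams neg_linear_predictor_expectation
#' @return The state with updated `lam_shape`, `lam_rate`.
#' @export
update_lambda <- function(state, problem) {
  om <- omega_moments(state)
  w <- neg_linear_predictor_expectation(state, problem)
  state$n_clipped <- state$n_clipped + attr(w, "n_clipped")
  state$lam_shape <- problem$y + om$E
  state$lam_rate <- 1 + om$E * as.numeric(w)
  state
}

#' Non-conjugate variational message passing step for q(beta)
#'
#' One NCVMP step: with `w_t = E[exp(-eta_t)]` and prior precision
#' `M = diag(E[1/zeta2_w], 1/intercept_var)`,
#' `Sigma = [E(omega) X' diag(E(lambda) w) X + M]^-1` and
#' `mu <- mu + Sigma [E(omega) X'(E(lambda) w - 1) - M mu]`.
#' NCVMP does not guarantee a monotone ELBO, so when `damp = TRUE` a step
#' that lowers the ELBO beyond tolerance is halved (convex combination of
#' old and new mu, Sigma) up to `damping_max` times.
#'
#' @inheritParams neg_linear_predictor_expectation
#' @param damp Apply ELBO-guarded step halving?
#' @return The state with updated `mu`, `Sigma`.
#' @export
update_beta <- function(state, problem, damp = TRUE) {
  cfg <- state$config
  X <- problem$X
  W <- length(problem$predictors)
  om <- omega_moments(state)
  w <- as.numeric(neg_linear_predictor_expectation(state, problem))
  e_lam <- state$lam_shape / state$lam_rate
  m_diag <- c(e_inv_zeta2(state), 1 / cfg$intercept_var)
  d <- e_lam * w
  prec <- om$E * crossprod(X * sqrt(d)) + diag(m_diag, W + 1)
  ch <- tryCatch(chol(prec), error = function(e) {
    abort(paste0("singular precision matrix in the coefficient update ",
                 "(min prior precision ", format(min(m_diag)), "); ",
                 "check for collinear or constant predictors."))
  })
  Sigma_new <- chol2inv(ch)
  grad <- om$E * crossprod(X, d - 1) - m_diag * state$mu
  mu_new <- state$mu + drop(Sigma_new %*% grad)

  if (!damp || cfg$damping_max == 0) {
    state$mu <- mu_new
    state$Sigma <- Sigma_new
    return(state)
  }
  e_old <- elbo(state, problem)
  cand <- state
  step <- 1
  for (h in 0:cfg$damping_max) {
    cand$mu <- (1 - step) * state$mu + step * mu_new
    cand$Sigma <- (1 - step) * state$Sigma + step * Sigma_new
    e_new <- elbo(cand, problem)
    if (e_new >= e_old - cfg$damping_tol * (1 + abs(e_old))) break
    step <- step / 2
  }
  cand
}

#' Quadrature update of the dispersion factor q(omega)
#'
#' Weights are proportional to
#' `exp(sum_t E_q[log p(lambda_t | X_t, beta, omega)] + log p(omega))`
#' evaluated pointwise on the grid and normalized with log-sum-exp. With an
#' empty problem the weights reduce to the gamma prior restricted to the
#' grid.
#'
#' @inheritParams neg_linear_predictor_expectation
#' @return The state with updated `omega_w`.
#' @export
update_omega <- function(state, problem) {
  cfg <- state$config
  if (!is.null(cfg$fixed_omega)) return(state)
  g <- state$omega_grid
  N <- length(problem$y)
  if (N > 0) {
    eta_bar <- drop(problem$X %*% state$mu) + problem$offset
    w <- as.numeric(neg_linear_predictor_expectation(state, problem))
    e_lam <- state$lam_shape / state$lam_rate
    e_loglam <- digamma(state$lam_shape) - log(state$lam_rate)
    s_eta <- sum(eta_bar); s_ll <- sum(e_loglam); s_lw <- sum(e_lam * w)
    ll <- N * g * log(g) - g * s_eta - N * lgamma(g) +
      (g - 1) * s_ll - g * s_lw
  } else {
    ll <- 0
  }
  lw <- ll + dgamma(g, shape = cfg$omega_prior_shape,
                    rate = cfg$omega_prior_rate, log = TRUE)
  state$omega_w <- normalize_log_weights(lw)
  state
}

#' Closed-form updates of the horseshoe scale factors
#'
#' Updates, in order, `q(zeta2_w)`, `q(a_w)`, `q(tau2)`, `q(b)`,
#' `q(sigma2)`, each inverse gamma with fixed shape (1, 1, (1+W)/2, 1, 1/2)
#' and a scale assembled from the freshest reciprocal expectations of its
#' neighbours in the hierarchy.
#'
#' @param state A `vb_state`.
#' @return The updated state. A no-op in fixed-zeta2 mode.
#' @export
update_horseshoe <- function(state) {
  cfg <- state$config
  if (!is.null(cfg$fixed_zeta2)) return(state)
  W <- length(state$zeta2_scale)
  if (W == 0) return(state)
  e_b2 <- state$mu[seq_len(W)]^2 + diag(state$Sigma)[seq_len(W)]
  state$zeta2_scale <- 0.5 * e_b2 + ig_e_inv(state$a_shape, state$a_scale)
  inv_z <- ig_e_inv(state$zeta2_shape, state$zeta2_scale)
  inv_t2 <- ig_e_inv(state$tau2_shape, state$tau2_scale)
  state$a_scale <- inv_z + inv_t2
  inv_a <- ig_e_inv(state$a_shape, state$a_scale)
  state$tau2_scale <- ig_e_inv(state$b_shape, state$b_scale) + sum(inv_a)
  inv_t2 <- ig_e_inv(state$tau2_shape, state$tau2_scale)
  state$b_scale <- inv_t2 + ig_e_inv(state$sigma2_shape, state$sigma2_scale)
  state$sigma2_scale <- ig_e_inv(state$b_shape, state$b_scale)
  state
}

#' Evidence lower bound
#'
#' `E_q[log p(theta, y)] - E_q[log q(theta)]` for the augmented model, with
#' the Poisson rates integrated through their Gamma factors. In the
#' fixed-omega / fixed-zeta2 modes the corresponding prior and entropy terms
#' are constants and are omitted, making the value an exact lower bound on
#' the log evidence of the reduced model; in the full model the dispersion
#' enters through its discrete quadrature factor and the value is used for
#' convergence monitoring.
#'
#' @inheritParams neg_linear_predictor_expectation
#' @return Numeric scalar.
#' @export
elbo <- function(state, problem) {
  cfg <- state$config
  y <- problem$y
  X <- problem$X
  N <- length(y)
  Wp1 <- ncol(X)
  W <- Wp1 - 1L
  mu <- state$mu
  Sig <- state$Sigma
  eta_bar <- drop(X %*% mu) + problem$offset
  w <- as.numeric(neg_linear_predictor_expectation(state, problem))
  a_l <- state$lam_shape; r_l <- state$lam_rate
  e_lam <- a_l / r_l
  e_loglam <- digamma(a_l) - log(r_l)
  om <- omega_moments(state)

  # E log p(y | lambda) + E log p(lambda | beta, omega) - E log q(lambda)
  t_y <- sum(y * e_loglam - e_lam - lgamma(y + 1))
  t_lam <- N * om$Ewlogw - om$E * sum(eta_bar) - N * om$Elgam +
    (om$E - 1) * sum(e_loglam) - om$E * sum(e_lam * w)
  ent_lam <- -sum(a_l * log(r_l) - lgamma(a_l) + (a_l - 1) * e_loglam -
                    r_l * e_lam)

  # coefficient prior and entropy
  e_b2 <- mu^2 + diag(Sig)
  if (!is.null(cfg$fixed_zeta2)) {
    elog_z <- rep(log(cfg$fixed_zeta2), W)
    einv_z <- rep(1 / cfg$fixed_zeta2, W)
  } else {
    elog_z <- ig_e_log(state$zeta2_shape, state$zeta2_scale)
    einv_z <- ig_e_inv(state$zeta2_shape, state$zeta2_scale)
  }
  t_beta <- -0.5 * Wp1 * log(2 * pi) -
    0.5 * log(cfg$intercept_var) - e_b2[Wp1] / (2 * cfg$intercept_var)
  if (W > 0) {
    t_beta <- t_beta - 0.5 * sum(elog_z) -
      0.5 * sum(e_b2[seq_len(W)] * einv_z)
  }
  ent_beta <- 0.5 * Wp1 * (1 + log(2 * pi)) +
    0.5 * determinant(Sig, logarithm = TRUE)$modulus[1]

  total <- t_y + t_lam + ent_lam + t_beta + ent_beta

  # dispersion prior + entropy (skipped when omega is fixed)
  if (is.null(cfg$fixed_omega)) {
    g <- state$omega_grid; qw <- state$omega_w
    pos <- qw > 0
    total <- total +
      sum(qw * dgamma(g, shape = cfg$omega_prior_shape,
                      rate = cfg$omega_prior_rate, log = TRUE)) -
      sum(qw[pos] * log(qw[pos]))
  }

  # horseshoe chain (skipped when zeta2 is fixed)
  if (is.null(cfg$fixed_zeta2) && W > 0) {
    einv_a <- ig_e_inv(state$a_shape, state$a_scale)
    elog_a <- ig_e_log(state$a_shape, state$a_scale)
    einv_t2 <- ig_e_inv(state$tau2_shape, state$tau2_scale)
    elog_t2 <- ig_e_log(state$tau2_shape, state$tau2_scale)
    einv_b <- ig_e_inv(state$b_shape, state$b_scale)
    elog_b <- ig_e_log(state$b_shape, state$b_scale)
    einv_s2 <- ig_e_inv(state$sigma2_shape, state$sigma2_scale)
    elog_s2 <- ig_e_log(state$sigma2_shape, state$sigma2_scale)
    lg_half <- lgamma(0.5)
    total <- total +
      sum(-0.5 * elog_a - lg_half - 1.5 * elog_z - einv_a * einv_z) +
      sum(-0.5 * elog_t2 - lg_half - 1.5 * elog_a - einv_t2 * einv_a) +
      (-0.5 * elog_b - lg_half - 1.5 * elog_t2 - einv_b * einv_t2) +
      (-0.5 * elog_s2 - lg_half - 1.5 * elog_b - einv_s2 * einv_b) +
      (-elog_s2) +
      sum(ig_entropy(state$zeta2_shape, state$zeta2_scale)) +
      sum(ig_entropy(state$a_shape, state$a_scale)) +
      ig_entropy(state$tau2_shape, state$tau2_scale) +
      ig_entropy(state$b_shape, state$b_scale) +
      ig_entropy(state$sigma2_shape, state$sigma2_scale)
  }
  total
}

#' Fit one gene's sparse NB regression by variational inference
#'
#' Runs the coordinate cycle `q(lambda)` -> `q(beta)` -> `q(omega)` ->
#' horseshoe scales until the relative ELBO change falls below `tol` or
#' `max_iter` sweeps are reached. The fit is deterministic given the data
#' and configuration.
#'
#' @param problem A [regression_problem()].
#' @param config A [vb_config()].
#' @return An object of class `nb_hs_fit` wrapping the converged state, the
#'   problem, the ELBO trace and a convergence flag. Non-convergence raises
#'   a warning, not an error.
#' @examples
#' y <- c(3, 5, 2, 6, 4, 7, 3, 5, 4, 6, 2, 5)
#' x <- scale(log1p(c(2, 4, 1, 5, 3, 6, 2, 4, 3, 5, 1, 4)))
#' prob <- regression_problem(y, cbind(x = as.numeric(x), 1))
#' fit <- fit_nb_horseshoe(prob, vb_config(max_iter = 50))
#' tidy(fit)
#' @export
fit_nb_horseshoe <- function(problem, config = vb_config()) {
  state <- init_state(problem, config)
  e_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    state <- update_lambda(state, problem)
    state <- update_beta(state, problem)
    state <- update_omega(state, problem)
    state <- update_horseshoe(state)
    e <- elbo(state, problem)
    state$elbo_trace <- c(state$elbo_trace, e)
    state$iter <- it
    if (config$verbose) inform(sprintf("sweep %d: ELBO %.6f", it, e))
    if (it > 1 && abs(e - e_prev) < config$tol * abs(e)) {
      converged <- TRUE
      break
    }
    e_prev <- e
  }
  state$converged <- converged
  if (!converged) {
    warn(sprintf("variational fit for gene %s did not converge in %d sweeps.",
                 problem$gene %||% "?", config$max_iter))
  }
  structure(list(state = state, problem = problem, config = config),
            class = "nb_hs_fit")
}

#' @export
print.nb_hs_fit <- function(x, ...) {
  cat(sprintf("<nb_hs_fit> gene %s: %d sweeps, ELBO %.4f, %sconverged\n",
              x$problem$gene %||% "?", x$state$iter,
              tail_elbo(x), if (isTRUE(x$state$converged)) "" else "NOT "))
  invisible(x)
}

tail_elbo <- function(fit) {
  tr <- fit$state$elbo_trace
  if (length(tr)) tr[length(tr)] else NA_real_
}

#' Posterior expectation of the dispersion
#'
#' @param fit An `nb_hs_fit`.
#' @return `E_q[omega]`.
#' @export
posterior_omega <- function(fit) {
  omega_moments(fit$state)$E
}

#' Tidy coefficient summaries of a variational fit
#'
#' @param x An `nb_hs_fit`.
#' @param conf.level Central credible interval level.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (intercept last):
#'   `term`, `estimate`, `std.error`, `conf.low`, `conf.high`, and `score`
#'   (the sign-probability edge score; see [edge_score()]).
#' @method tidy nb_hs_fit
#' @export
tidy.nb_hs_fit <- function(x, conf.level = 0.95, ...) {
  st <- x$state
  se <- sqrt(diag(st$Sigma))
  z <- qnorm(1 - (1 - conf.level) / 2)
  tibble(
    term = colnames(x$problem$X),
    estimate = st$mu,
    std.error = se,
    conf.low = st$mu - z * se,
    conf.high = st$mu + z * se,
    score = edge_score(st$mu, se)
  )
}

#' One-row summary of a variational fit
#'
#' @param x An `nb_hs_fit`.
#' @param ... Unused.
#' @return A tibble with the final ELBO, sweep count, convergence flag,
#'   posterior mean dispersion, problem size, and clip-event count.
#' @method glance nb_hs_fit
#' @export
glance.nb_hs_fit <- function(x, ...) {
  tibble(
    elbo = tail_elbo(x),
    iterations = x$state$iter,
    converged = isTRUE(x$state$converged),
    omega = posterior_omega(x),
    nobs = length(x$problem$y),
    n_predictors = length(x$problem$predictors),
    n_clipped = x$state$n_clipped
  )
}

#' Coefficient plot for a variational fit
#'
#' Posterior means with central credible intervals for every predictor.
#'
#' @param object An `nb_hs_fit`.
#' @param conf.level Credible interval level.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nb_hs_fit
#' @export
autoplot.nb_hs_fit <- function(object, conf.level = 0.95, ...) {
  td <- tidy(object, conf.level = conf.level)
  td <- filter(td, .data$term != "(intercept)")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "coefficient (posterior mean, CI)", y = NULL) +
    ggplot2::theme_minimal()
}
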