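# Closed-form correctness of each coordinate update, checked by direct
# substitution and against independent oracles.

make_state <- function(prob, config = vb_config()) init_state(prob, config)

test_that("q(lambda) update substitutes shape y + E[omega], rate 1 + E[omega]E[exp(-eta)]", {
  prob <- regression_problem(c(0, 5), cbind(x = c(0, 0), 1))
  st <- make_state(prob, vb_config(fixed_omega = 1))
  st$mu <- c(0, 0); st$Sigma <- matrix(0, 2, 2)
  st <- update_lambda(st, prob)
  # y = 0, E[omega] = 1, E[exp(-eta)] = 1 -> Gamma(1, 2), mean 1/2
  expect_equal(st$lam_shape[1], 1)
  expect_equal(st$lam_rate[1], 2)
  expect_equal((st$lam_shape / st$lam_rate)[1], 0.5)

  # y = 5, E[omega] = 2, E[exp(-eta)] = 0.5 -> Gamma(7, 2)
  st2 <- make_state(prob, vb_config(fixed_omega = 2))
  st2$mu <- c(0, log(2)); st2$Sigma <- matrix(0, 2, 2)
  st2 <- update_lambda(st2, prob)
  expect_equal(st2$lam_shape[2], 7)
  expect_equal(st2$lam_rate[2], 2)
})

test_that("q(lambda) matches the exact conjugate Poisson-Gamma posterior", {
  # one datum, beta degenerate at the truth: lambda | y is exactly
  # Gamma(y + omega, 1 + omega exp(-eta))
  y <- 9; eta <- log(6); omega <- 50
  prob <- regression_problem(c(y, y), cbind(x = c(0, 0), 1))
  st <- make_state(prob, vb_config(fixed_omega = omega))
  st$mu <- c(0, eta); st$Sigma <- matrix(0, 2, 2)
  st <- update_lambda(st, prob)
  expect_equal(st$lam_shape[1], y + omega)
  expect_equal(st$lam_rate[1], 1 + omega * exp(-eta))
  # with large omega the rate posterior shrinks toward the model mean
  post_mean <- (y + omega) / (1 + omega * exp(-eta))
  expect_lt(abs(post_mean - 6), abs(y - 6))
})

test_that("expected inverse-link matches the log-normal identity and Monte Carlo", {
  prob <- regression_problem(c(1, 2, 3), cbind(x = c(1, -1, 0.5), 1))
  st <- make_state(prob, vb_config())
  st$mu <- c(0, 0); st$Sigma <- matrix(0, 2, 2)
  expect_equal(as.numeric(neg_linear_predictor_expectation(st, prob)),
               rep(1, 3))
  # scalar case: X = 1, mu = 1, Sigma = 2 -> exp(-1 + 1) = 1
  st$mu <- c(1, 0); st$Sigma <- diag(c(2, 0))
  expect_equal(as.numeric(neg_linear_predictor_expectation(st, prob))[3],
               exp(-0.5 + 0.5^2 * 2 / 2))
  # arbitrary small case vs Monte Carlo over Gaussian draws of beta
  st$mu <- c(0.3, -0.2)
  st$Sigma <- matrix(c(0.5, 0.1, 0.1, 0.3), 2)
  got <- as.numeric(neg_linear_predictor_expectation(st, prob))
  bs <- withr::with_seed(31, MASS::mvrnorm(1e6, st$mu, st$Sigma))
  for (t in 1:3) {
    draws <- exp(-drop(bs %*% prob$X[t, ]))
    se <- sd(draws) / sqrt(1e6)
    expect_lt(abs(got[t] - mean(draws)), 3 * se)
  }
})

test_that("coefficient update shrinks fully under an infinite-precision prior", {
  prob <- sim_problem(n = 40, w = 3, seed = 3)
  st <- make_state(prob, vb_config(fixed_omega = 2, fixed_zeta2 = 1e-12))
  st <- update_lambda(st, prob)
  st <- update_beta(st, prob, damp = FALSE)
  expect_lt(max(abs(st$mu[1:3])), 1e-6)
})

test_that("coefficient update is a fixed point at its own solution", {
  prob <- toy_problem(n = 12, seed = 6)
  cfg <- vb_config(fixed_omega = 2, fixed_zeta2 = 1, tol = 1e-12,
                   max_iter = 400)
  fit <- fit_nb_horseshoe(prob, cfg)
  st <- fit$state
  st2 <- update_beta(update_lambda(st, prob), prob, damp = FALSE)
  expect_lt(max(abs(st2$mu - st$mu)), 1e-4)
  expect_lt(max(abs(st2$Sigma - st$Sigma)), 1e-4)
})

test_that("converged coefficient mean matches a dense-grid posterior oracle", {
  for (seed in c(1, 2)) {
    prob <- toy_problem(n = 12, omega = 2, slope = 0.7, seed = seed)
    cfg <- vb_config(fixed_omega = 2, fixed_zeta2 = 1)
    fit <- fit_nb_horseshoe(prob, cfg)
    oracle <- oracle_grid_posterior(prob, omega = 2, zeta2 = 1, config = cfg)
    expect_lt(abs(fit$state$mu[1] - oracle$slope_mean), 0.05)
  }
})

test_that("dispersion weights normalize, track the truth, and fall back to the prior", {
  prob <- sim_problem(n = 500, w = 1, active = 1, beta_active = 0.5,
                      omega = 2, seed = 11)
  st <- make_state(prob, vb_config())
  st$mu <- c(0.5, log(30)); st$Sigma <- diag(1e-10, 2)
  for (i in 1:30) {
    st <- update_lambda(st, prob)
    st <- update_omega(st, prob)
  }
  expect_equal(sum(st$omega_w), 1)
  e_om <- sum(st$omega_w * st$omega_grid)
  expect_gt(e_om, 1.5)
  expect_lt(e_om, 2.7)

  # data-free limit: q(omega) proportional to the prior on the grid
  empty <- list(y = numeric(0), X = matrix(0, 0, 2), offset = numeric(0))
  st0 <- make_state(sim_problem(n = 10, w = 1), vb_config())
  st0 <- update_omega(st0, empty)
  prior <- dgamma(st0$omega_grid, 0.01, rate = 0.01)
  expect_equal(st0$omega_w, prior / sum(prior), tolerance = 1e-12)
})

test_that("horseshoe updates follow their closed forms", {
  prob <- sim_problem(n = 20, w = 3, seed = 13)
  st <- make_state(prob, vb_config())
  # E[beta_w^2] = 1, E[1/a_w] = 0.5 -> q(zeta2_w) = InvGamma(1, 1)
  st$mu <- c(sqrt(0.5), sqrt(0.5), sqrt(0.5), 0)
  st$Sigma <- diag(c(0.5, 0.5, 0.5, 0))
  st$a_shape <- 1; st$a_scale <- rep(2, 3)      # E[1/a] = 1/2
  st$tau2_scale <- 1e12                         # E[1/tau2] ~ 0
  st <- update_horseshoe(st)
  expect_equal(st$zeta2_shape, 1)
  expect_equal(st$zeta2_scale, rep(1, 3))
  expect_equal(1 / st$zeta2_scale, rep(1, 3))   # E[1/zeta2]
  # q(tau2) shape is (1 + W)/2 regardless of data
  expect_equal(st$tau2_shape, 2)
})

test_that("shrinkage scales separate active from null coefficients", {
  wins <- vapply(1:20, function(seed) {
    prob <- sim_problem(n = 30, w = 2, active = 1, beta_active = 1,
                        omega = 5, seed = seed)
    fit <- fit_nb_horseshoe(prob, vb_config(max_iter = 100))
    inv_z <- fit$state$zeta2_shape / fit$state$zeta2_scale
    inv_z[1] < inv_z[2]  # active coefficient gets the larger scale
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})
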