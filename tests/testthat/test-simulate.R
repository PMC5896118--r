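test_that("sampled structures are sparse with capped edge counts", {
  adj <- sample_structure(25, seed = 1)
  expect_lt(sum(adj), 0.1 * 25 * 24)
  expect_equal(sum(adj), round(1.5 * 25))
  expect_true(all(diag(adj) == 0))

  adj2 <- sample_structure(2, seed = 1)
  expect_lte(sum(adj2), 2)

  expect_error(sample_structure(5, density = 1), "below 1")
  expect_error(sample_structure(1), "at least 2")
})

test_that("a reference network of exactly the requested size is returned as-is", {
  adj <- sample_structure(25, seed = 3)
  ref <- tibble::tibble(
    parent = rownames(adj)[which(adj == 1, arr.ind = TRUE)[, 1]],
    child = colnames(adj)[which(adj == 1, arr.ind = TRUE)[, 2]])
  got <- sample_structure(25, reference = ref, seed = 3)
  expect_setequal(rownames(got), rownames(adj))
  got <- got[rownames(adj), rownames(adj)]
  expect_equal(unname(got), unname(adj))
})

test_that("coefficient draws follow the two-component mixture", {
  adj <- matrix(1L, 105, 105); diag(adj) <- 0L
  spec <- sample_parameters(adj, beta_mean = 0.3, beta_sd = 0.1, seed = 5)
  b <- spec$beta[adj == 1L]
  expect_gte(length(b), 1e4)
  expect_equal(mean(abs(b)), 0.3, tolerance = 0.01)
  expect_equal(mean(b > 0), 0.5, tolerance = 3 * 0.5 / sqrt(length(b)))
  # zero-edge adjacency gives an all-zero coefficient matrix
  spec0 <- sample_parameters(matrix(0L, 4, 4), seed = 5)
  expect_true(all(spec0$beta == 0))
})

test_that("simulated counts have the right shape and are seed-reproducible", {
  adj <- sample_structure(25, seed = 7)
  spec <- sample_parameters(adj, timepoints = 20, replicates = 3, seed = 7)
  d <- simulate_counts(spec)
  expect_equal(dim(d), c(25, 60))
  expect_true(all(d$counts >= 0))
  expect_true(all(d$counts == floor(d$counts)))
  d2 <- simulate_counts(spec)
  expect_identical(d$counts, d2$counts)
})

test_that("without edges, counts fluctuate around the baseline mean", {
  adj <- matrix(0L, 5, 5,
                dimnames = list(sprintf("g%02d", 1:5), sprintf("g%02d", 1:5)))
  tab <- tibble::tibble(mean = c(20, 50, 100, 200, 400), dispersion = 5)
  spec <- sample_parameters(adj, mean_dispersion = tab,
                            timepoints = 20, replicates = 3, seed = 9)
  d <- simulate_counts(spec)
  for (g in rownames(adj)) {
    m <- spec$baseline_mean[g]
    v <- m + m^2 / spec$dispersion[g]
    se <- sqrt(v / 60)
    expect_lt(abs(mean(d$counts[g, ]) - m), 4 * se)
  }
})

test_that("huge dispersions give Poisson-like counts", {
  adj <- matrix(0L, 3, 3)
  tab <- tibble::tibble(mean = c(30, 80, 150), dispersion = 1e6)
  spec <- sample_parameters(adj, mean_dispersion = tab, timepoints = 40,
                            replicates = 5, seed = 11)
  d <- simulate_counts(spec)
  for (g in rownames(spec$adjacency)) {
    ratio <- var(d$counts[g, ]) / mean(d$counts[g, ])
    expect_gt(ratio, 0.6)
    expect_lt(ratio, 1.6)
  }
})

test_that("structure, parameter and count draws are independent streams", {
  adj <- sample_structure(6, seed = 13)
  s1 <- sample_parameters(adj, seed = 1)
  s2 <- sample_parameters(adj, seed = 2)
  # same structure regardless of the parameter seed
  expect_identical(s1$adjacency, s2$adjacency)
  expect_false(identical(s1$beta, s2$beta))
  # counts depend on their own seed, not only the spec seed
  d1 <- simulate_counts(s1, seed = 100)
  d2 <- simulate_counts(s1, seed = 101)
  expect_false(identical(d1$counts, d2$counts))
})

test_that("a spec round-trips through its plain-text serialization", {
  adj <- sample_structure(5, seed = 17)
  spec <- sample_parameters(adj, seed = 17)
  p <- tempfile(fileext = ".json")
  write_simulation_spec(spec, p)
  back <- read_simulation_spec(p)
  expect_equal(back$beta, spec$beta)
  expect_equal(back$adjacency, spec$adjacency)
  expect_equal(back$baseline_mean, spec$baseline_mean)
  expect_equal(back$timepoints, spec$timepoints)
})

test_that("the packaged mean/dispersion table matches its generator", {
  packaged <- read_mean_dispersion()
  fresh <- synthetic_mean_dispersion()
  expect_equal(nrow(packaged), 200)
  expect_equal(packaged$mean, fresh$mean, tolerance = 1e-8)
  expect_equal(packaged$dispersion, fresh$dispersion, tolerance = 1e-8)
  expect_true(all(packaged$dispersion >= 0.05 & packaged$dispersion <= 5))
})

test_that("identifiable end-to-end: strong edges are ranked above prevalence", {
  aucs <- prevs <- numeric(3)
  for (k in 1:3) {
    adj <- sample_structure(10, seed = 20 + k)
    spec <- sample_parameters(adj, beta_mean = 0.8, seed = 20 + k)
    d <- simulate_counts(spec)
    net <- suppressWarnings(infer_network(d, vb_config(max_iter = 150)))
    rep <- benchmark_network(spec, net)
    aucs[k] <- rep$auc_pr
    prevs[k] <- rep$prevalence
  }
  expect_gt(median(aucs), 3 * median(prevs))
})
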