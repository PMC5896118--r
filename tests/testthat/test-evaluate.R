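test_that("MCC matches hand computation and conventions", {
  expect_equal(mcc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  # TP=1, TN=2, FP=1, FN=1 -> 1/6
  expect_equal(mcc(c(1, 1, 0, 0, 0), c(1, 0, 1, 0, 0)), 1 / 6)
  expect_warning(m <- mcc(c(1, 0, 1), c(1, 1, 1)), "degenerate")
  expect_equal(m, 0)
  expect_error(mcc(c(1, 0), c(1)), "equal length")
})

test_that("MCC is symmetric under simultaneous class and call swap", {
  withr::with_seed(41, {
    for (i in 1:10) {
      tr <- rbinom(30, 1, 0.4)
      cl <- rbinom(30, 1, 0.5)
      expect_equal(suppressWarnings(mcc(tr, cl)),
                   suppressWarnings(mcc(1 - tr, 1 - cl)))
    }
  })
})

test_that("AUC-PR: perfect ranking, worked example, permutation null", {
  expect_equal(auc_pr(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1)), 1)
  ex <- auc_pr(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.1))
  expect_equal(ex, oracle_auc_pr(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.1)),
               tolerance = 1e-5)
  withr::with_seed(43, {
    tr <- rbinom(1e4, 1, 0.1)
    sc <- runif(1e4)
  })
  a <- auc_pr(tr, sc)
  expect_gt(a, 0.07); expect_lt(a, 0.14)
  expect_error(auc_pr(c(0, 0), c(0.1, 0.2)), "positive")
})

test_that("partial AUC-ROC: perfect, chance, brute-force equality", {
  expect_equal(partial_auc_roc(c(1, 1, 0, 0), c(4, 3, 2, 1), 0.95), 1)
  withr::with_seed(47, {
    tr <- rbinom(2e4, 1, 0.3)
    sc <- runif(2e4)
  })
  expect_equal(partial_auc_roc(tr, sc, 0.95), 0.5, tolerance = 0.06)
  withr::with_seed(49, {
    tr <- rbinom(30, 1, 0.4)
    sc <- tr * 0.3 + runif(30)  # informative, above the diagonal
  })
  expect_equal(partial_auc_roc(tr, sc, 0.95), oracle_pauc(tr, sc, 0.95),
               tolerance = 1e-12)
  expect_error(partial_auc_roc(c(1, 1), c(1, 2)), "both classes")
  expect_error(partial_auc_roc(c(1, 0), c(1, 2), cutoff = 1), "in \\(0, 1\\)")
})

test_that("partial AUC-ROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(53, {
    tr <- rbinom(200, 1, 0.3)
    sc <- tr + rnorm(200)
  })
  ours <- partial_auc_roc(tr, sc, 0.95)
  ref <- pROC::auc(pROC::roc(tr, sc, direction = "<", quiet = TRUE),
                   partial.auc = c(0.95, 1),
                   partial.auc.focus = "specificity",
                   partial.auc.correct = TRUE)
  expect_equal(ours, as.numeric(ref), tolerance = 1e-8)
})

test_that("curve metrics are invariant under strictly monotone score transforms", {
  withr::with_seed(59, {
    tr <- rbinom(50, 1, 0.3)
    sc <- rnorm(50)
  })
  for (f in list(function(s) 2 * s + 3, function(s) exp(s),
                 function(s) atan(s))) {
    expect_equal(auc_pr(tr, f(sc)), auc_pr(tr, sc))
    expect_equal(partial_auc_roc(tr, f(sc), 0.9),
                 partial_auc_roc(tr, sc, 0.9))
  }
})

test_that("all metrics agree with brute-force oracles on small instances", {
  withr::with_seed(61, {
    for (rep in 1:40) {
      n <- sample(4:12, 1)
      tr <- rbinom(n, 1, 0.4)
      if (sum(tr) == 0) tr[sample(n, 1)] <- 1
      if (sum(tr) == n) tr[sample(n, 1)] <- 0
      sc <- round(runif(n), 2)  # rounded to provoke ties
      cl <- rbinom(n, 1, 0.5)
      expect_equal(suppressWarnings(mcc(tr, cl)), oracle_mcc(tr, cl))
      expect_equal(auc_pr(tr, sc), oracle_auc_pr(tr, sc), tolerance = 1e-5)
      expect_equal(partial_auc_roc(tr, sc, 0.95), oracle_pauc(tr, sc, 0.95),
                   tolerance = 1e-12)
      expect_equal(partial_auc_roc(tr, sc, 0.8), oracle_pauc(tr, sc, 0.8),
                   tolerance = 1e-12)
    }
  })
})

test_that("benchmark_network scores direction and handles degenerate calls", {
  adj <- sample_structure(6, seed = 67)
  spec <- sample_parameters(adj, seed = 67)
  truth <- tidy(spec)
  nodes <- rownames(adj)
  pairs <- tidyr::expand_grid(parent = nodes, child = nodes) |>
    dplyr::filter(parent != child)
  key <- paste(pairs$parent, pairs$child)
  tkey <- paste(truth$parent, truth$child)

  # inferred == truth -> all three metrics are 1
  perfect <- pairs
  perfect$score <- as.numeric(key %in% tkey)
  perfect$selected <- key %in% tkey
  rep1 <- benchmark_network(adj, perfect, nodes = nodes)
  expect_equal(rep1$mcc, 1)
  expect_equal(rep1$auc_pr, 1)
  expect_equal(rep1$pauc_roc, 1)

  # reversing every edge of an acyclic truth with no reciprocal edges
  recip <- any(tkey %in% paste(truth$child, truth$parent))
  rev <- pairs
  rkey <- paste(truth$child, truth$parent)
  rev$score <- as.numeric(key %in% rkey)
  rev$selected <- key %in% rkey
  rep2 <- benchmark_network(adj, rev, nodes = nodes)
  if (!recip) expect_lte(rep2$mcc, 0)

  # empty inferred edge set: MCC 0 with warning, curves still computed
  none <- pairs
  none$score <- 0
  none$selected <- FALSE
  expect_warning(rep3 <- benchmark_network(adj, none, nodes = nodes),
                 "degenerate")
  expect_equal(rep3$mcc, 0)
  expect_true(is.finite(rep3$auc_pr))

  # node-set mismatch names the difference
  expect_error(benchmark_network(adj, perfect, nodes = c(nodes[-1], "gX")),
               "gX")
})

test_that("curve plots build", {
  withr::with_seed(71, {
    tr <- rbinom(40, 1, 0.3)
    sc <- tr + rnorm(40)
  })
  expect_s3_class(plot_pr_curve(tr, sc), "ggplot")
  expect_s3_class(plot_roc_curve(tr, sc), "ggplot")
})
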