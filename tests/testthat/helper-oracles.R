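# Independent oracles used across the suite. These re-derive expected
# values by brute force (threshold enumeration, dense-grid integration,
# Monte Carlo) and deliberately share no code with the package internals
# they check.

# --- metric oracles -------------------------------------------------------

oracle_confusion <- function(truth, call) {
  c(tp = sum(truth == 1 & call == 1), tn = sum(truth == 0 & call == 0),
    fp = sum(truth == 0 & call == 1), fn = sum(truth == 1 & call == 0))
}

oracle_mcc <- function(truth, call) {
  k <- oracle_confusion(truth, call)
  den <- prod(c(k["tp"] + k["fp"], k["tp"] + k["fn"],
                k["tn"] + k["fp"], k["tn"] + k["fn"]))
  if (den == 0) return(0)
  unname((k["tp"] * k["tn"] - k["fp"] * k["fn"]) / sqrt(den))
}

# ROC/PR points by explicit threshold sweep (one threshold per distinct
# score, predicted positive = score >= threshold).
oracle_curve_points <- function(truth, score) {
  thr <- sort(unique(score), decreasing = TRUE)
  pts <- t(vapply(thr, function(h) {
    call <- score >= h
    c(tp = sum(truth == 1 & call), fp = sum(truth == 0 & call))
  }, c(tp = 0, fp = 0)))
  rbind(c(tp = 0, fp = 0), pts)
}

# AUC-PR by fine-grained numerical integration of precision over the
# true-positive count, with the false-positive count interpolated linearly
# between threshold points (the continuous-interpolation convention).
oracle_auc_pr <- function(truth, score, steps = 1e5) {
  pts <- oracle_curve_points(truth, score)
  p_tot <- sum(truth == 1)
  area <- 0
  for (k in seq_len(nrow(pts) - 1)) {
    dtp <- pts[k + 1, "tp"] - pts[k, "tp"]
    if (dtp == 0) next
    tt <- seq(pts[k, "tp"], pts[k + 1, "tp"], length.out = steps + 1)
    ff <- pts[k, "fp"] + (pts[k + 1, "fp"] - pts[k, "fp"]) *
      (tt - pts[k, "tp"]) / dtp
    prec <- ifelse(tt + ff == 0, 1, tt / (tt + ff))
    mid <- (prec[-1] + prec[-length(prec)]) / 2
    area <- area + sum(mid * diff(tt))
  }
  area / p_tot
}

# Partial AUC-ROC by trapezoid integration of the restricted ROC with
# linear boundary interpolation, then McClish standardization.
oracle_pauc <- function(truth, score, cutoff = 0.95) {
  pts <- oracle_curve_points(truth, score)
  fpr <- pts[, "fp"] / sum(truth == 0)
  tpr <- pts[, "tp"] / sum(truth == 1)
  fmax <- 1 - cutoff
  area <- 0
  for (k in seq_len(length(fpr) - 1)) {
    if (fpr[k] >= fmax) break
    x1 <- min(fpr[k + 1], fmax)
    y1 <- if (fpr[k + 1] > fmax)
      tpr[k] + (tpr[k + 1] - tpr[k]) * (fmax - fpr[k]) / (fpr[k + 1] - fpr[k])
    else tpr[k + 1]
    area <- area + (x1 - fpr[k]) * (tpr[k] + y1) / 2
  }
  0.5 * (1 + (area - fmax^2 / 2) / (fmax - fmax^2 / 2))
}

# Directed betweenness by all-pairs shortest-path enumeration.
oracle_betweenness <- function(edges, nodes) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) adj[cbind(match(edges$parent, nodes), match(edges$child, nodes))] <- TRUE
  # enumerate all simple paths s -> t, keep shortest
  paths_from <- function(s, t) {
    out <- list()
    walk <- function(path) {
      cur <- path[length(path)]
      if (cur == t && length(path) > 1) { out[[length(out) + 1]] <<- path; return() }
      for (nx in nodes[adj[cur, ]]) if (!nx %in% path) walk(c(path, nx))
    }
    walk(s)
    out
  }
  b <- setNames(numeric(n), nodes)
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    ps <- paths_from(s, t)
    if (!length(ps)) next
    lens <- vapply(ps, length, 1L)
    sp <- ps[lens == min(lens)]
    for (v in nodes) {
      if (v == s || v == t) next
      thru <- sum(vapply(sp, function(p) v %in% p, TRUE))
      b[v] <- b[v] + thru / length(sp)
    }
  }
  b / ((n - 1) * (n - 2))
}

# --- posterior / evidence oracles ----------------------------------------

# Dense 2-D grid over (slope, intercept) for a W = 1 problem with fixed
# dispersion and fixed slope prior variance. Returns the log evidence and
# the posterior mean of the slope.
oracle_grid_posterior <- function(problem, omega, zeta2, config,
                                  slope_lim = c(-4, 4), icpt_center = NULL,
                                  n_grid = 301) {
  if (is.null(icpt_center)) icpt_center <- log(mean(problem$y) + 0.5)
  bg <- seq(slope_lim[1], slope_lim[2], length.out = n_grid)
  cg <- seq(icpt_center - 3, icpt_center + 3, length.out = n_grid)
  lp <- outer(bg, cg, Vectorize(function(b, bc) {
    eta <- drop(problem$X %*% c(b, bc)) + problem$offset
    sum(dnbinom(problem$y, size = omega, mu = exp(eta), log = TRUE)) +
      dnorm(b, 0, sqrt(zeta2), log = TRUE) +
      dnorm(bc, 0, sqrt(config$intercept_var), log = TRUE)
  }))
  m <- max(lp)
  w <- exp(lp - m)
  list(log_evidence = m + log(sum(w) * diff(bg)[1] * diff(cg)[1]),
       slope_mean = sum(bg * rowSums(w)) / sum(w))
}

# --- small data builders --------------------------------------------------

toy_problem <- function(n = 12, omega = 2, slope = 0.7, icpt = log(20),
                        seed = 1) {
  withr::with_seed(seed, {
    x <- as.numeric(scale(log1p(rnbinom(n, size = 1, mu = 50))))
    y <- rnbinom(n, size = omega, mu = exp(icpt + slope * x))
    regression_problem(y, cbind(x = x, 1))
  })
}

sim_problem <- function(n = 57, w = 5, active = 1, beta_active = 0.8,
                        omega = 2, icpt = log(30), seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * w), n, w)
    X <- scale(X)
    beta <- rep(0, w); beta[seq_len(active)] <- beta_active
    y <- rnbinom(n, size = omega, mu = exp(icpt + drop(X %*% beta)))
    regression_problem(y, cbind(X, 1),
                       predictors = paste0("x", seq_len(w)))
  })
}

small_count_ts <- function(m = 2, l = 4, r = 1, seed = 1) {
  withr::with_seed(seed, {
    genes <- sprintf("g%02d", seq_len(m))
    samples <- tidyr::expand_grid(time = seq_len(l), replicate = seq_len(r))
    samples$sample <- sprintf("t%02d_r%d", samples$time, samples$replicate)
    counts <- matrix(rnbinom(m * nrow(samples), size = 2, mu = 50),
                     m, nrow(samples),
                     dimnames = list(genes, samples$sample))
    count_ts(counts, samples[, c("sample", "time", "replicate")],
             size_factor_method = "total")
  })
}
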