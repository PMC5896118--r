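#' Sample a directed regulatory network structure
#'
#' Surrogate generator for benchmark structures: edges are added one at a
#' time with the child drawn uniformly and the parent drawn with probability
#' proportional to its current out-degree plus one (preferential attachment
#' on regulators), giving a heavy-tailed out-degree with a few hub
#' regulators and sparse in-degrees, as in curated microbial regulatory
#' networks. Alternatively, a user-supplied reference edge list can be
#' subsampled by neighbourhood (module) extraction.
#'
#' @param n_nodes Number of genes (at least 2).
#' @param mean_in_degree Target mean number of parents per gene; the edge
#'   count is `round(mean_in_degree * n_nodes)`, capped at `n(n-1)`.
#' @param density Optional explicit edge density of ordered pairs,
#'   overriding `mean_in_degree`; must be below 1.
#' @param reference Optional reference network: a two-column edge data
#'   frame (`parent`, `child`) to subsample a connected module of
#'   `n_nodes` genes from, instead of generating a structure.
#' @param seed Integer seed.
#' @return A square 0/1 adjacency matrix with gene dimnames;
#'   `adj[i, j] = 1` means i regulates j.
#' @export
sample_structure <- function(n_nodes, mean_in_degree = 1.5, density = NULL,
                             reference = NULL, seed = 1L) {
  if (n_nodes < 2) abort("`n_nodes` must be at least 2.")
  if (!is.null(reference)) {
    return(subsample_reference(reference, n_nodes, seed))
  }
  max_edges <- n_nodes * (n_nodes - 1)
  if (!is.null(density)) {
    if (density >= 1) {
      abort("`density` implies at least n(n-1) edges; choose a value below 1.")
    }
    n_edges <- round(density * max_edges)
  } else {
    n_edges <- min(round(mean_in_degree * n_nodes), max_edges)
  }
  genes <- sprintf("g%02d", seq_len(n_nodes))
  adj <- matrix(0L, n_nodes, n_nodes, dimnames = list(genes, genes))
  with_seed(seed, {
    placed <- 0
    attempts <- 0
    while (placed < n_edges && attempts < 100 * n_edges) {
      attempts <- attempts + 1
      child <- sample.int(n_nodes, 1)
      parent <- sample.int(n_nodes, 1, prob = rowSums(adj) + 1)
      if (parent == child || adj[parent, child] == 1L) next
      adj[parent, child] <- 1L
      placed <- placed + 1
    }
  })
  adj
}

subsample_reference <- function(reference, n_nodes, seed) {
  reference <- as_tibble(reference)
  names(reference)[1:2] <- c("parent", "child")
  nodes <- unique(c(reference$parent, reference$child))
  if (length(nodes) < n_nodes) {
    abort("reference network has fewer nodes than requested.")
  }
  keep <- if (length(nodes) == n_nodes) nodes else with_seed(seed, {
    # grow a module outwards from a random seed gene
    g <- igraph::graph_from_data_frame(reference, directed = TRUE,
                                       vertices = nodes)
    start <- sample(nodes, 1)
    ord <- igraph::bfs(igraph::as_undirected(g), root = start,
                       unreachable = TRUE)$order
    igraph::V(g)$name[ord][seq_len(n_nodes)]
  })
  sub <- filter(reference, .data$parent %in% keep, .data$child %in% keep)
  adj <- matrix(0L, n_nodes, n_nodes, dimnames = list(keep, keep))
  adj[cbind(match(sub$parent, keep), match(sub$child, keep))] <- 1L
  adj
}

#' Synthetic per-gene mean/dispersion table
#'
#' Generates a table of per-gene (mean, dispersion) pairs emulating the
#' empirical marginals of a bulk RNA-Seq count data set: log-normal means
#' and log-uniform dispersions in `[0.05, 5]`. A pre-generated copy ships
#' as `inst/extdata/synthetic_mean_dispersion.tsv`; this function is the
#' code that produced it.
#'
#' @param n_genes Number of rows.
#' @param meanlog,sdlog Log-normal parameters of the mean distribution.
#' @param dispersion_range Range of the log-uniform dispersion draw.
#' @param seed Integer seed.
#' @return A tibble with columns `mean`, `dispersion`.
#' @export
synthetic_mean_dispersion <- function(n_genes = 200,
                                      meanlog = log(100), sdlog = 1.3,
                                      dispersion_range = c(0.05, 5),
                                      seed = 20180411L) {
  with_seed(seed, tibble(
    mean = rlnorm(n_genes, meanlog, sdlog),
    dispersion = exp(runif(n_genes, log(dispersion_range[1]),
                           log(dispersion_range[2])))
  ))
}

#' Read a per-gene mean/dispersion table
#'
#' @param path TSV with columns `mean` and `dispersion`; defaults to the
#'   packaged synthetic table.
#' @return A tibble with columns `mean`, `dispersion`.
#' @export
read_mean_dispersion <- function(path = system.file("extdata",
                                                    "synthetic_mean_dispersion.tsv",
                                                    package = "nbdbn")) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("mean", "dispersion") %in% names(tb)) || nrow(tb) == 0) {
    abort("mean/dispersion table must be non-empty with columns `mean`, `dispersion`.")
  }
  if (any(tb$mean <= 0) || any(tb$dispersion <= 0)) {
    abort("means and dispersions must be strictly positive.")
  }
  tb
}

#' Draw simulation parameters for a benchmark network
#'
#' Nonzero coefficients sit exactly on the true edges and are drawn from an
#' equally weighted two-component normal mixture `N(beta_mean, beta_sd^2)` /
#' `N(-beta_mean, beta_sd^2)`. Per-gene baseline means and dispersions are
#' drawn with replacement from an empirical (or the packaged synthetic)
#' table, and each intercept is set to the log baseline mean so that
#' stationary counts track the drawn mean.
#'
#' @param adjacency 0/1 adjacency matrix from [sample_structure()].
#' @param mean_dispersion Table of per-gene `(mean, dispersion)` pairs;
#'   defaults to the packaged synthetic table.
#' @param beta_mean,beta_sd Mixture component magnitude and standard
#'   deviation (defaults 0.3 and 0.1).
#' @param timepoints Number of time points L (at least 2; default 20).
#' @param replicates Number of replicates R (default 3).
#' @param size_factor_model `"unit"` (all 1) or `"lognormal"`
#'   (`log s ~ N(0, 0.2^2)`) per sample.
#' @param seed Integer seed.
#' @return An object of class `simulation_spec`.
#' @export
sample_parameters <- function(adjacency,
                              mean_dispersion = NULL,
                              beta_mean = 0.3, beta_sd = 0.1,
                              timepoints = 20L, replicates = 3L,
                              size_factor_model = c("unit", "lognormal"),
                              seed = 1L) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency),
            timepoints >= 2, replicates >= 1)
  size_factor_model <- match.arg(size_factor_model)
  if (is.null(mean_dispersion)) mean_dispersion <- read_mean_dispersion()
  mean_dispersion <- as_tibble(mean_dispersion)
  if (nrow(mean_dispersion) == 0) abort("empty mean/dispersion table.")
  M <- nrow(adjacency)
  genes <- rownames(adjacency) %||% sprintf("g%02d", seq_len(M))
  dimnames(adjacency) <- list(genes, genes)
  n_samples <- timepoints * replicates
  with_seed(seed, {
    beta <- matrix(0, M, M, dimnames = list(genes, genes))
    n_edges <- sum(adjacency == 1L)
    if (n_edges > 0) {
      sign <- sample(c(-1, 1), n_edges, replace = TRUE)
      beta[adjacency == 1L] <- sign * beta_mean + rnorm(n_edges, 0, beta_sd)
    }
    rows <- sample.int(nrow(mean_dispersion), M, replace = TRUE)
    baseline_mean <- mean_dispersion$mean[rows]
    dispersion <- mean_dispersion$dispersion[rows]
    sf <- if (size_factor_model == "unit") rep(1, n_samples) else
      exp(rnorm(n_samples, 0, 0.2))
    structure(list(
      adjacency = adjacency, beta = beta,
      intercept = log(baseline_mean),
      baseline_mean = setNames(baseline_mean, genes),
      dispersion = setNames(dispersion, genes),
      timepoints = as.integer(timepoints),
      replicates = as.integer(replicates),
      size_factors = sf,
      beta_mixture = c(mean = beta_mean, sd = beta_sd),
      seed = as.integer(seed)
    ), class = "simulation_spec")
  })
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("<simulation_spec> %d genes, %d edges, L = %d, R = %d\n",
              nrow(x$adjacency), sum(x$adjacency), x$timepoints, x$replicates))
  invisible(x)
}

#' Serialize / restore a simulation spec
#'
#' Plain-text (JSON) provenance record of every parameter draw.
#'
#' @param spec A `simulation_spec`.
#' @param path File path.
#' @return `write_simulation_spec()` returns `path` invisibly;
#'   `read_simulation_spec()` returns the spec.
#' @export
write_simulation_spec <- function(spec, path) {
  out <- unclass(spec)
  out$genes <- rownames(spec$adjacency)
  out$adjacency <- as.data.frame(out$adjacency)
  out$beta <- as.data.frame(out$beta)
  jsonlite::write_json(out, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_simulation_spec
#' @export
read_simulation_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  genes <- x$genes
  x$genes <- NULL
  x$adjacency <- as.matrix(x$adjacency)
  x$beta <- as.matrix(x$beta)
  dimnames(x$adjacency) <- dimnames(x$beta) <- list(genes, genes)
  x$baseline_mean <- setNames(as.numeric(x$baseline_mean), genes)
  x$dispersion <- setNames(as.numeric(x$dispersion), genes)
  x$beta_mixture <- unlist(x$beta_mixture)
  structure(x, class = "simulation_spec")
}

#' Simulate an RNA-Seq count time series from the network model
#'
#' For each replicate the first time point is drawn from every gene's
#' baseline NB2; each later time point t draws gene i from
#' `NB2(s_t * exp(intercept_i + sum_p beta[p, i] * u_p), omega_i)` where
#' `u_p = log(1 + count_p / s) - log(1 + baseline_p)` is the parent's
#' depth-normalized log count at t-1, centred at its baseline — the same
#' log-scale predictor convention used when fitting. An error names the
#' gene and time point if a linear predictor exceeds the clip bound.
#'
#' @param spec A [sample_parameters()] result.
#' @param seed Integer seed (defaults to the spec's seed, offset so the
#'   structure, parameter and count draws are independent streams).
#' @param clip Abort if any |linear predictor| exceeds this bound.
#' @return A [count_ts()]; samples are named `t<time>_r<replicate>` and
#'   size factors are taken from the spec (not re-estimated).
#' @export
simulate_counts <- function(spec, seed = spec$seed + 1000L, clip = 50) {
  stopifnot(inherits(spec, "simulation_spec"))
  M <- nrow(spec$adjacency)
  L <- spec$timepoints
  R <- spec$replicates
  genes <- rownames(spec$adjacency)
  samples <- tidyr::expand_grid(replicate = seq_len(R), time = seq_len(L)) |>
    mutate(sample = sprintf("t%02d_r%d", .data$time, .data$replicate)) |>
    select("sample", "time", "replicate") |>
    arrange(.data$time, .data$replicate)
  sf <- setNames(spec$size_factors[seq_len(L * R)], samples$sample)
  counts <- matrix(0L, M, nrow(samples), dimnames = list(genes, samples$sample))
  with_seed(seed, {
    for (r in seq_len(R)) {
      prev <- NULL
      for (t in seq_len(L)) {
        smp <- sprintf("t%02d_r%d", t, r)
        s_t <- sf[smp]
        if (t == 1) {
          y <- rnb2(M, mu = s_t * spec$baseline_mean, omega = spec$dispersion)
        } else {
          s_prev <- sf[sprintf("t%02d_r%d", t - 1, r)]
          u <- log1p(prev / s_prev) - log1p(spec$baseline_mean)
          eta <- spec$intercept + drop(crossprod(spec$beta, u))
          if (any(abs(eta) > clip)) {
            g_bad <- genes[which.max(abs(eta))]
            abort(sprintf(paste0("linear predictor exploded for gene '%s' at time %d ",
                                 "(|eta| > %g); reduce coefficient magnitudes or ",
                                 "use a log-scale transform."), g_bad, t, clip))
          }
          y <- rnb2(M, mu = s_t * exp(eta), omega = spec$dispersion)
        }
        counts[, smp] <- y
        prev <- y
      }
    }
  })
  count_ts(counts, samples, size_factors = sf)
}

#' True-edge tibble of a simulation spec
#'
#' @param x A `simulation_spec`.
#' @param ... Unused.
#' @return A tibble with columns `parent`, `child`, `beta`.
#' @method tidy simulation_spec
#' @export
tidy.simulation_spec <- function(x, ...) {
  idx <- which(x$adjacency == 1L, arr.ind = TRUE)
  genes <- rownames(x$adjacency)
  tibble(parent = genes[idx[, 1]], child = genes[idx[, 2]],
         beta = x$beta[idx]) |>
    arrange(.data$parent, .data$child)
}

#' Write the true network as an edge-list TSV
#'
#' @param spec A `simulation_spec`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_true_edges <- function(spec, path) {
  readr::write_tsv(tidy(spec), path)
  invisible(path)
}
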