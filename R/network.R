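#' Sign-probability edge score
#'
#' For a Gaussian coefficient posterior with mean `mu` and standard
#' deviation `sd`, returns `1 - 2 * pnorm(-|mu| / sd)`: the posterior
#' probability that the coefficient shares the sign of its mean, minus the
#' opposite tail. The score exceeds `c` exactly when zero lies outside the
#' central `c` credible interval, so the "posterior probability > 0.95" and
#' "zero outside the 95% credible interval" selection rules coincide.
#'
#' @param mu Posterior mean(s).
#' @param sd Posterior standard deviation(s), strictly positive.
#' @return Scores in `[0, 1)`.
#' @examples
#' edge_score(1.959964, 1)  # ~0.95
#' @export
edge_score <- function(mu, sd) {
  if (any(sd <= 0)) abort("`sd` must be strictly positive.")
  1 - 2 * pnorm(-abs(mu) / sd)
}

#' Infer a directed gene regulatory network
#'
#' Fits one sparse negative-binomial regression per gene: the gene's counts
#' at times 2..L are regressed on every other gene's (transformed) value at
#' the preceding time point, with a horseshoe prior on the coefficients.
#' Each ordered pair (parent -> child) receives the posterior mean and sd
#' of the corresponding coefficient and a sign-probability score; edges
#' scoring above `cutoff` are selected. Fits are independent across genes,
#' so the result does not depend on processing order.
#'
#' @param data A [count_ts()].
#' @param config A [vb_config()] shared by all per-gene fits.
#' @param cutoff Selection cutoff on the edge score (default 0.95).
#' @param transform Predictor transform, see [build_problem()].
#' @param self_edges Allow self-loops (off by default).
#' @return An object of class `nb_dbn` with elements `edges` (tibble:
#'   `parent`, `child`, `beta_mean`, `beta_sd`, `score`, `selected`),
#'   `fits` (per-gene glance rows), `nodes`, `cutoff`, `transform`.
#'   Per-gene non-convergence is recorded in `fits`, never fatal.
#' @export
infer_network <- function(data, config = vb_config(), cutoff = 0.95,
                          transform = c("log-std", "log", "raw"),
                          self_edges = FALSE) {
  stopifnot(inherits(data, "count_ts"))
  transform <- match.arg(transform)
  genes <- rownames(data$counts)
  res <- map(genes, function(g) {
    prob <- build_problem(data, g, transform = transform,
                          self_edges = self_edges)
    fit <- withCallingHandlers(
      fit_nb_horseshoe(prob, config),
      warning = function(w) invokeRestart("muffleWarning")
    )
    td <- tidy(fit)
    td <- filter(td, .data$term != "(intercept)")
    list(edges = tibble(parent = td$term, child = g,
                        beta_mean = td$estimate, beta_sd = td$std.error,
                        score = td$score),
         fit = mutate(glance(fit), gene = g, .before = 1))
  })
  edges <- bind_rows(map(res, "edges")) |>
    mutate(selected = .data$score > cutoff) |>
    arrange(.data$parent, .data$child)
  structure(list(edges = edges,
                 fits = bind_rows(map(res, "fit")),
                 nodes = genes, cutoff = cutoff, transform = transform),
            class = "nb_dbn")
}

#' @export
print.nb_dbn <- function(x, ...) {
  cat(sprintf("<nb_dbn> %d nodes, %d/%d edges selected at score > %.2f (%s transform)\n",
              length(x$nodes), sum(x$edges$selected), nrow(x$edges),
              x$cutoff, x$transform))
  if (any(!x$fits$converged)) {
    cat(sprintf("  %d gene fit(s) did not converge\n", sum(!x$fits$converged)))
  }
  invisible(x)
}

#' @describeIn infer_network Edge table of the network.
#' @param x An `nb_dbn`.
#' @param ... Unused.
#' @method tidy nb_dbn
#' @export
tidy.nb_dbn <- function(x, ...) x$edges

#' @describeIn infer_network One-row network summary.
#' @method glance nb_dbn
#' @export
glance.nb_dbn <- function(x, ...) {
  tibble(n_nodes = length(x$nodes),
         n_edges_selected = sum(x$edges$selected),
         n_possible = nrow(x$edges),
         n_converged = sum(x$fits$converged),
         cutoff = x$cutoff,
         transform = x$transform)
}

#' Re-threshold a network's selected edges
#'
#' @param network An `nb_dbn`.
#' @param cutoff New score cutoff.
#' @return The network with `selected` flags (and `cutoff`) updated.
#' @export
select_edges <- function(network, cutoff) {
  stopifnot(inherits(network, "nb_dbn"))
  network$edges$selected <- network$edges$score > cutoff
  network$cutoff <- cutoff
  network
}

as_igraph <- function(network) {
  sel <- filter(network$edges, .data$selected)
  igraph::graph_from_data_frame(sel[, c("parent", "child")],
                                directed = TRUE,
                                vertices = network$nodes)
}

#' Betweenness centrality of the selected-edge digraph
#'
#' Fraction of all-pairs directed shortest paths passing through each node
#' (unit edge weights, normalized by `(n - 1)(n - 2)`). Nodes of an empty
#' graph all get zero.
#'
#' @param network An `nb_dbn`, or an edge tibble with columns
#'   `parent`, `child` (all edges taken as selected) plus a `nodes`
#'   character vector.
#' @param nodes Node set when `network` is a plain edge table.
#' @return A tibble with columns `node`, `betweenness`.
#' @export
betweenness_centrality <- function(network, nodes = NULL) {
  if (inherits(network, "nb_dbn")) {
    g <- as_igraph(network)
  } else {
    nodes <- nodes %||% unique(c(network$parent, network$child))
    g <- igraph::graph_from_data_frame(network[, c("parent", "child")],
                                       directed = TRUE, vertices = nodes)
  }
  b <- igraph::betweenness(g, directed = TRUE, normalized = TRUE)
  tibble(node = names(b), betweenness = unname(b))
}

#' Write an edge table as TSV
#'
#' @param network An `nb_dbn`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edges <- function(network, path) {
  readr::write_tsv(tidy(network), path)
  invisible(path)
}

#' Export the selected-edge digraph as GraphML
#'
#' @param network An `nb_dbn`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Edge-score heatmap of an inferred network
#'
#' Parent-by-child tiles coloured by edge score; selected edges outlined.
#'
#' @param object An `nb_dbn`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nb_dbn
#' @export
autoplot.nb_dbn <- function(object, ...) {
  ed <- mutate(object$edges,
               parent = factor(.data$parent, levels = object$nodes),
               child = factor(.data$child, levels = object$nodes))
  ggplot2::ggplot(ed, ggplot2::aes(x = .data$child, y = .data$parent,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = filter(ed, .data$selected),
                       colour = "black", linewidth = 0.6) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "child (regulated at t)", y = "parent (regulator at t-1)",
                  fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Ridge regression baseline on log counts
#'
#' A comparison method run through the same network evaluator: per gene, a
#' ridge (L2) regression of `log(1 + count / s)` at time t on the same
#' transformed predictors at time t-1, with the penalty chosen by
#' cross-validation. Edge scores are absolute coefficient magnitudes;
#' no binary calls are produced.
#'
#' @param data A [count_ts()].
#' @param transform Predictor transform, see [build_problem()].
#' @param seed Seed for the cross-validation folds.
#' @return An edge tibble (`parent`, `child`, `score`) usable by
#'   [benchmark_network()].
#' @export
ridge_baseline <- function(data, transform = c("log-std", "log", "raw"),
                           seed = 1L) {
  stopifnot(inherits(data, "count_ts"))
  transform <- match.arg(transform)
  genes <- rownames(data$counts)
  with_seed(seed, map_dfr(genes, function(g) {
    prob <- build_problem(data, g, transform = transform)
    x <- prob$X[, seq_along(prob$predictors), drop = FALSE]
    yy <- log1p(prob$y / exp(prob$offset))
    cv <- glmnet::cv.glmnet(x, yy, alpha = 0, nfolds = 5, standardize = FALSE)
    co <- as.numeric(coef(cv, s = "lambda.min"))[-1]
    tibble(parent = prob$predictors, child = g, score = abs(co))
  }))
}
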