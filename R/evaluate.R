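# Benchmark metrics for directed edge prediction. All three metrics treat
# every ordered gene pair (parent != child) as one instance; direction is
# scored, so a reversed edge is a miss plus a false positive.

# Cumulative confusion path over score thresholds (ties collapsed to a
# single threshold). Returns tp/fp counts after each distinct score.
confusion_path <- function(truth, score) {
  o <- order(score, decreasing = TRUE)
  t_s <- truth[o]
  s_s <- score[o]
  last <- !duplicated(s_s, fromLast = TRUE)
  list(tp = cumsum(t_s)[last], fp = cumsum(1 - t_s)[last],
       threshold = s_s[last])
}

check_predictions <- function(truth, score = NULL, call = NULL) {
  if (!all(truth %in% c(0, 1))) abort("`truth` must be 0/1.")
  if (!is.null(score) && length(score) != length(truth)) {
    abort("`truth` and `score` must have equal length.")
  }
  if (!is.null(call) && length(call) != length(truth)) {
    abort("`truth` and `call` must have equal length.")
  }
}

#' Matthews correlation coefficient
#'
#' MCC of binary edge calls against 0/1 truth labels. When any marginal of
#' the confusion table is zero the coefficient is undefined; by convention
#' 0 is returned with a warning.
#'
#' @param truth 0/1 truth labels.
#' @param call Logical or 0/1 predicted calls.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(truth, call) {
  check_predictions(truth, call = call)
  call <- as.numeric(call)
  tp <- sum(truth == 1 & call == 1)
  tn <- sum(truth == 0 & call == 0)
  fp <- sum(truth == 0 & call == 1)
  fn <- sum(truth == 1 & call == 0)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) {
    warn("degenerate confusion-table marginal; returning MCC = 0.")
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Area under the precision-recall curve
#'
#' AUC-PR with continuous (Davis-Goadrich) interpolation: between
#' consecutive thresholds the false-positive count is interpolated linearly
#' in the true-positive count and precision is integrated in closed form.
#' Tied scores are treated as a single threshold.
#'
#' @param truth 0/1 truth labels (at least one positive).
#' @param score Continuous scores, larger = more confident edge.
#' @return AUC-PR in `(0, 1]`.
#' @export
auc_pr <- function(truth, score) {
  check_predictions(truth, score = score)
  p_tot <- sum(truth == 1)
  if (p_tot == 0) abort("AUC-PR needs at least one positive label.")
  path <- confusion_path(truth, score)
  tp <- c(0, path$tp)
  fp <- c(0, path$fp)
  area <- 0
  for (k in seq_len(length(tp) - 1)) {
    dtp <- tp[k + 1] - tp[k]
    if (dtp == 0) next
    s <- (fp[k + 1] - fp[k]) / dtp
    alpha <- 1 + s
    gam <- fp[k] - s * tp[k]
    if (abs(gam) < 1e-12) {
      area <- area + dtp / alpha
    } else {
      anti <- function(t) t / alpha - gam / alpha^2 * log(alpha * t + gam)
      area <- area + anti(tp[k + 1]) - anti(tp[k])
    }
  }
  area / p_tot
}

#' Standardized partial area under the ROC curve
#'
#' Area under the ROC curve restricted to the high-specificity region
#' (specificity at least `cutoff`, i.e. false-positive rate at most
#' `1 - cutoff`), with the McClish correction mapping chance to 0.5 and a
#' perfect ranking to 1. Tied scores form single diagonal ROC segments and
#' the curve is interpolated linearly at the region boundary.
#'
#' @param truth 0/1 truth labels (both classes present).
#' @param score Continuous scores, larger = more confident edge.
#' @param cutoff Specificity (or sensitivity) bound in `(0, 1)`;
#'   default 0.95.
#' @param focus `"specificity"` (default) restricts FPR; `"sensitivity"`
#'   restricts TPR instead, via the class-swap reflection of the ROC.
#' @return Corrected partial AUC in `[0, 1]`.
#' @export
partial_auc_roc <- function(truth, score, cutoff = 0.95,
                            focus = c("specificity", "sensitivity")) {
  check_predictions(truth, score = score)
  focus <- match.arg(focus)
  if (cutoff <= 0 || cutoff >= 1) abort("`cutoff` must be in (0, 1).")
  p_tot <- sum(truth == 1)
  n_tot <- sum(truth == 0)
  if (p_tot == 0 || n_tot == 0) abort("both classes must be present.")
  if (focus == "sensitivity") {
    return(partial_auc_roc(1 - truth, -score, cutoff, focus = "specificity"))
  }
  path <- confusion_path(truth, score)
  fpr <- c(0, path$fp / n_tot)
  tpr <- c(0, path$tp / p_tot)
  fmax <- 1 - cutoff
  area <- 0
  for (k in seq_len(length(fpr) - 1)) {
    x0 <- fpr[k]; x1 <- fpr[k + 1]
    y0 <- tpr[k]; y1 <- tpr[k + 1]
    if (x0 >= fmax) break
    if (x1 > fmax) {
      y1 <- y0 + (y1 - y0) * (fmax - x0) / (x1 - x0)
      x1 <- fmax
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  min_a <- fmax^2 / 2
  max_a <- fmax
  0.5 * (1 + (area - min_a) / (max_a - min_a))
}

as_edge_table <- function(x, what) {
  if (inherits(x, "nb_dbn")) {
    return(list(edges = x$edges, nodes = x$nodes))
  }
  if (inherits(x, "simulation_spec")) {
    return(list(edges = mutate(tidy(x), truth = 1), nodes = rownames(x$adjacency)))
  }
  if (is.matrix(x)) {
    idx <- which(x != 0, arr.ind = TRUE)
    nodes <- rownames(x) %||% as.character(seq_len(nrow(x)))
    return(list(edges = tibble(parent = nodes[idx[, 1]], child = nodes[idx[, 2]]),
                nodes = nodes))
  }
  if (is.data.frame(x)) {
    return(list(edges = as_tibble(x), nodes = NULL))
  }
  abort(sprintf("cannot interpret `%s` as a network.", what))
}

#' Benchmark an inferred network against a gold standard
#'
#' Aligns every ordered gene pair (parent != child) between the true and
#' inferred networks and computes MCC (from the binary calls), AUC-PR and
#' corrected partial AUC-ROC (from the continuous scores), plus the
#' confusion counts and the true-edge prevalence.
#'
#' @param truth The gold standard: an adjacency matrix, a
#'   `simulation_spec`, or an edge tibble with `parent`, `child`.
#' @param network The inferred network: an `nb_dbn`, or an edge tibble with
#'   `parent`, `child`, `score` and optionally `selected`.
#' @param nodes Node set; required when neither argument carries one.
#' @param cutoff Partial AUC-ROC specificity cutoff.
#' @return A one-row tibble: `mcc`, `auc_pr`, `pauc_roc`, `tp`, `fp`, `tn`,
#'   `fn`, `n_pairs`, `prevalence`. `mcc` is `NA` when the inferred network
#'   carries no binary calls.
#' @export
benchmark_network <- function(truth, network, nodes = NULL, cutoff = 0.95) {
  tr <- as_edge_table(truth, "truth")
  inf <- as_edge_table(network, "network")
  nodes <- nodes %||% inf$nodes %||% tr$nodes
  if (is.null(nodes)) abort("supply `nodes` when using plain edge tables.")
  if (!is.null(tr$nodes) && !setequal(tr$nodes, nodes)) {
    d <- c(setdiff(tr$nodes, nodes), setdiff(nodes, tr$nodes))
    abort(paste0("node sets differ between truth and inferred network: ",
                 paste(d, collapse = ", ")))
  }
  pairs <- tidyr::expand_grid(parent = nodes, child = nodes) |>
    filter(.data$parent != .data$child)
  pairs$truth <- as.integer(
    paste(pairs$parent, pairs$child) %in%
      paste(tr$edges$parent, tr$edges$child))
  ed <- inf$edges
  pairs <- left_join(pairs, ed, by = c("parent", "child"))
  if (anyNA(pairs$score)) {
    abort("inferred network is missing scores for some ordered pairs.")
  }
  has_calls <- "selected" %in% names(ed)
  m <- if (has_calls) mcc(pairs$truth, pairs$selected) else NA_real_
  tp <- if (has_calls) sum(pairs$truth == 1 & pairs$selected) else NA_integer_
  fp <- if (has_calls) sum(pairs$truth == 0 & pairs$selected) else NA_integer_
  tn <- if (has_calls) sum(pairs$truth == 0 & !pairs$selected) else NA_integer_
  fn <- if (has_calls) sum(pairs$truth == 1 & !pairs$selected) else NA_integer_
  tibble(mcc = m,
         auc_pr = auc_pr(pairs$truth, pairs$score),
         pauc_roc = partial_auc_roc(pairs$truth, pairs$score, cutoff),
         tp = tp, fp = fp, tn = tn, fn = fn,
         n_pairs = nrow(pairs),
         prevalence = mean(pairs$truth))
}

#' Precision-recall and ROC curve plots
#'
#' @param truth 0/1 truth labels.
#' @param score Continuous scores.
#' @return A ggplot object.
#' @export
plot_pr_curve <- function(truth, score) {
  check_predictions(truth, score = score)
  path <- confusion_path(truth, score)
  df <- tibble(recall = path$tp / sum(truth == 1),
               precision = path$tp / (path$tp + path$fp))
  ggplot2::ggplot(df, ggplot2::aes(.data$recall, .data$precision)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = mean(truth), linetype = 2,
                        colour = "grey60") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}

#' @rdname plot_pr_curve
#' @export
plot_roc_curve <- function(truth, score) {
  check_predictions(truth, score = score)
  path <- confusion_path(truth, score)
  df <- tibble(fpr = c(0, path$fp / sum(truth == 0)),
               tpr = c(0, path$tp / sum(truth == 1)))
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
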