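#' Construct a regression problem
#'
#' A `regression_problem` holds one gene's response/predictor decomposition:
#' the response counts `y` at times 2..L, a design matrix whose rows are
#' (transformed) predictor values at the preceding time point, a final
#' all-ones intercept column, and an offset of log size factors for the
#' response samples.
#'
#' @param y Non-negative integer response counts (length N).
#' @param X Design matrix, N x (W + 1); the last column must be all ones.
#' @param offset Numeric offset vector of length N (log size factors);
#'   defaults to zeros.
#' @param predictors Labels for the W predictor columns.
#' @param gene Optional response gene identifier.
#' @param transform Label of the predictor transform that produced `X`.
#' @param dropped Labels of predictor columns that were constant and were
#'   zeroed out by standardization.
#' @return An object of class `regression_problem`.
#' @export
regression_problem <- function(y, X, offset = NULL, predictors = NULL,
                               gene = NULL, transform = "raw",
                               dropped = character()) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (length(y) != nrow(X)) abort("`y` and `X` must have matching rows.")
  if (length(y) < 2) abort("a regression problem needs at least 2 rows.")
  if (any(y < 0) || any(y != floor(y))) abort("`y` must be non-negative integers.")
  if (any(abs(X[, ncol(X)] - 1) > 0)) {
    abort("the last column of `X` must be the all-ones intercept column.")
  }
  if (is.null(offset)) offset <- rep(0, length(y))
  if (length(offset) != length(y)) abort("`offset` must match `y` in length.")
  W <- ncol(X) - 1L
  if (is.null(predictors)) predictors <- colnames(X)[seq_len(W)] %||%
      paste0("x", seq_len(W))
  colnames(X) <- c(predictors, "(intercept)")
  structure(list(y = y, X = X, offset = as.numeric(offset),
                 predictors = predictors, gene = gene,
                 transform = transform, dropped = dropped),
            class = "regression_problem")
}

#' @export
print.regression_problem <- function(x, ...) {
  cat(sprintf("<regression_problem> gene %s: N = %d, W = %d (%s transform)\n",
              x$gene %||% "?", length(x$y), length(x$predictors), x$transform))
  invisible(x)
}

# Predictor transform used both when building design matrices and when
# simulating from the model: log(1 + count / s) stabilizes the raw count
# scale so coefficients of order 0.3 are meaningful inside exp().
transform_predictor <- function(counts, sf, transform) {
  switch(transform,
         raw = counts,
         log = ,
         `log-std` = log1p(sweep(counts, 2, sf, "/")),
         abort(sprintf("unknown transform '%s'.", transform)))
}

#' Build one gene's regression problem from a count time series
#'
#' The response is the gene's counts at times 2..L (each replicate
#' contributing its own transitions; transitions never cross replicates).
#' Each design row holds the remaining genes' values at the preceding time
#' point of the same replicate, transformed per `transform`, plus an
#' intercept column. Offsets are the log size factors of the response
#' samples.
#'
#' @param data A [count_ts()].
#' @param gene Response gene identifier.
#' @param transform Predictor transform: `"log-std"` (log(1 + count/s),
#'   then centred and scaled to unit variance; the default), `"log"`
#'   (log(1 + count/s) only), or `"raw"` (untransformed counts).
#' @param self_edges Keep the response gene itself among the predictors?
#'   Off by default, so W = M - 1.
#' @return A [regression_problem()]. Predictor columns that are constant
#'   under `"log-std"` are set to zero and listed in the `dropped` field.
#' @export
build_problem <- function(data, gene,
                          transform = c("log-std", "log", "raw"),
                          self_edges = FALSE) {
  stopifnot(inherits(data, "count_ts"))
  transform <- match.arg(transform)
  if (!gene %in% rownames(data$counts)) {
    abort(sprintf("gene '%s' not present in the data.", gene))
  }
  times <- unique(data$samples$time)
  L <- length(times)
  if (L < 2) abort("at least 2 time points are required.")
  reps <- unique(data$samples$replicate)
  sample_of <- function(t, r) {
    data$samples$sample[data$samples$time == t & data$samples$replicate == r]
  }
  pred_genes <- if (self_edges) rownames(data$counts) else
    setdiff(rownames(data$counts), gene)

  resp_samples <- character(0)
  pred_samples <- character(0)
  for (r in reps) {
    resp_samples <- c(resp_samples, vapply(times[-1], sample_of, character(1), r = r))
    pred_samples <- c(pred_samples, vapply(times[-L], sample_of, character(1), r = r))
  }
  y <- as.numeric(data$counts[gene, resp_samples])
  sf_pred <- data$size_factors[pred_samples]
  Xg <- data$counts[pred_genes, pred_samples, drop = FALSE]
  Xt <- t(transform_predictor(Xg, sf_pred, transform))  # rows = transitions
  dropped <- character(0)
  if (transform == "log-std") {
    mu <- colMeans(Xt)
    s <- apply(Xt, 2, sd)
    const <- s == 0
    s[const] <- 1
    Xt <- sweep(sweep(Xt, 2, mu, "-"), 2, s, "/")
    Xt[, const] <- 0
    dropped <- pred_genes[const]
  }
  X <- cbind(Xt, 1)
  regression_problem(y = y, X = X,
                     offset = log(data$size_factors[resp_samples]),
                     predictors = pred_genes, gene = gene,
                     transform = transform, dropped = dropped)
}
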