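#' Count time series container
#'
#' Holds a gene-by-sample matrix of RNA-Seq counts together with the sample
#' metadata (time point and replicate per sample) and per-sample size
#' factors. Time points are ordered as they first appear in the metadata,
#' not lexicographically.
#'
#' @param counts Integer matrix, genes in rows (rownames required), samples
#'   in columns (colnames required).
#' @param samples Data frame with columns `sample`, `time`, `replicate`;
#'   one row per column of `counts`.
#' @param size_factors Optional named positive numeric vector, one entry per
#'   sample. If `NULL`, estimated with [size_factors()] using
#'   `size_factor_method`.
#' @param size_factor_method Method passed to [size_factors()] when
#'   `size_factors` is `NULL`.
#' @return An object of class `count_ts`.
#' @export
count_ts <- function(counts, samples,
                     size_factors = NULL,
                     size_factor_method = c("median-ratio", "total", "none")) {
  samples <- as_tibble(samples)
  if (!all(c("sample", "time", "replicate") %in% names(samples))) {
    abort("`samples` must have columns `sample`, `time`, `replicate`.")
  }
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have gene rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(counts))) {
    abort(paste0("duplicate gene identifier: ",
                 rownames(counts)[duplicated(rownames(counts))][1]))
  }
  if (anyDuplicated(samples$sample)) abort("duplicate sample identifier in metadata.")
  missing_meta <- setdiff(colnames(counts), samples$sample)
  if (length(missing_meta)) {
    abort(paste0("sample(s) missing from metadata: ",
                 paste(missing_meta, collapse = ", ")))
  }
  missing_counts <- setdiff(samples$sample, colnames(counts))
  if (length(missing_counts)) {
    abort(paste0("sample(s) missing from counts: ",
                 paste(missing_counts, collapse = ", ")))
  }
  counts <- counts[, samples$sample, drop = FALSE]
  bad <- which(counts < 0 | counts != floor(counts) | !is.finite(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("non-integer or negative count at gene '%s', sample '%s'.",
                  rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  if (anyDuplicated(samples[, c("time", "replicate")])) {
    abort("(time, replicate) pairs must be unique.")
  }
  grid <- tidyr::expand_grid(time = unique(samples$time),
                             replicate = unique(samples$replicate))
  miss <- dplyr::anti_join(grid, samples, by = c("time", "replicate"))
  if (nrow(miss)) {
    abort(sprintf("missing sample for (time = %s, replicate = %s).",
                  miss$time[1], miss$replicate[1]))
  }
  if (is.null(size_factors)) {
    size_factors <- size_factors(counts, method = match.arg(size_factor_method))
  }
  size_factors <- size_factors[colnames(counts)]
  if (any(is.na(size_factors)) || any(size_factors <= 0)) {
    abort("size factors must be positive, one per sample.")
  }
  structure(list(counts = counts, samples = samples,
                 size_factors = size_factors),
            class = "count_ts")
}

#' @export
print.count_ts <- function(x, ...) {
  cat(sprintf("<count_ts> %d genes x %d samples (%d time points, %d replicates)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$time)),
              length(unique(x$samples$replicate))))
  invisible(x)
}

#' @export
dim.count_ts <- function(x) dim(x$counts)

#' Long-format view of a count time series
#'
#' @param x A `count_ts`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample`, `time`, `replicate`,
#'   `count`, `size_factor`.
#' @method as_tibble count_ts
#' @export
as_tibble.count_ts <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "count")
  sf <- tibble(sample = names(x$size_factors), size_factor = unname(x$size_factors))
  long |>
    left_join(x$samples, by = "sample") |>
    left_join(sf, by = "sample") |>
    select("gene", "sample", "time", "replicate", "count", "size_factor")
}

#' Expression trajectories of a count time series
#'
#' One line per gene and replicate of depth-normalized counts over time.
#'
#' @param object A `count_ts`.
#' @param genes Optional character vector restricting which genes are drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot count_ts
#' @export
autoplot.count_ts <- function(object, genes = NULL, ...) {
  long <- as_tibble(object)
  if (!is.null(genes)) long <- filter(long, .data$gene %in% genes)
  long <- mutate(long,
                 time_idx = match(.data$time, unique(object$samples$time)),
                 norm = .data$count / .data$size_factor)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_idx, y = .data$norm,
                                     colour = .data$gene,
                                     group = interaction(.data$gene, .data$replicate))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = "time point", y = "normalized count", colour = "gene") +
    ggplot2::theme_minimal()
}
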