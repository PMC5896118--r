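#' Per-sample size factors
#'
#' Estimates sequencing-depth scaling factors for each sample. The default
#' is the median-of-ratios estimator (each sample's median ratio of counts
#' to per-gene geometric means, genes with any zero excluded), computed via
#' \code{DESeq2::estimateSizeFactorsForMatrix}. The `"total"` fallback
#' normalizes per-sample count sums to mean 1; `"none"` returns all ones.
#'
#' @param counts Gene-by-sample count matrix.
#' @param method `"median-ratio"` (default), `"total"`, or `"none"`.
#' @return Named positive numeric vector, one factor per sample.
#' @examples
#' m <- matrix(c(1, 2, 2, 4, 3, 6), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' size_factors(m)            # 1/sqrt(2), sqrt(2)
#' size_factors(m, "total")
#' @export
size_factors <- function(counts, method = c("median-ratio", "total", "none")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  samples <- colnames(counts) %||% paste0("s", seq_len(ncol(counts)))
  sf <- switch(method,
    "median-ratio" = {
      if (!any(apply(counts, 1, function(r) all(r > 0)))) {
        abort(paste0("median-of-ratios needs at least one gene with nonzero ",
                     "counts in every sample; use method = \"total\"."))
      }
      DESeq2::estimateSizeFactorsForMatrix(counts)
    },
    "total" = {
      cs <- colSums(counts)
      cs / mean(cs)
    },
    "none" = rep(1, ncol(counts))
  )
  setNames(as.numeric(sf), samples)
}

#' Read a count time series from TSV files
#'
#' The counts file is tab-separated with gene identifiers in the first
#' column and one column per sample; the metadata file has columns
#' `sample`, `time`, `replicate`. Sample sets must match between the two
#' files, every (time, replicate) pair must be present, and counts must be
#' non-negative integers. Time points are ordered as they appear in the
#' metadata.
#'
#' @param counts_path Path to the count matrix TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @param size_factor_method Passed to [size_factors()].
#' @return A [count_ts()].
#' @export
read_counts <- function(counts_path, metadata_path,
                        size_factor_method = c("median-ratio", "total", "none")) {
  tb <- readr::read_tsv(counts_path, show_col_types = FALSE)
  genes <- as.character(tb[[1]])
  m <- as.matrix(tb[, -1])
  rownames(m) <- genes
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  if (!all(c("sample", "time", "replicate") %in% names(meta))) {
    abort("metadata must have columns `sample`, `time`, `replicate`.")
  }
  count_ts(m, meta, size_factor_method = match.arg(size_factor_method))
}

#' Write a count time series as TSV files
#'
#' @param data A [count_ts()].
#' @param counts_path Output path for the count matrix.
#' @param metadata_path Output path for the sample metadata.
#' @return `counts_path`, invisibly.
#' @export
write_count_ts <- function(data, counts_path, metadata_path) {
  stopifnot(inherits(data, "count_ts"))
  tb <- as_tibble(data$counts, rownames = "gene")
  readr::write_tsv(tb, counts_path)
  readr::write_tsv(data$samples, metadata_path)
  invisible(counts_path)
}
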