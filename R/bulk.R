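#' Construct a bulk expression matrix with batch annotation
#'
#' Container for cross-study bulk RNA-seq harmonization: a genes x samples
#' numeric matrix plus a batch id per sample.
#'
#' @param values Genes x samples numeric matrix (no missing values).
#' @param batches Character/factor vector of batch ids, one per sample.
#' @return A list of class \code{BulkMatrix}.
#' @export
bulk_matrix <- function(values, batches) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("bulk matrix contains missing values")
  if (length(batches) != ncol(values)) {
    stop(sprintf("batches has length %d but matrix has %d samples",
                 length(batches), ncol(values)))
  }
  structure(list(values = values, batches = as.character(batches)),
            class = "BulkMatrix")
}

#' Shifted log2 transform
#'
#' Elementwise \code{log2(x + pseudocount)}, the first harmonization step
#' for raw bulk expression values.
#'
#' @param values Non-negative numeric matrix.
#' @param pseudocount Positive shift added before the log (default 1, so 0
#'   maps to 0).
#' @return Transformed matrix.
#' @export
log2_shift <- function(values, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  if (any(values < 0)) stop("log2_shift requires non-negative values")
  log2(values + pseudocount)
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to share one empirical distribution: each
#' sample's sorted values are replaced by the cross-sample means of the
#' order statistics, in the sample's original rank order; ties within a
#' sample receive the mean of their reference values. Backed by
#' \code{\link[limma]{normalizeQuantiles}}. The operation is idempotent.
#'
#' @param values Genes x samples numeric matrix with >= 2 samples (a single
#'   sample is returned unchanged with a warning).
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input")
    return(values)
  }
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Per-gene batch-mean centering
#'
#' Removes additive batch effects by, for every gene, subtracting each
#' batch's mean and adding back the grand mean — the no-covariate special
#' case of linear-model batch residualization. Every gene's per-batch means
#' become equal across batches and its grand mean is preserved.
#'
#' @param values Genes x samples numeric matrix.
#' @param batches Batch id per sample; every batch must have >= 1 sample.
#' @return Batch-centered matrix of the same shape.
#' @export
batch_center <- function(values, batches) {
  values <- as.matrix(values)
  batches <- as.character(batches)
  if (length(batches) != ncol(values)) {
    stop("batches must have one entry per sample (column)")
  }
  ids <- unique(batches)
  grand <- rowMeans(values)
  out <- values
  for (b in ids) {
    cols <- batches == b
    out[, cols] <- values[, cols] - rowMeans(values[, cols, drop = FALSE]) + grand
  }
  out
}

#' Full bulk harmonization: log2, quantile normalize, batch center
#'
#' @param bulk A \code{\link{bulk_matrix}} of raw non-negative values.
#' @param pseudocount Shift for \code{\link{log2_shift}}.
#' @return A \code{BulkMatrix} of harmonized values.
#' @export
harmonize_bulk <- function(bulk, pseudocount = 1) {
  stopifnot(inherits(bulk, "BulkMatrix"))
  v <- log2_shift(bulk$values, pseudocount)
  v <- quantile_normalize(v)
  v <- batch_center(v, bulk$batches)
  bulk_matrix(v, bulk$batches)
}
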