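#' Quality-control parameters
#'
#' Defaults follow standard single-cell practice for droplet data: a gene is
#' kept if detected in at least 3 cells; a cell is kept if it detects at
#' least 200 genes and its mitochondrial UMI fraction does not exceed 5%
#' (cells strictly above 5% are treated as dying and removed). Optional
#' depth bounds (UMIs per cell, genes per cell upper bound) default to off
#' because they are dataset-specific.
#'
#' @param min_cells_per_gene Minimum number of cells a gene must be detected
#'   in (count > 0) to be kept.
#' @param min_genes_per_cell Minimum number of detected genes for a cell.
#' @param max_mito_fraction Maximum allowed mitochondrial fraction of a
#'   cell's UMIs; the bound is inclusive (a cell at exactly this fraction is
#'   kept).
#' @param umi_bounds Optional numeric length-2 vector \code{c(low, high)} of
#'   inclusive total-UMI bounds per cell, or \code{NULL} (off).
#' @param genes_per_cell_upper Optional inclusive upper bound on detected
#'   genes per cell, or \code{NULL} (off).
#' @return A validated list of class \code{QCParams}.
#' @export
qc_params <- function(min_cells_per_gene = 3, min_genes_per_cell = 200,
                      max_mito_fraction = 0.05, umi_bounds = NULL,
                      genes_per_cell_upper = NULL) {
  stopifnot(min_cells_per_gene >= 0, min_genes_per_cell >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  if (!is.null(umi_bounds)) {
    stopifnot(length(umi_bounds) == 2, umi_bounds[1] >= 0,
              umi_bounds[1] <= umi_bounds[2])
  }
  structure(list(min_cells_per_gene = min_cells_per_gene,
                 min_genes_per_cell = min_genes_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 umi_bounds = umi_bounds,
                 genes_per_cell_upper = genes_per_cell_upper),
            class = "QCParams")
}

#' Apply quality-control filters in a single pass
#'
#' Gene and cell criteria are both evaluated on the raw input matrix
#' simultaneously (not iterated to a fixed point): a kept gene may therefore
#' fall below \code{min_cells_per_gene} among the surviving cells. The
#' mitochondrial fraction of a zero-count cell is defined as 0, so such
#' cells are removed by the detected-gene rule rather than a division error.
#'
#' Multiplet removal is supported only as an external exclusion list
#' (\code{exclude_barcodes}): cells on the list are dropped before any other
#' criterion and reported separately.
#'
#' @param dataset An \code{\link{expression_dataset}}.
#' @param params A \code{\link{qc_params}} object.
#' @param exclude_barcodes Optional character vector of barcodes to drop
#'   (e.g. externally identified multiplets).
#' @return A list with elements \code{dataset} (the filtered
#'   \code{ExpressionDataset}) and \code{report} (a \code{QCReport} list of
#'   in/out dimensions and per-criterion removal counts; criteria can
#'   overlap, so per-criterion counts may sum to more than the total
#'   removed).
#' @export
apply_qc <- function(dataset, params = qc_params(), exclude_barcodes = NULL) {
  validate_expression_dataset(dataset)
  stopifnot(inherits(params, "QCParams"))
  counts <- dataset$counts
  n_cells_in <- nrow(counts)
  n_genes_in <- ncol(counts)

  excluded <- dataset$cell_meta$barcode %in% exclude_barcodes
  eligible <- !excluded

  # all criteria measured on the raw input matrix
  detected <- counts > 0
  cells_per_gene <- Matrix::colSums(detected[eligible, , drop = FALSE])
  genes_per_cell <- Matrix::rowSums(detected)
  total_umi <- Matrix::rowSums(counts)
  mito_umi <- Matrix::rowSums(counts[, dataset$gene_meta$is_mito,
                                     drop = FALSE])
  mito_frac <- ifelse(total_umi > 0, mito_umi / total_umi, 0)

  gene_keep <- cells_per_gene >= params$min_cells_per_gene
  fail_genes <- genes_per_cell < params$min_genes_per_cell
  fail_mito <- mito_frac > params$max_mito_fraction
  fail_depth <- rep(FALSE, n_cells_in)
  if (!is.null(params$umi_bounds)) {
    fail_depth <- total_umi < params$umi_bounds[1] |
      total_umi > params$umi_bounds[2]
  }
  fail_upper <- rep(FALSE, n_cells_in)
  if (!is.null(params$genes_per_cell_upper)) {
    fail_upper <- genes_per_cell > params$genes_per_cell_upper
  }
  cell_keep <- eligible & !fail_genes & !fail_mito & !fail_depth & !fail_upper

  out <- subset_cells(dataset, cells = which(cell_keep),
                      genes = which(gene_keep))
  report <- list(
    n_cells_in = n_cells_in, n_cells_out = sum(cell_keep),
    n_genes_in = n_genes_in, n_genes_out = sum(gene_keep),
    removed_excluded = sum(excluded),
    removed_low_genes = sum(eligible & fail_genes),
    removed_high_mito = sum(eligible & fail_mito),
    removed_depth = sum(eligible & fail_depth),
    removed_high_genes = sum(eligible & fail_upper),
    removed_genes_low_cells = sum(!gene_keep))
  class(report) <- "QCReport"
  list(dataset = out, report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QC: cells %d -> %d, genes %d -> %d\n",
              x$n_cells_in, x$n_cells_out, x$n_genes_in, x$n_genes_out))
  cat(sprintf("  cells removed: %d low-genes, %d high-mito, %d depth, %d excluded\n",
              x$removed_low_genes, x$removed_high_mito,
              x$removed_depth + x$removed_high_genes, x$removed_excluded))
  invisible(x)
}
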