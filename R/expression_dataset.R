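#' Single-cell expression dataset container
#'
#' The package's central container: a sparse cells x genes matrix of
#' non-negative integer UMI counts plus aligned per-cell and per-gene
#' metadata. All package functions use the cells x genes orientation
#' internally regardless of on-disk layout.
#'
#' @param counts A cells x genes matrix coercible to a sparse
#'   \code{\link[Matrix]{dgCMatrix-class}}; entries must be non-negative
#'   integers (UMI counts).
#' @param cell_meta A data.frame with one row per cell. Must contain a
#'   \code{barcode} column (unique); \code{dataset_id}, \code{group_label}
#'   and \code{cluster} columns are added as \code{NA} when absent.
#' @param gene_meta A data.frame with one row per gene. Must contain a
#'   \code{symbol} column (unique); the logical \code{is_mito} column is
#'   derived with \code{\link{detect_mito}} when absent.
#' @param dataset_id Convenience scalar filled into \code{cell_meta$dataset_id}
#'   when that column is missing.
#'
#' @return An object of class \code{ExpressionDataset}: a list with elements
#'   \code{counts}, \code{cell_meta}, \code{gene_meta} and (after
#'   \code{\link{normalize_log}}) \code{lognorm}.
#' @export
expression_dataset <- function(counts, cell_meta = NULL, gene_meta = NULL,
                               dataset_id = "dataset1") {
  counts <- as_count_matrix(counts)
  n_cells <- nrow(counts)
  n_genes <- ncol(counts)

  if (is.null(cell_meta)) {
    cell_meta <- data.frame(barcode = sprintf("cell%d", seq_len(n_cells)),
                            stringsAsFactors = FALSE)
  }
  if (is.null(gene_meta)) {
    if (is.null(colnames(counts))) {
      stop("gene_meta or column names on 'counts' are required")
    }
    gene_meta <- data.frame(symbol = colnames(counts), stringsAsFactors = FALSE)
  }
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  gene_meta <- as.data.frame(gene_meta, stringsAsFactors = FALSE)
  if (!"dataset_id" %in% names(cell_meta)) cell_meta$dataset_id <- dataset_id
  if (!"group_label" %in% names(cell_meta)) cell_meta$group_label <- NA_character_
  if (!"cluster" %in% names(cell_meta)) cell_meta$cluster <- NA_character_
  if (!"is_mito" %in% names(gene_meta)) {
    gene_meta$is_mito <- detect_mito(gene_meta$symbol)
  }

  rownames(counts) <- cell_meta$barcode
  colnames(counts) <- gene_meta$symbol
  obj <- structure(list(counts = counts, cell_meta = cell_meta,
                        gene_meta = gene_meta),
                   class = "ExpressionDataset")
  validate_expression_dataset(obj)
  obj
}

# Coerce to sparse dgCMatrix and enforce the count contract.
as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (is.matrix(counts)) {
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  }
  counts <- methods::as(counts, "generalMatrix")
  counts <- methods::as(counts * 1, "CsparseMatrix")  # pattern/logical -> double
  x <- counts@x
  if (any(!is.finite(x))) stop("counts contain non-finite values")
  if (any(x < 0)) stop("counts must be non-negative")
  if (any(x != round(x))) stop("counts must be integral (UMI counts)")
  counts
}

#' Validate an ExpressionDataset
#'
#' Checks the container invariants: metadata lengths match the matrix shape,
#' counts are non-negative integers, barcodes and gene symbols are unique.
#' Called by all constructors; exported for defensive use at module
#' boundaries.
#'
#' @param x An \code{ExpressionDataset}.
#' @return \code{x}, invisibly, or an error describing the violation.
#' @export
validate_expression_dataset <- function(x) {
  stopifnot(inherits(x, "ExpressionDataset"))
  if (nrow(x$counts) != nrow(x$cell_meta)) {
    stop(sprintf("counts has %d cells but cell_meta has %d rows",
                 nrow(x$counts), nrow(x$cell_meta)))
  }
  if (ncol(x$counts) != nrow(x$gene_meta)) {
    stop(sprintf("counts has %d genes but gene_meta has %d rows",
                 ncol(x$counts), nrow(x$gene_meta)))
  }
  if (anyDuplicated(x$cell_meta$barcode)) stop("cell barcodes must be unique")
  if (anyDuplicated(x$gene_meta$symbol)) stop("gene symbols must be unique")
  if (!is.logical(x$gene_meta$is_mito)) stop("is_mito must be logical")
  if (length(x$counts@x) && (any(x$counts@x < 0) ||
                             any(x$counts@x != round(x$counts@x)))) {
    stop("counts must be non-negative integers")
  }
  invisible(x)
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d cells x %d genes (%d mito genes)\n",
              nrow(x$counts), ncol(x$counts), sum(x$gene_meta$is_mito)))
  cat(sprintf("  datasets: %s\n",
              paste(unique(x$cell_meta$dataset_id), collapse = ", ")))
  if (!is.null(x$lognorm)) cat("  layers: counts, lognorm\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$counts)

#' Subset an ExpressionDataset by cells and/or genes
#'
#' @param x An \code{ExpressionDataset}.
#' @param cells,genes Index vectors (integer, logical or character) into
#'   cells / genes; missing means keep all.
#' @param ... Ignored.
#' @return The subset \code{ExpressionDataset}; the \code{lognorm} layer, if
#'   present, is subset alongside.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL, ...) {
  if (is.null(cells)) cells <- seq_len(nrow(x$counts))
  if (is.null(genes)) genes <- seq_len(ncol(x$counts))
  if (is.character(cells)) cells <- match(cells, x$cell_meta$barcode)
  if (is.character(genes)) genes <- match(genes, x$gene_meta$symbol)
  x$counts <- x$counts[cells, genes, drop = FALSE]
  x$cell_meta <- x$cell_meta[cells, , drop = FALSE]
  x$gene_meta <- x$gene_meta[genes, , drop = FALSE]
  rownames(x$cell_meta) <- NULL
  rownames(x$gene_meta) <- NULL
  if (!is.null(x$lognorm)) x$lognorm <- x$lognorm[cells, genes, drop = FALSE]
  validate_expression_dataset(x)
  x
}

#' Flag mitochondrial genes by symbol prefix
#'
#' Case-insensitive prefix match on \code{"MT-"}, covering both the human
#' (\code{MT-ND4}) and mouse (\code{mt-Nd4}) nomenclature. An explicit gene
#' list overrides prefix matching entirely.
#'
#' @param symbols Character vector of gene symbols.
#' @param mito_genes Optional explicit character vector of mitochondrial gene
#'   symbols; when given, the prefix rule is not used.
#' @return Logical vector parallel to \code{symbols}.
#' @export
detect_mito <- function(symbols, mito_genes = NULL) {
  if (!is.null(mito_genes)) return(symbols %in% mito_genes)
  grepl("^mt-", symbols, ignore.case = TRUE)
}
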