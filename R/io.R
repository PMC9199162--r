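#' Read a 10x-style Matrix-Market triplet dataset
#'
#' Reads a coordinate-format sparse matrix plus its line-aligned barcode and
#' feature sidecar files. 10x-style exports store genes as matrix rows; the
#' returned container is always cells x genes, controlled by
#' \code{orientation} (default \code{"genes_rows"}, the 10x dialect).
#'
#' @param matrix_path Path to the \code{.mtx} coordinate file.
#' @param barcodes_path Path to a one-column TSV of cell barcodes.
#' @param features_path Path to a TSV of features; the gene symbol is taken
#'   from column 2 when present (10x convention: id, symbol, type), else
#'   column 1.
#' @param orientation Which axis the on-disk matrix rows represent.
#' @param dataset_id Dataset identifier recorded per cell.
#' @param mito_genes Optional explicit mitochondrial gene list passed to
#'   \code{\link{detect_mito}}.
#' @return An \code{\link{expression_dataset}}.
#' @export
read_sparse_triplet <- function(matrix_path, barcodes_path, features_path,
                                orientation = c("genes_rows", "cells_rows"),
                                dataset_id = "dataset1", mito_genes = NULL) {
  orientation <- match.arg(orientation)
  for (p in c(matrix_path, barcodes_path, features_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  }
  m <- Matrix::readMM(matrix_path)
  barcodes <- readLines(barcodes_path)
  feat <- utils::read.table(features_path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, quote = "",
                            colClasses = "character")
  symbols <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]

  if (orientation == "genes_rows") m <- Matrix::t(m)
  if (nrow(m) != length(barcodes)) {
    stop(sprintf("matrix implies %d cells but '%s' has %d barcodes",
                 nrow(m), barcodes_path, length(barcodes)))
  }
  if (ncol(m) != length(symbols)) {
    stop(sprintf("matrix implies %d genes but '%s' has %d features",
                 ncol(m), features_path, length(symbols)))
  }
  gene_meta <- data.frame(symbol = symbols,
                          is_mito = detect_mito(symbols, mito_genes),
                          stringsAsFactors = FALSE)
  if (ncol(feat) >= 2) gene_meta$gene_id <- feat[[1]]
  expression_dataset(m,
                     cell_meta = data.frame(barcode = barcodes,
                                            stringsAsFactors = FALSE),
                     gene_meta = gene_meta, dataset_id = dataset_id)
}

#' Write an ExpressionDataset as Matrix-Market triplet plus sidecars
#'
#' Inverse of \code{\link{read_sparse_triplet}}; writes the 10x dialect
#' (genes as matrix rows). Round-trips counts and names exactly.
#'
#' @param dataset An \code{ExpressionDataset}.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sparse_triplet <- function(dataset, dir) {
  validate_expression_dataset(dataset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(dataset$counts), file.path(dir, "matrix.mtx"))
  writeLines(dataset$cell_meta$barcode, file.path(dir, "barcodes.tsv"))
  feat <- dataset$gene_meta
  ids <- if ("gene_id" %in% names(feat)) feat$gene_id else feat$symbol
  utils::write.table(data.frame(ids, feat$symbol),
                     file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a dense count table
#'
#' Reads a rectangular TSV/CSV with a header row and an index column into the
#' same container as \code{\link{read_sparse_triplet}}.
#'
#' @param path Path to the table; delimiter inferred from the extension
#'   (\code{.csv} = comma, otherwise tab).
#' @param orientation \code{"cells_rows"} if rows are cells,
#'   \code{"genes_rows"} if rows are genes.
#' @param dataset_id Dataset identifier recorded per cell.
#' @param mito_genes Optional explicit mitochondrial gene list.
#' @return An \code{\link{expression_dataset}}.
#' @export
read_dense_table <- function(path, orientation = c("cells_rows", "genes_rows"),
                             dataset_id = "dataset1", mito_genes = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  lines <- readLines(path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) > 1) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("ragged table: row %d has %d fields, expected %d",
                 bad, widths[bad], widths[1]))
  }
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m) || anyNA(m)) {
    idx <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))),
                 arr.ind = TRUE)
    if (nrow(idx)) {
      stop(sprintf("non-numeric value at row '%s', column '%s'",
                   rownames(m)[idx[1, 1]], colnames(m)[idx[1, 2]]))
    }
    stop("table is not numeric")
  }
  if (orientation == "genes_rows") m <- t(m)
  symbols <- colnames(m)
  expression_dataset(m,
                     cell_meta = data.frame(barcode = rownames(m),
                                            stringsAsFactors = FALSE),
                     gene_meta = data.frame(
                       symbol = symbols,
                       is_mito = detect_mito(symbols, mito_genes),
                       stringsAsFactors = FALSE),
                     dataset_id = dataset_id)
}

#' Write an ExpressionDataset as a dense TSV (cells as rows)
#'
#' @param dataset An \code{ExpressionDataset}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_dense_table <- function(dataset, path) {
  m <- as.matrix(dataset$counts)
  utils::write.table(data.frame(barcode = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene panel set
#'
#' A \code{GenePanel} maps cell-type names to ordered marker gene lists,
#' used by \code{\link{annotate_clusters}}. Symbols are deduplicated within
#' a panel preserving first appearance.
#'
#' @param panels Named list of character vectors (cell type -> gene symbols).
#' @return An object of class \code{GenePanel}.
#' @export
gene_panel <- function(panels) {
  if (!length(panels) || is.null(names(panels)) || any(names(panels) == "")) {
    stop("panels must be a non-empty named list")
  }
  panels <- lapply(panels, function(g) unique(as.character(g)))
  empty <- names(panels)[lengths(panels) == 0]
  if (length(empty)) {
    stop(sprintf("empty panel for cell type(s): %s",
                 paste(empty, collapse = ", ")))
  }
  structure(list(panels = panels), class = "GenePanel")
}

#' Read gene panels from a two-column table
#'
#' Expects columns \code{cell_type} and \code{gene_symbol} (header optional;
#' the first two columns are used). Panel order and within-panel gene order
#' follow first appearance in the file.
#'
#' @param path Path to a TSV/CSV file.
#' @return A \code{\link{gene_panel}}.
#' @export
read_gene_panels <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  if (nrow(tab) == 0) stop("panel file has zero rows")
  if (ncol(tab) < 2) stop("panel file needs two columns (cell_type, gene)")
  types <- as.character(tab[[1]])
  genes <- as.character(tab[[2]])
  panels <- lapply(split(genes, factor(types, levels = unique(types))), unique)
  gene_panel(panels)
}
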