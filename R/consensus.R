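#' Per-gene detection frequency within a cell type
#'
#' Fraction of the cell type's cells in which each gene has a raw count
#' above zero.
#'
#' @param dataset An \code{\link{expression_dataset}}.
#' @param labels Per-cell cell-type labels (length = number of cells).
#' @param cell_type The cell type to evaluate.
#' @return Named numeric vector (one proportion per gene).
#' @export
detection_frequency <- function(dataset, labels, cell_type) {
  validate_expression_dataset(dataset)
  stopifnot(length(labels) == nrow(dataset$counts))
  if (!cell_type %in% labels) {
    stop(sprintf("unknown cell type '%s'; available: %s", cell_type,
                 paste(sort(unique(labels)), collapse = ", ")))
  }
  sub <- dataset$counts[labels == cell_type, , drop = FALSE]
  f <- Matrix::colSums(sub > 0) / nrow(sub)
  names(f) <- dataset$gene_meta$symbol
  f
}

#' Rank ratio (rank quantile) of a value vector
#'
#' The normative ranking underlying the consensus score. For gene g with
#' value v_g among G genes,
#' \deqn{ratio(g) = \frac{\#\{h \ne g: v_h < v_g\} + 0.5\,\#\{h \ne g: v_h = v_g\}}{G - 1}.}
#' A ratio of 0.6 means the gene's value exceeds 60% of the other genes'. A
#' strict unique maximum scores exactly 1 and a strict unique minimum
#' exactly 0; ties carry half weight, so an all-equal vector scores 0.5
#' everywhere.
#'
#' @param values Numeric vector, length >= 2.
#' @return Numeric vector of ratios in [0, 1], names preserved.
#' @export
rank_ratio <- function(values) {
  g <- length(values)
  if (g < 2) stop("rank_ratio needs at least 2 values")
  # rank(average) = #below + 0.5*#tied(incl. self) + 0.5, hence:
  r <- (rank(values, ties.method = "average") - 1) / (g - 1)
  names(r) <- names(values)
  r
}

#' Consensus score of every gene in every cell type
#'
#' For each cell type independently, every gene receives the sum of two
#' rank ratios: of its detection frequency (raw counts) and of its mean
#' log-normalized expression, both taken across all genes within that cell
#' type. The score is continuous on [0, 2]: a gene that is both the most
#' frequently detected and the most expressed in a cell type scores exactly
#' 2, the strict minimum in both scores exactly 0.
#'
#' @param dataset A dataset with a \code{lognorm} layer
#'   (\code{\link{normalize_log}}).
#' @param labels Per-cell cell-type labels; types with zero cells are
#'   omitted with a warning.
#' @return A data.frame sorted by decreasing consensus within cell type,
#'   with columns \code{cell_type}, \code{gene}, \code{detection_frequency},
#'   \code{mean_expression}, \code{freq_ratio}, \code{expr_ratio},
#'   \code{consensus}.
#' @export
consensus_scores <- function(dataset, labels) {
  layer <- require_lognorm(dataset)
  stopifnot(length(labels) == nrow(layer))
  if (ncol(layer) < 2) stop("consensus scores need at least 2 genes")
  types <- if (is.factor(labels)) levels(labels) else unique(labels)
  empty <- setdiff(types, as.character(labels))
  if (length(empty)) {
    warning(sprintf("omitting cell type(s) with 0 cells: %s",
                    paste(empty, collapse = ", ")))
    types <- setdiff(types, empty)
  }
  labels <- as.character(labels)
  out <- lapply(types, function(ct) {
    cells <- which(labels == ct)
    freq <- Matrix::colSums(dataset$counts[cells, , drop = FALSE] > 0) /
      length(cells)
    expr <- sparse_col_means(layer[cells, , drop = FALSE])
    fr <- rank_ratio(freq)
    er <- rank_ratio(expr)
    df <- data.frame(cell_type = ct, gene = dataset$gene_meta$symbol,
                     detection_frequency = as.numeric(freq),
                     mean_expression = as.numeric(expr),
                     freq_ratio = fr, expr_ratio = er,
                     consensus = fr + er,
                     stringsAsFactors = FALSE, row.names = NULL)
    df[order(-df$consensus, df$gene), ]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
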