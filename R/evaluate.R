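## Benchmark metrics: assignment accuracy, adjusted Rand index, rank-based
## AUC, and expression-decile stratification of genes.

#' Clone-assignment accuracy
#'
#' Fraction of cells whose label equals the ground truth. Clone identities
#' are shared between fit and truth (assignment is to named profiles), so no
#' label-matching step is applied. By default unassigned cells count as
#' incorrect; set `exclude_unassigned = TRUE` to drop them from the
#' denominator instead.
#'
#' @param labels named (or positionally matched) predicted labels.
#' @param truth ground-truth labels over the same cells.
#' @param exclude_unassigned drop `"unassigned"` cells from the denominator.
#' @return fraction in `[0, 1]`.
#' @export
clone_accuracy <- function(labels, truth, exclude_unassigned = FALSE) {
  if (!is.null(names(labels)) && !is.null(names(truth))) {
    common <- intersect(names(labels), names(truth))
    if (length(common) == 0) stop_ca("label and truth cell sets are disjoint")
    labels <- labels[common]; truth <- truth[common]
  } else if (length(labels) != length(truth)) {
    stop_ca("labels and truth differ in length and carry no names")
  }
  if (exclude_unassigned) {
    keep <- labels != "unassigned"
    if (!any(keep)) return(0)
    labels <- labels[keep]; truth <- truth[keep]
  }
  mean(labels == truth)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement; identical partitions score 1,
#' random labelings score approximately 0.
#'
#' @param labels,truth label vectors over the same cells (named vectors are
#'   aligned by name).
#' @return ARI in `[-1, 1]`.
#' @export
ari <- function(labels, truth) {
  if (!is.null(names(labels)) && !is.null(names(truth))) {
    common <- intersect(names(labels), names(truth))
    if (length(common) == 0) stop_ca("label and truth cell sets are disjoint")
    labels <- labels[common]; truth <- truth[common]
  }
  stopifnot(length(labels) == length(truth))
  if (identical(as.character(labels), as.character(truth))) return(1)
  mclust::adjustedRandIndex(labels, truth)
}

#' Rank-based area under the ROC curve
#'
#' The Mann-Whitney statistic divided by `n1 * n0`; tied scores contribute
#' one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param binary_truth 0/1 (or logical) class labels; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, binary_truth) {
  y <- as.integer(as.logical(binary_truth))
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop_ca("AUC undefined: truth contains one class only")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratify genes by mean normalized expression
#'
#' Normalized expression is the count divided by the cell total (per-cell
#' relative abundance), averaged over cells; genes are ranked and split into
#' `n_bins` (near-)equal-size bins from low (bin 1) to high expression. Ties
#' are broken by input gene order. "Top 40%" corresponds to the top 4 of 10
#' bins.
#'
#' @param genes gene identifiers (subset of `expr` genes).
#' @param expr an [expression_matrix()].
#' @param n_bins number of bins (default 10 deciles).
#' @return integer bin index per gene (named), 1 = lowest expression.
#' @export
stratify_by_expression <- function(genes, expr, n_bins = 10) {
  stopifnot(all(genes %in% colnames(expr$counts)))
  tot <- pmax(expr$cell_totals, 1)
  norm <- colMeans(expr$counts[, genes, drop = FALSE] / tot)
  ord <- order(norm, seq_along(norm))      # ties by input order
  bins <- integer(length(genes))
  bins[ord] <- ceiling(seq_along(genes) / (length(genes) / n_bins))
  bins <- pmin(bins, n_bins)
  stats::setNames(bins, genes)
}

#' Genes in the top fraction by normalized expression
#'
#' @param expr an [expression_matrix()].
#' @param frac fraction of genes to keep (default 0.4, the top four
#'   expression deciles).
#' @param genes gene universe (default: all genes in `expr`).
#' @return character vector of gene identifiers.
#' @export
top_expressed_genes <- function(expr, frac = 0.4, genes = colnames(expr$counts)) {
  bins <- stratify_by_expression(genes, expr, n_bins = 10)
  cutoff <- 10 - round(frac * 10) + 1
  genes[bins >= cutoff]
}
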