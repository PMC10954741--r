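## Preprocessing: clade-level copy number by mode, selection of genes with
## clone-specific copy number (CSCN), clone-level BAF aggregation and SNP
## filtering.

#' Summarize a clade's copy number by the per-gene mode
#'
#' For each gene, takes the statistical mode of the copy number over the
#' clade's member cells (ties broken by the smallest tied value; copy numbers
#' are already truncated at the container's cap).
#'
#' @param cn a [cn_matrix()].
#' @param cells character vector of member scDNA cell identifiers.
#' @return named numeric vector of per-gene modal copy numbers.
#' @export
clade_cn_mode <- function(cn, cells) {
  stopifnot(inherits(cn, "cn_matrix"))
  cells <- as.character(cells)
  if (length(cells) == 0) stop_ca("empty cell set")
  missing <- setdiff(cells, rownames(cn$cn))
  if (length(missing)) stop_ca("cells absent from CN matrix: %s", missing[1])
  sub <- cn$cn[cells, , drop = FALSE]
  apply(sub, 2L, int_mode)
}

#' Select genes with clone-specific copy number that are expressed
#'
#' A gene is kept when its copy number differs between at least two clones
#' and it is detected (count > 0) in at least `min_expr_frac` of the RNA
#' cells. Input order is preserved; the result is invariant to permuting the
#' clone columns.
#'
#' @param profile a [clone_cn_profile()].
#' @param expr an [expression_matrix()] sharing a gene universe with
#'   `profile`.
#' @param min_expr_frac minimum detection fraction (default 0.01).
#' @return character vector of selected gene identifiers.
#' @export
select_cscn_genes <- function(profile, expr, min_expr_frac = 0.01) {
  genes <- intersect(rownames(profile$cn), colnames(expr$counts))
  if (!length(genes)) return(character())
  diffs <- cscn_genes(profile)
  detected <- colMeans(expr$counts[, genes, drop = FALSE] > 0) >= min_expr_frac
  genes[genes %in% diffs & detected[genes]]
}

#' Aggregate per-cell BAF to clone level
#'
#' Clone-level \eqn{b_{sc}} is the mean of the per-cell BAF over the clade's
#' member cells; missing entries (`NA`) are ignored rather than imputed.
#' SNPs with no covered cell in some clone are dropped with a logged count.
#'
#' @param cell_baf scDNA-cell x SNP matrix of per-cell BAFs (may contain
#'   `NA`).
#' @param clades named list of character vectors partitioning (a subset of)
#'   the rows of `cell_baf` into clones.
#' @param verbose log dropped SNPs.
#' @return SNP x clone matrix of clone BAFs.
#' @export
clone_baf <- function(cell_baf, clades, verbose = TRUE) {
  stopifnot(is.list(clades), length(clades) >= 1)
  if (any(lengths(clades) == 0)) stop_ca("every clade must be nonempty")
  out <- vapply(clades, function(cells) {
    colMeans(cell_baf[cells, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(cell_baf)))
  out <- matrix(out, ncol = length(clades),
                dimnames = list(colnames(cell_baf), names(clades)))
  ok <- rowSums(is.na(out)) == 0
  if (any(!ok)) {
    ca_log("clone_baf: dropped %d SNPs with no covered cell in some clone",
           sum(!ok), verbose = verbose)
  }
  out[ok, , drop = FALSE]
}

#' Filter SNPs for the allele model
#'
#' Retains SNPs with aggregate scRNA coverage of at least `min_total_reads`,
#' a between-clone BAF spread of at least `min_baf_delta`, and (by default)
#' not on chromosome X. The X filter exists because X-inactivation produces
#' allelic imbalance in scRNA that is absent from scDNA, which would mislead
#' the model.
#'
#' @param allele an [allele_data()].
#' @param min_total_reads minimum aggregate scRNA reads per SNP (default 10).
#' @param exclude_chrX drop SNPs annotated on chromosome X (default `TRUE`).
#' @param min_baf_delta minimum `max_c b_sc - min_c b_sc` (default 0.05).
#' @param verbose log the retained count.
#' @return a filtered [allele_data()].
#' @export
filter_snps <- function(allele, min_total_reads = 10, exclude_chrX = TRUE,
                        min_baf_delta = 0.05, verbose = TRUE) {
  S <- n_snps(allele)
  if (S == 0) return(allele)
  cov_ok <- colSums(allele$total_counts) >= min_total_reads
  spread <- apply(allele$baf_clone, 1L, function(r) max(r) - min(r))
  baf_ok <- spread >= min_baf_delta
  chr_ok <- rep(TRUE, S)
  if (exclude_chrX && !is.null(allele$chrom)) {
    chr_ok <- !(allele$chrom %in% c("X", "chrX", "x", "chrx"))
  }
  keep <- which(cov_ok & baf_ok & chr_ok)
  ca_log("filter_snps: kept %d / %d SNPs", length(keep), S, verbose = verbose)
  subset_allele(allele, keep)
}

subset_allele <- function(allele, idx) {
  allele_data(allele$baf_clone[idx, , drop = FALSE],
              allele$ref_counts[, idx, drop = FALSE],
              allele$total_counts[, idx, drop = FALSE],
              chrom = if (!is.null(allele$chrom)) allele$chrom[idx] else NULL,
              pos = if (!is.null(allele$pos)) allele$pos[idx] else NULL)
}

## restrict allele data to a set of RNA cells (rows)
subset_allele_cells <- function(allele, cells) {
  allele_data(allele$baf_clone,
              allele$ref_counts[cells, , drop = FALSE],
              allele$total_counts[cells, , drop = FALSE],
              chrom = allele$chrom, pos = allele$pos)
}
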