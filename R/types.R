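## Domain types. All containers are light S3 wrappers around base matrices
## with dimnames carrying the cell / gene / clone / SNP identifiers.

#' Construct an expression matrix container
#'
#' Holds raw scRNA-seq read counts for N cells by G genes, together with the
#' per-cell total read counts \eqn{l_n} (row sums). Counts must be
#' non-negative integers and identifiers unique.
#'
#' @param counts numeric matrix, cells in rows, genes in columns.
#' @param cell_ids,gene_ids optional character vectors; default to the
#'   dimnames of `counts`.
#' @return an object of class `expression_matrix` with elements `counts`
#'   (integer-valued matrix with dimnames) and `cell_totals`.
#' @export
expression_matrix <- function(counts, cell_ids = rownames(counts),
                              gene_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(cell_ids)) stop_ca("duplicate cell identifiers")
  if (anyDuplicated(gene_ids)) stop_ca("duplicate gene identifiers")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_ca("counts must be non-negative integers; first offence at row %d (%s), column %d (%s)",
            bad[1, 1], cell_ids[bad[1, 1]], bad[1, 2], gene_ids[bad[1, 2]])
  }
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_totals = rowSums(counts)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes, median depth %g\n",
              nrow(x$counts), ncol(x$counts), stats::median(x$cell_totals)))
  invisible(x)
}

#' Construct a cell-level copy-number matrix
#'
#' Integer copy numbers from scDNA-seq, cells in rows and genes in columns.
#' Copy numbers above `cn_cap` (default 10) are truncated to `cn_cap` on
#' construction; truncation is idempotent.
#'
#' @param cn numeric matrix of non-negative integers.
#' @param cell_ids,gene_ids identifier vectors (default: dimnames).
#' @param cn_cap truncation ceiling for extreme amplifications.
#' @return object of class `cn_matrix`.
#' @export
cn_matrix <- function(cn, cell_ids = rownames(cn), gene_ids = colnames(cn),
                      cn_cap = 10) {
  cn <- as.matrix(cn)
  if (is.null(cell_ids)) cell_ids <- paste0("dna", seq_len(nrow(cn)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(cn)))
  if (anyDuplicated(cell_ids)) stop_ca("duplicate cell identifiers")
  if (anyDuplicated(gene_ids)) stop_ca("duplicate gene identifiers")
  if (any(cn < 0) || any(cn != round(cn))) {
    stop_ca("copy numbers must be non-negative integers")
  }
  cn[cn > cn_cap] <- cn_cap
  storage.mode(cn) <- "double"
  dimnames(cn) <- list(as.character(cell_ids), as.character(gene_ids))
  structure(list(cn = cn, cn_cap = cn_cap), class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat(sprintf("<cn_matrix> %d cells x %d genes (cap %g)\n",
              nrow(x$cn), ncol(x$cn), x$cn_cap))
  invisible(x)
}

#' Construct a gene-by-clone copy-number profile
#'
#' The model input \eqn{\lambda_{gc}}: one copy-number column per clone.
#' Values above `cn_cap` are truncated; values below `cn_floor` (default 0.1)
#' are raised to `cn_floor`, so that a homozygous deletion still admits the
#' occasional stray read instead of a zero-probability count.
#'
#' @param cn numeric matrix, genes in rows, clones in columns.
#' @param gene_ids,clone_ids identifiers (default: dimnames).
#' @param cn_floor,cn_cap clamping bounds for \eqn{\lambda}.
#' @return object of class `clone_cn_profile`.
#' @export
clone_cn_profile <- function(cn, gene_ids = rownames(cn),
                             clone_ids = colnames(cn),
                             cn_floor = 0.1, cn_cap = 10) {
  cn <- as.matrix(cn)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(cn)))
  if (is.null(clone_ids)) clone_ids <- LETTERS[seq_len(ncol(cn))]
  if (ncol(cn) < 2) stop_ca("a clone profile needs at least 2 clones")
  if (anyDuplicated(gene_ids)) stop_ca("duplicate gene identifiers")
  if (anyDuplicated(clone_ids)) stop_ca("duplicate clone identifiers")
  if (any(cn < 0)) stop_ca("copy numbers must be non-negative")
  cn[cn > cn_cap] <- cn_cap
  cn[cn < cn_floor] <- cn_floor
  storage.mode(cn) <- "double"
  dimnames(cn) <- list(as.character(gene_ids), as.character(clone_ids))
  structure(list(cn = cn, cn_floor = cn_floor, cn_cap = cn_cap),
            class = "clone_cn_profile")
}

#' @export
print.clone_cn_profile <- function(x, ...) {
  cat(sprintf("<clone_cn_profile> %d genes x %d clones (%s)\n",
              nrow(x$cn), ncol(x$cn), paste(colnames(x$cn), collapse = ", ")))
  invisible(x)
}

#' Genes whose copy number differs between clones
#'
#' @param profile a [clone_cn_profile()].
#' @return character vector of gene identifiers with clone-specific copy
#'   number (CSCN genes).
#' @export
cscn_genes <- function(profile) {
  cn <- profile$cn
  rownames(cn)[apply(cn, 1L, function(r) max(r) - min(r) > 1e-9)]
}

#' Construct an allele-data container
#'
#' Per-SNP clone B-allele frequencies \eqn{b_{sc}} from scDNA together with
#' per-cell scRNA reference and total read counts at the same heterozygous
#' SNPs. An empty container (`S = 0`) is accepted and degrades the
#' integrated model to the total-copy-number model.
#'
#' @param baf_clone S x C matrix of clone BAFs in `[0, 1]`.
#' @param ref_counts,total_counts N x S matrices of scRNA reference / total
#'   read counts, `0 <= ref <= total`.
#' @param snp_ids,clone_ids,cell_ids identifiers (default: dimnames).
#' @param chrom,pos optional per-SNP chromosome labels and 1-based positions
#'   (used only for reporting and chromosome-X filtering).
#' @return object of class `allele_data`.
#' @export
allele_data <- function(baf_clone, ref_counts, total_counts,
                        snp_ids = rownames(baf_clone),
                        clone_ids = colnames(baf_clone),
                        cell_ids = rownames(ref_counts),
                        chrom = NULL, pos = NULL) {
  baf_clone <- as.matrix(baf_clone)
  ref_counts <- as.matrix(ref_counts)
  total_counts <- as.matrix(total_counts)
  S <- nrow(baf_clone)
  if (is.null(snp_ids)) snp_ids <- if (S) paste0("snp", seq_len(S)) else character()
  if (is.null(clone_ids)) clone_ids <- LETTERS[seq_len(ncol(baf_clone))]
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(ref_counts)))
  if (S > 0) {
    if (any(baf_clone < 0 | baf_clone > 1)) stop_ca("clone BAF outside [0, 1]")
    if (ncol(ref_counts) != S || ncol(total_counts) != S) {
      stop_ca("count matrices must have one column per SNP")
    }
    bad <- which(ref_counts > total_counts | ref_counts < 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop_ca("reference count exceeds total (or is negative) at cell %s, SNP %s",
              cell_ids[bad[1, 1]], snp_ids[bad[1, 2]])
    }
  }
  dimnames(baf_clone) <- list(snp_ids, clone_ids)
  dimnames(ref_counts) <- list(cell_ids, snp_ids)
  dimnames(total_counts) <- list(cell_ids, snp_ids)
  if (!is.null(chrom)) chrom <- as.character(chrom)
  structure(list(baf_clone = baf_clone, ref_counts = ref_counts,
                 total_counts = total_counts, chrom = chrom, pos = pos),
            class = "allele_data")
}

#' @export
print.allele_data <- function(x, ...) {
  cat(sprintf("<allele_data> %d SNPs x %d clones, %d cells\n",
              nrow(x$baf_clone), ncol(x$baf_clone), nrow(x$ref_counts)))
  invisible(x)
}

#' Number of SNPs in an allele-data container
#' @param allele an [allele_data()] object or `NULL`.
#' @return integer SNP count (0 for `NULL`).
#' @export
n_snps <- function(allele) {
  if (is.null(allele)) 0L else nrow(allele$baf_clone)
}

#' Empty allele data
#' @param cell_ids cell identifiers for the (zero-column) count matrices.
#' @param clone_ids clone identifiers.
#' @return an [allele_data()] object with zero SNPs.
#' @export
empty_allele_data <- function(cell_ids = character(), clone_ids = c("A", "B")) {
  n <- length(cell_ids)
  allele_data(matrix(0, 0, length(clone_ids),
                     dimnames = list(NULL, clone_ids)),
              matrix(0, n, 0, dimnames = list(cell_ids, NULL)),
              matrix(0, n, 0, dimnames = list(cell_ids, NULL)))
}

new_fit_result <- function(clone_posterior, clone_label, consistency, p_k, p_a,
                           mu0, mu1, pi, psi, w, chi, elbo_trace, converged,
                           seed, n_iter, baseline_r = NULL, restart_labels = NULL) {
  structure(list(clone_posterior = clone_posterior, clone_label = clone_label,
                 consistency = consistency, p_k = p_k, p_a = p_a,
                 mu0 = mu0, mu1 = mu1, pi = pi, psi = psi, w = w, chi = chi,
                 elbo_trace = elbo_trace, converged = converged, seed = seed,
                 n_iter = n_iter, baseline_r = baseline_r,
                 restart_labels = restart_labels),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d cells -> %d clones; ELBO %.2f after %d iterations (%s)\n",
              nrow(x$clone_posterior), ncol(x$clone_posterior),
              utils::tail(x$elbo_trace, 1), x$n_iter,
              if (isTRUE(x$converged)) "converged" else "max iterations"))
  tab <- table(factor(x$clone_label))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

validate_fit_result <- function(fit, tol = 1e-8) {
  stopifnot(inherits(fit, "fit_result"))
  rs <- rowSums(fit$clone_posterior)
  if (any(abs(rs - 1) > tol)) stop_ca("posterior rows do not sum to 1")
  if (any(fit$p_k < -tol | fit$p_k > 1 + tol)) stop_ca("p_k outside [0, 1]")
  if (length(fit$p_a) && any(fit$p_a < -tol | fit$p_a > 1 + tol)) {
    stop_ca("p_a outside [0, 1]")
  }
  if (abs(sum(fit$pi) - 1) > tol) stop_ca("pi does not sum to 1")
  if (any(fit$mu0 <= 0) || any(fit$mu1 <= 0)) stop_ca("mu must be positive")
  invisible(TRUE)
}
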