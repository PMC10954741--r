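## Readers and writers. All delimited files are tab-separated with a header
## row (UTF-8); sparse expression travels as matrix-market triplets with
## sidecar barcode / feature lists (10x convention: features in rows, cells
## in columns).

read_tsv_ca <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

write_tsv_ca <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Read an scRNA count matrix
#'
#' Two on-disk layouts are supported: a matrix-market triplet file with
#' sidecar barcode and feature lists (the 10x convention, genes in rows and
#' cells in columns — transposed on load), or a dense tab-separated table
#' with a `cell_id` first column and one column per gene.
#'
#' @param path path to the `.mtx` file or the dense TSV.
#' @param format `"auto"` (by extension), `"mtx"` or `"dense"`.
#' @param barcodes,features sidecar paths for the mtx layout; default to
#'   `barcodes.tsv` and `features.tsv` (or `genes.tsv`) next to the matrix.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "mtx", "dense"),
                            barcodes = NULL, features = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense"
  }
  if (!file.exists(path)) stop_ca("no such file: %s", path)
  if (format == "mtx") {
    dir <- dirname(path)
    if (is.null(barcodes)) barcodes <- file.path(dir, "barcodes.tsv")
    if (is.null(features)) {
      features <- file.path(dir, "features.tsv")
      if (!file.exists(features)) features <- file.path(dir, "genes.tsv")
    }
    m <- Matrix::readMM(path)
    bc <- readLines(barcodes, encoding = "UTF-8")
    ft <- utils::read.delim(features, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(ft) || ncol(m) != length(bc)) {
      stop_ca("matrix is %d x %d but features/barcodes have %d/%d entries",
              nrow(m), ncol(m), length(ft), length(bc))
    }
    counts <- t(as.matrix(m))  # cells x genes
    expression_matrix(counts, cell_ids = bc, gene_ids = ft)
  } else {
    df <- read_tsv_ca(path)
    cells <- as.character(df[[1]])
    counts <- as.matrix(df[, -1, drop = FALSE])
    expression_matrix(counts, cell_ids = cells, gene_ids = colnames(df)[-1])
  }
}

#' Write an expression matrix as matrix-market triplets with sidecars
#'
#' @param expr an [expression_matrix()].
#' @param dir output directory (created if missing); files `matrix.mtx`,
#'   `barcodes.tsv`, `features.tsv`.
#' @return `dir`, invisibly.
#' @export
write_expression <- function(expr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(expr$counts), sparse = TRUE)  # genes x cells
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(expr$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(expr$counts), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read a copy-number table
#'
#' Cell-level mode expects a TSV with a `cell_id` first column and one column
#' per gene; clone-level mode expects a `gene_id` first column and one column
#' per clone. Copy numbers above 10 are truncated to 10; in clone-level mode
#' values are additionally floored at `cn_floor`.
#'
#' @param path TSV path.
#' @param mode `"cell"` or `"clone"`.
#' @param cn_floor floor applied to clone profiles (see [clone_cn_profile()]).
#' @return a [cn_matrix()] or [clone_cn_profile()].
#' @export
read_cn <- function(path, mode = c("cell", "clone"), cn_floor = 0.1) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop_ca("no such file: %s", path)
  df <- read_tsv_ca(path)
  if (ncol(df) < 2) stop_ca("copy-number table needs id column plus data columns")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (mode == "cell") {
    cn_matrix(m, cell_ids = ids, gene_ids = colnames(df)[-1])
  } else {
    clone_cn_profile(m, gene_ids = ids, clone_ids = colnames(df)[-1],
                     cn_floor = cn_floor)
  }
}

#' Write a clone copy-number profile as TSV
#' @param profile a [clone_cn_profile()] or [cn_matrix()].
#' @param path output path.
#' @export
write_cn <- function(profile, path) {
  if (inherits(profile, "clone_cn_profile")) {
    df <- data.frame(gene_id = rownames(profile$cn), profile$cn,
                     check.names = FALSE)
  } else {
    df <- data.frame(cell_id = rownames(profile$cn), profile$cn,
                     check.names = FALSE)
  }
  write_tsv_ca(df, path)
  invisible(path)
}

#' Read a rooted phylogeny over scDNA cells
#'
#' Parses a Newick file with [ape::read.tree()]. Leaf labels must be unique;
#' they are matched against scDNA cell identifiers downstream. Node
#' identifiers are assigned deterministically in preorder. A root with more
#' than two children is accepted but flagged via the `"multifurcating_root"`
#' attribute.
#'
#' @param path Newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop_ca("no such file: %s", path)
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tr)) stop_ca("could not parse Newick in %s", path)
  if (anyDuplicated(tr$tip.label)) stop_ca("duplicate leaf names in tree")
  root <- ape::Ntip(tr) + 1L
  nchild <- sum(tr$edge[, 1] == root)
  attr(tr, "multifurcating_root") <- nchild > 2
  tr
}

#' Read allele data from a BAF table and a long count table
#'
#' `path_baf`: TSV with columns `snp_id`, `chrom`, `pos`, then one column per
#' clone holding scDNA B-allele frequencies. `path_counts`: long TSV with
#' columns `cell_id`, `snp_id`, `ref_count`, `total_count` holding scRNA
#' read counts (SNP/cell pairs with zero coverage may be omitted). SNPs
#' missing from either table are dropped with a logged count.
#'
#' @param path_baf,path_counts TSV paths.
#' @param cell_ids optional cell universe; defaults to the cells seen in the
#'   count table.
#' @param verbose log dropped-SNP counts.
#' @return an [allele_data()].
#' @export
read_allele <- function(path_baf, path_counts, cell_ids = NULL, verbose = TRUE) {
  baf <- read_tsv_ca(path_baf)
  cnt <- read_tsv_ca(path_counts)
  need <- c("cell_id", "snp_id", "ref_count", "total_count")
  if (!all(need %in% colnames(cnt))) {
    stop_ca("count table must have columns %s", paste(need, collapse = ", "))
  }
  if (any(cnt$ref_count > cnt$total_count | cnt$ref_count < 0)) {
    i <- which(cnt$ref_count > cnt$total_count | cnt$ref_count < 0)[1]
    stop_ca("ref_count > total_count at cell %s, SNP %s",
            cnt$cell_id[i], cnt$snp_id[i])
  }
  meta_cols <- intersect(c("snp_id", "chrom", "pos"), colnames(baf))
  clone_cols <- setdiff(colnames(baf), meta_cols)
  snps_baf <- as.character(baf$snp_id)
  snps_cnt <- unique(as.character(cnt$snp_id))
  keep <- intersect(snps_baf, snps_cnt)
  dropped <- length(union(snps_baf, snps_cnt)) - length(keep)
  if (dropped > 0) {
    ca_log("read_allele: dropped %d SNPs absent from one of the two tables",
           dropped, verbose = verbose)
  }
  baf <- baf[match(keep, snps_baf), , drop = FALSE]
  if (is.null(cell_ids)) cell_ids <- unique(as.character(cnt$cell_id))
  S <- length(keep)
  ref <- matrix(0, length(cell_ids), S, dimnames = list(cell_ids, keep))
  tot <- matrix(0, length(cell_ids), S, dimnames = list(cell_ids, keep))
  cnt <- cnt[cnt$snp_id %in% keep & cnt$cell_id %in% cell_ids, , drop = FALSE]
  if (nrow(cnt)) {
    ij <- cbind(match(cnt$cell_id, cell_ids), match(cnt$snp_id, keep))
    ref[ij] <- cnt$ref_count
    tot[ij] <- cnt$total_count
  }
  bm <- as.matrix(baf[, clone_cols, drop = FALSE])
  uninformative <- sum(apply(bm, 1L, function(r) max(r) - min(r) < 1e-9))
  if (uninformative > 0) {
    ca_log("read_allele: %d SNPs have identical BAF in all clones (uninformative)",
           uninformative, verbose = verbose)
  }
  allele_data(bm, ref, tot, snp_ids = keep, clone_ids = clone_cols,
              cell_ids = cell_ids,
              chrom = if ("chrom" %in% meta_cols) baf$chrom else NULL,
              pos = if ("pos" %in% meta_cols) baf$pos else NULL)
}

#' Write allele data back to the two-table layout
#' @param allele an [allele_data()].
#' @param path_baf,path_counts output TSV paths.
#' @export
write_allele <- function(allele, path_baf, path_counts) {
  df <- data.frame(snp_id = rownames(allele$baf_clone), check.names = FALSE)
  if (!is.null(allele$chrom)) df$chrom <- allele$chrom
  if (!is.null(allele$pos)) df$pos <- allele$pos
  df <- cbind(df, as.data.frame(allele$baf_clone, check.names = FALSE))
  write_tsv_ca(df, path_baf)
  idx <- which(allele$total_counts > 0, arr.ind = TRUE)
  cnt <- data.frame(cell_id = rownames(allele$total_counts)[idx[, 1]],
                    snp_id = colnames(allele$total_counts)[idx[, 2]],
                    ref_count = allele$ref_counts[idx],
                    total_count = allele$total_counts[idx])
  write_tsv_ca(cnt, path_counts)
  invisible(path_baf)
}

#' Write fit results to a directory
#'
#' Emits the per-cell assignment table (label, max posterior and the full
#' posterior row), the per-gene dosage-probability table, the per-SNP allele
#' table (when SNPs were used), the ELBO trace as CSV, and a JSON metadata
#' record (seed, convergence, stop reasons for hierarchical results).
#'
#' @param fit a `fit_result` or `hierarchical_assignment`.
#' @param outdir output directory, created if missing.
#' @param metadata optional named list merged into the JSON record.
#' @return `outdir`, invisibly.
#' @export
write_results <- function(fit, outdir, metadata = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(fit, "hierarchical_assignment")) {
    write_tsv_ca(fit$cell_table, file.path(outdir, "assignment.tsv"))
    meta <- c(list(kind = "hierarchical", seed = fit$seed,
                   n_nodes = length(fit$nodes),
                   stop_reasons = lapply(fit$nodes, function(nd) nd$stop_reason)),
              metadata)
    jsonlite::write_json(meta, file.path(outdir, "run_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    node_tab <- do.call(rbind, lapply(fit$nodes, function(nd) {
      data.frame(node = nd$label, stop_reason = nd$stop_reason,
                 n_dna = nd$n_dna, n_rna = nd$n_rna, n_cscn = nd$n_cscn,
                 elbo = nd$elbo %||% NA_real_)
    }))
    write_tsv_ca(node_tab, file.path(outdir, "nodes.tsv"))
    return(invisible(outdir))
  }
  validate_fit_result(fit)
  post <- fit$clone_posterior
  ass <- data.frame(cell_id = rownames(post), label = fit$clone_label,
                    max_posterior = apply(post, 1L, max),
                    consistency = fit$consistency, check.names = FALSE)
  ass <- cbind(ass, as.data.frame(post, check.names = FALSE))
  write_tsv_ca(ass, file.path(outdir, "assignment.tsv"))
  write_tsv_ca(data.frame(gene_id = names(fit$p_k), p_k = fit$p_k,
                          mu0 = fit$mu0, mu1 = fit$mu1),
               file.path(outdir, "gene_dosage.tsv"))
  if (length(fit$p_a)) {
    write_tsv_ca(data.frame(snp_id = names(fit$p_a), p_a = fit$p_a),
                 file.path(outdir, "snp_allele.tsv"))
  }
  utils::write.csv(data.frame(iteration = seq_along(fit$elbo_trace),
                              elbo = fit$elbo_trace),
                   file.path(outdir, "elbo_trace.csv"), row.names = FALSE)
  meta <- c(list(kind = "flat", seed = fit$seed, converged = fit$converged,
                 n_iter = fit$n_iter,
                 clones = colnames(post)), metadata)
  jsonlite::write_json(meta, file.path(outdir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
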