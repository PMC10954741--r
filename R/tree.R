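## Recursive clade assignment: walk the scDNA phylogeny from the root,
## summarize each surviving child clade's copy number by the per-gene mode,
## fit the clone model over the children, label the RNA cells, and recurse
## into each child with its assigned cells until a stopping condition.

#' Recursion configuration
#'
#' Stopping defaults mirror the method's documented behaviour: recursion at
#' a node stops when fewer than `min_consistency_stop` (70%) of its cells
#' are consistently assigned between repeated runs, when fewer than
#' `min_cscn_genes` (100) genes have clone-specific copy number among the
#' children, or when fewer than `min_cells` (100) scDNA or scRNA cells
#' remain; child clades with fewer than `min_dna_subclade` (20) scDNA cells
#' are ignored altogether.
#'
#' @param min_consistency_stop node-level stop threshold on the fraction of
#'   consistently assigned cells.
#' @param min_cscn_genes minimum number of clone-differential genes.
#' @param min_cells minimum scDNA and scRNA cells at a node.
#' @param min_dna_subclade minimum scDNA cells for a child clade to enter
#'   the clone set.
#' @param max_depth recursion depth cap (default unlimited).
#' @param min_expr_frac expression-detection fraction for CSCN gene
#'   selection.
#' @param labeling a [labeling_config()].
#' @param inference an [inference_config()].
#' @return a `recursion_config` list.
#' @export
recursion_config <- function(min_consistency_stop = 0.7, min_cscn_genes = 100,
                             min_cells = 100, min_dna_subclade = 20,
                             max_depth = Inf, min_expr_frac = 0.01,
                             labeling = labeling_config(),
                             inference = inference_config()) {
  stopifnot(min_consistency_stop > 0, min_cscn_genes > 0, min_cells > 0,
            min_dna_subclade > 0)
  structure(list(min_consistency_stop = min_consistency_stop,
                 min_cscn_genes = min_cscn_genes, min_cells = min_cells,
                 min_dna_subclade = min_dna_subclade, max_depth = max_depth,
                 min_expr_frac = min_expr_frac, labeling = labeling,
                 inference = inference),
            class = "recursion_config")
}

tree_children <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}

## tip indices under a node (iterative preorder walk)
tree_tip_idx <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  stack <- node
  tips <- integer()
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    ch <- tree_children(tree, nd)
    tips <- c(tips, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  tips
}

tree_leaves <- function(tree, node) tree$tip.label[tree_tip_idx(tree, node)]

#' Deterministic clade names for a phylogeny
#'
#' Children of the root are named `A`, `B`, `C`, ... in left-to-right tree
#' order; deeper splits append `.1`, `.2`, ... so subclone labels read like
#' `B.1` or `D.4`.
#'
#' @param tree a rooted `phylo`.
#' @return named character vector mapping internal/tip node ids (as
#'   character) to labels; the root maps to `"root"`.
#' @export
name_clades <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  labels <- c(stats::setNames("root", root))
  walk <- function(node, label) {
    ch <- tree_children(tree, node)
    if (!length(ch)) return(invisible())
    nm <- if (node == root) LETTERS[seq_along(ch)] else paste0(label, ".", seq_along(ch))
    for (i in seq_along(ch)) {
      labels[as.character(ch[i])] <<- nm[i]
      walk(ch[i], nm[i])
    }
  }
  walk(root, "root")
  labels
}

## optional allele inputs for the recursion: per-scDNA-cell BAF plus scRNA
## SNP counts; clone-level BAF is recomputed for each node's children
build_node_allele <- function(allele_cells, clades, rna_cells, config) {
  if (is.null(allele_cells)) return(NULL)
  b <- clone_baf(allele_cells$cell_baf, clades, verbose = FALSE)
  if (nrow(b) == 0) return(NULL)
  snps <- rownames(b)
  ad <- allele_data(b, allele_cells$ref_counts[rna_cells, snps, drop = FALSE],
                    allele_cells$total_counts[rna_cells, snps, drop = FALSE],
                    chrom = if (!is.null(allele_cells$chrom)) {
                      allele_cells$chrom[match(snps, colnames(allele_cells$cell_baf))]
                    } else NULL)
  ad <- filter_snps(ad, verbose = FALSE)
  if (n_snps(ad) == 0) NULL else ad
}

#' Recursively assign expression profiles to phylogenetic clades
#'
#' Starting from the root, each node's surviving children (clades with at
#' least `min_dna_subclade` scDNA cells) define a clone set whose copy
#' number is the per-gene mode over the clade; cells are assigned by
#' [fit_clone_model()] with restarts, and the recursion descends into each
#' child with its assigned cells. Cells unassigned at a node keep the
#' parent-level label. Stop reasons are recorded per node.
#'
#' @param tree rooted `phylo` whose tip labels are scDNA cell identifiers.
#' @param cn a [cn_matrix()] over (at least) the tree's tips.
#' @param expr an [expression_matrix()] of the RNA cells to place.
#' @param allele optional list for the integrated model with elements
#'   `cell_baf` (scDNA cells x SNPs, may contain `NA`), `ref_counts` and
#'   `total_counts` (RNA cells x SNPs) and optionally `chrom`.
#' @param config a [recursion_config()].
#' @param verbose log progress.
#' @return a `hierarchical_assignment`: per-cell label paths (`labels`),
#'   a `cell_table` data frame, and per-node records (`nodes`) with stop
#'   reasons.
#' @export
recursive_assign <- function(tree, cn, expr, allele = NULL,
                             config = recursion_config(), verbose = TRUE) {
  stopifnot(inherits(cn, "cn_matrix"), inherits(expr, "expression_matrix"))
  missing <- setdiff(tree$tip.label, rownames(cn$cn))
  if (length(missing)) {
    stop_ca("%d tree leaves are absent from the CN matrix (e.g. %s)",
            length(missing), missing[1])
  }
  root <- ape::Ntip(tree) + 1L
  labels <- stats::setNames(rep("root", nrow(expr$counts)),
                            rownames(expr$counts))
  nodes <- list()

  visit <- function(node, node_label, rna_cells, depth) {
    dna_cells <- tree_leaves(tree, node)
    rec <- list(label = node_label, node = node, n_dna = length(dna_cells),
                n_rna = length(rna_cells), n_cscn = NA_integer_,
                stop_reason = NA_character_, elbo = NULL)
    ch <- tree_children(tree, node)
    child_cells <- lapply(ch, function(x) tree_leaves(tree, x))
    keep <- lengths(child_cells) >= config$min_dna_subclade
    ch <- ch[keep]; child_cells <- child_cells[keep]
    if (length(ch) < 2) {
      rec$stop_reason <- "leaf"
      nodes[[length(nodes) + 1L]] <<- rec
      return(invisible())
    }
    if (depth >= config$max_depth ||
        length(dna_cells) < config$min_cells ||
        length(rna_cells) < config$min_cells) {
      rec$stop_reason <- "too_few_cells"
      nodes[[length(nodes) + 1L]] <<- rec
      return(invisible())
    }
    child_labels <- if (node == root) {
      LETTERS[seq_along(ch)]
    } else paste0(node_label, ".", seq_along(ch))
    names(child_cells) <- child_labels
    prof_cn <- vapply(child_cells, function(cells) clade_cn_mode(cn, cells),
                      numeric(ncol(cn$cn)))
    profile <- clone_cn_profile(prof_cn, gene_ids = colnames(cn$cn),
                                clone_ids = child_labels)
    sub_expr <- expression_matrix(expr$counts[rna_cells, , drop = FALSE])
    cscn <- select_cscn_genes(profile, sub_expr,
                              min_expr_frac = config$min_expr_frac)
    rec$n_cscn <- length(cscn)
    if (length(cscn) < config$min_cscn_genes) {
      rec$stop_reason <- "too_few_cscn_genes"
      nodes[[length(nodes) + 1L]] <<- rec
      return(invisible())
    }
    node_expr <- expression_matrix(sub_expr$counts[, cscn, drop = FALSE])
    node_profile <- clone_cn_profile(profile$cn[cscn, , drop = FALSE])
    node_allele <- build_node_allele(allele, child_cells, rna_cells, config)
    infc <- config$inference
    infc$seed <- derive_seed(infc$seed, node)
    fit <- tryCatch(
      fit_clone_model(node_expr, node_profile, node_allele, infc,
                      labeling = config$labeling, verbose = FALSE),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rec$stop_reason <- "too_few_cscn_genes"
      nodes[[length(nodes) + 1L]] <<- rec
      return(invisible())
    }
    rec$elbo <- utils::tail(fit$elbo_trace, 1)
    consistent_frac <- mean(fit$consistency >= config$labeling$min_consistency)
    if (consistent_frac < config$min_consistency_stop) {
      rec$stop_reason <- "consistency_below_threshold"
      nodes[[length(nodes) + 1L]] <<- rec
      ca_log("node %s: only %.0f%% of cells consistently assigned; stopping",
             node_label, 100 * consistent_frac, verbose = verbose)
      return(invisible())
    }
    rec$stop_reason <- "split"
    nodes[[length(nodes) + 1L]] <<- rec
    assigned <- fit$clone_label
    for (i in seq_along(ch)) {
      cells_i <- names(assigned)[assigned == child_labels[i]]
      labels[cells_i] <<- child_labels[i]
      ca_log("node %s -> %s: %d cells", node_label, child_labels[i],
             length(cells_i), verbose = verbose)
      visit(ch[i], child_labels[i], cells_i, depth + 1)
    }
    invisible()
  }

  visit(root, "root", rownames(expr$counts), 0)
  cell_table <- data.frame(cell_id = names(labels), label = unname(labels),
                           stringsAsFactors = FALSE)
  structure(list(labels = labels, cell_table = cell_table, nodes = nodes,
                 seed = config$inference$seed),
            class = "hierarchical_assignment")
}

#' @export
print.hierarchical_assignment <- function(x, ...) {
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat(sprintf("<hierarchical_assignment> %d cells, %d visited nodes\n",
              length(x$labels), length(x$nodes)))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Number of resolved subclones in a hierarchical assignment
#'
#' Distinct terminal labels (excluding cells still at the root).
#' @param h a `hierarchical_assignment`.
#' @return integer count.
#' @export
n_subclones <- function(h) {
  length(setdiff(unique(h$labels), "root"))
}

#' Robustness of the recursion to phylogeny corruption
#'
#' For each shuffle fraction, randomly permutes the binding between that
#' share of scDNA cells and their CN profiles (making the tree a worse
#' description of the CN data), reruns the recursion, and reports the number
#' of resolved subclones and the agreement (ARI) with the unshuffled run.
#'
#' @param tree,cn,expr,allele,config as in [recursive_assign()].
#' @param shuffle_fracs fractions in `[0, 1]`.
#' @param seed seed for the shuffles.
#' @return data frame with columns `frac`, `n_subclones`, `agreement`,
#'   `unassigned_frac`.
#' @export
shuffle_robustness <- function(tree, cn, expr, allele = NULL,
                               shuffle_fracs = c(0, 0.2, 0.5, 1),
                               config = recursion_config(), seed = 1,
                               verbose = TRUE) {
  stopifnot(all(shuffle_fracs >= 0 & shuffle_fracs <= 1))
  base <- recursive_assign(tree, cn, expr, allele, config, verbose = FALSE)
  out <- lapply(shuffle_fracs, function(fr) {
    if (fr == 0) {
      h <- base
    } else {
      set.seed(derive_seed(seed, round(1000 * fr)))
      m <- round(fr * nrow(cn$cn))
      idx <- sample(nrow(cn$cn), m)
      perm <- sample(idx)
      cn2 <- cn$cn
      cn2[idx, ] <- cn2[perm, , drop = FALSE]
      h <- recursive_assign(tree, cn_matrix(cn2), expr, allele, config,
                            verbose = FALSE)
    }
    ca_log("shuffle %.0f%%: %d subclones", 100 * fr, n_subclones(h),
           verbose = verbose)
    data.frame(frac = fr, n_subclones = n_subclones(h),
               agreement = ari(h$labels, base$labels),
               unassigned_frac = mean(h$labels == "root"))
  })
  do.call(rbind, out)
}

#' Flat-mode assignment for predefined clone labels
#'
#' When clone labels (rather than a tree) are supplied, the recursion is
#' skipped and a single multiway fit is performed.
#'
#' @param cn a [cn_matrix()] of scDNA cells.
#' @param dna_labels named clone label per scDNA cell.
#' @param expr an [expression_matrix()].
#' @param allele optional [allele_data()].
#' @param config a [recursion_config()] (its `inference`/`labeling` parts
#'   are used).
#' @param verbose logging flag.
#' @return a `fit_result`.
#' @export
assign_to_clones <- function(cn, dna_labels, expr, allele = NULL,
                             config = recursion_config(), verbose = TRUE) {
  clades <- split(names(dna_labels), dna_labels)
  prof_cn <- vapply(clades, function(cells) clade_cn_mode(cn, cells),
                    numeric(ncol(cn$cn)))
  profile <- clone_cn_profile(prof_cn, gene_ids = colnames(cn$cn),
                              clone_ids = names(clades))
  cscn <- select_cscn_genes(profile, expr,
                            min_expr_frac = config$min_expr_frac)
  if (!length(cscn)) stop_ca("model not applicable: no CSCN genes")
  fit_clone_model(expression_matrix(expr$counts[, cscn, drop = FALSE]),
                  clone_cn_profile(profile$cn[cscn, , drop = FALSE]),
                  allele, config$inference, labeling = config$labeling,
                  verbose = verbose)
}
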