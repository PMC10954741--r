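## Recursion tests run on small simulated tree datasets with thresholds
## scaled to the data size (the thresholds themselves are configurable; the
## defaults are exercised in the acceptance suite).

small_tree_config <- function(seed = 91, ...) {
  recursion_config(min_cscn_genes = 10, min_cells = 20, min_dna_subclade = 5,
                   inference = fast_inference(seed, n_restarts = 2), ...)
}

test_that("clade naming is deterministic and dotted", {
  tr <- ape::read.tree(text = "(((a,b),(c,d)),(e,f));")
  labs <- name_clades(tr)
  root <- ape::Ntip(tr) + 1
  kids <- tr$edge[tr$edge[, 1] == root, 2]
  expect_equal(unname(labs[as.character(kids)]), c("A", "B"))
  grandkids <- tr$edge[tr$edge[, 1] == kids[1], 2]
  expect_equal(unname(labs[as.character(grandkids)]), c("A.1", "A.2"))
  tr2 <- ape::read.tree(text = "(a,b);")
  labs2 <- name_clades(tr2)
  expect_setequal(unname(labs2), c("root", "A", "B"))
})

test_that("recursion recovers simulated clades and refines label paths", {
  cfg <- sim_config(n_cells = 300, n_genes = 120, n_clones = 3,
                    frac_dosage = 0.9, n_dna_per_clone = 15,
                    cn_noise_rate = 0, depth_mean = 2000, depth_size = 10,
                    seed = 93)
  td <- simulate_tree_dataset(cfg)
  h <- recursive_assign(td$tree, td$cn, td$expr,
                        config = small_tree_config(93), verbose = FALSE)
  expect_s3_class(h, "hierarchical_assignment")
  expect_gte(n_subclones(h), 2)
  ## refinement: every cell labeled "X.y" was labeled "X" at the parent
  ## level, which the dotted-path construction guarantees; check the
  ## resolved labels agree with truth up to the hierarchy
  deep <- h$labels[grepl("\\.", h$labels)]
  if (length(deep)) {
    parents <- sub("\\.[0-9]+$", "", deep)
    expect_true(all(nchar(parents) < nchar(deep)))
  }
  ## clustering agreement with the true clones should be strong
  expect_gt(ari(h$labels, td$truth$z[names(h$labels)]), 0.6)
  ## determinism
  h2 <- recursive_assign(td$tree, td$cn, td$expr,
                         config = small_tree_config(93), verbose = FALSE)
  expect_identical(h$labels, h2$labels)
})

test_that("stopping conditions fire with the documented reasons", {
  cfg <- sim_config(n_cells = 120, n_genes = 60, n_clones = 2,
                    frac_dosage = 0.9, n_dna_per_clone = 12,
                    cn_noise_rate = 0, depth_mean = 1500, seed = 95)
  td <- simulate_tree_dataset(cfg)
  ## small subclades are ignored: with min_dna_subclade above the clade
  ## size, the root keeps fewer than 2 children and becomes a leaf
  h <- recursive_assign(td$tree, td$cn, td$expr,
                        config = recursion_config(
                          min_cscn_genes = 10, min_cells = 10,
                          min_dna_subclade = 50,
                          inference = fast_inference(95, 2)),
                        verbose = FALSE)
  expect_equal(h$nodes[[1]]$stop_reason, "leaf")
  expect_true(all(h$labels == "root"))
  ## too few CSCN genes at the root
  h2 <- recursive_assign(td$tree, td$cn, td$expr,
                         config = recursion_config(
                           min_cscn_genes = 1e4, min_cells = 10,
                           min_dna_subclade = 5,
                           inference = fast_inference(95, 2)),
                         verbose = FALSE)
  expect_equal(h2$nodes[[1]]$stop_reason, "too_few_cscn_genes")
  ## too few cells at the root
  h3 <- recursive_assign(td$tree, td$cn, td$expr,
                         config = recursion_config(
                           min_cscn_genes = 10, min_cells = 1e5,
                           min_dna_subclade = 5,
                           inference = fast_inference(95, 2)),
                         verbose = FALSE)
  expect_equal(h3$nodes[[1]]$stop_reason, "too_few_cells")
  ## an impossible consistency bar stops the recursion at the root
  h4 <- recursive_assign(td$tree, td$cn, td$expr,
                         config = recursion_config(
                           min_cscn_genes = 10, min_cells = 10,
                           min_dna_subclade = 5, min_consistency_stop = 1.01,
                           inference = fast_inference(95, 2)),
                         verbose = FALSE)
  expect_equal(h4$nodes[[1]]$stop_reason, "consistency_below_threshold")
})

test_that("flat star tree with clone-leaf clades equals a single fit", {
  cfg <- sim_config(n_cells = 150, n_genes = 80, n_clones = 2,
                    frac_dosage = 1, n_dna_per_clone = 10,
                    cn_noise_rate = 0, depth_mean = 1500, seed = 97)
  td <- simulate_tree_dataset(cfg)
  h <- recursive_assign(td$tree, td$cn, td$expr,
                        config = small_tree_config(97), verbose = FALSE)
  ## flat mode: single multiway fit against predefined labels
  flat <- assign_to_clones(td$cn, td$truth$dna_clone, td$expr,
                           config = small_tree_config(97), verbose = FALSE)
  ## both routes should agree with the truth for nearly all assigned cells
  expect_gte(clone_accuracy(flat$clone_label, td$truth$z,
                            exclude_unassigned = TRUE), 0.95)
  tree_lab <- h$labels
  names(td$truth$z) <- names(td$truth$z)
  expect_gt(ari(tree_lab, td$truth$z[names(tree_lab)]), 0.8)
})

test_that("shuffling the phylogeny degrades resolution monotonically-ish", {
  cfg <- sim_config(n_cells = 200, n_genes = 80, n_clones = 2,
                    frac_dosage = 1, n_dna_per_clone = 15,
                    cn_noise_rate = 0, depth_mean = 1500, seed = 99)
  td <- simulate_tree_dataset(cfg)
  rb <- shuffle_robustness(td$tree, td$cn, td$expr,
                           shuffle_fracs = c(0, 1),
                           config = small_tree_config(99), seed = 99,
                           verbose = FALSE)
  expect_equal(rb$n_subclones[1], 2)
  expect_equal(rb$agreement[1], 1)   # fraction 0 reproduces the base run
  ## full shuffle destroys the CN-clade correspondence: fewer subclones or
  ## a collapse toward unassigned/root
  expect_lte(rb$n_subclones[2], rb$n_subclones[1])
})
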