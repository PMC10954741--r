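## Shared fixture builders; everything is generated in code at test time.

tiny_expr <- function() {
  expression_matrix(matrix(c(5, 0, 1, 2, 0, 0), nrow = 3, byrow = TRUE,
                           dimnames = list(c("c1", "c2", "c3"),
                                           c("geneA", "geneB"))))
}

tiny_profile <- function(cn = matrix(c(2, 2, 2, 4), 2, 2,
                                     dimnames = list(c("geneA", "geneB"),
                                                     c("A", "B")))) {
  clone_cn_profile(cn)
}

## small but informative simulated dataset for fast inference tests
small_sim <- function(seed = 7, n_cells = 200, n_genes = 150,
                      frac_dosage = 1, n_clones = 2, ...) {
  simulate_expression(sim_config(n_cells = n_cells, n_genes = n_genes,
                                 n_clones = n_clones,
                                 frac_dosage = frac_dosage,
                                 depth_mean = 2000, depth_size = 10,
                                 seed = seed, ...))
}

fast_inference <- function(seed = 7, n_restarts = 2, ...) {
  inference_config(seed = seed, n_restarts = n_restarts,
                   max_iterations = 400, ...)
}

## flat Dirichlet draw for oracle tests
rdirichlet_unit <- function(C) {
  x <- rgamma(C, 1, 1)
  x / sum(x)
}
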