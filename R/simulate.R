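## Ground-truth simulator for the benchmark regimes: expression counts from
## the dosage generative model, allele counts from the allele model, and
## matched phylogeny / cell-level CN datasets for the recursive algorithm.

#' Simulation configuration
#'
#' Defaults reproduce the benchmark conditions: 3 clones, 1000 cells, 500
#' genes all located in clone-specific copy-number regions, 60% of genes
#' carrying a dosage effect, per-cell depth negative-binomial with mean
#' 5000, and sparse SNP coverage (Poisson mean 0.2 reads per SNP per cell).
#' Clone copy numbers are drawn per gene as a shared base (mostly 2--4) with
#' one clone deviating, giving the modest 1--2 copy subclonal differences
#' seen in real tumours; expression rates come from the model's own
#' softplus-normal family with a long-tailed spread of gene means, and the
#' per-cell noise factors follow the model priors. See the methods vignette
#' for how these magnitudes were chosen.
#'
#' @param n_cells,n_genes,n_clones problem dimensions.
#' @param frac_dosage fraction of genes with a true dosage effect.
#' @param n_snps number of heterozygous SNPs for the allele model (0 = no
#'   allele data).
#' @param depth_mean,depth_size negative-binomial parameters for per-cell
#'   depth \eqn{l_n}.
#' @param snp_depth_mean Poisson mean of per-SNP per-cell scRNA coverage.
#' @param noise_dim noise dimension D of the generative model.
#' @param mu0_loc,mu1_loc,mu_scale normal location/scale of the
#'   pre-softplus per-copy and base expression rates.
#' @param cn_base_levels,cn_base_probs distribution of the shared per-gene
#'   base copy number.
#' @param cn_step_probs probabilities of the deviating clone's offset being
#'   `+/-1` vs `+/-2`.
#' @param noise_scale multiplier on the per-gene noise loadings for the
#'   most lowly expressed genes (1 = the Gamma(2,1) precision prior as is).
#' @param noise_scale_high multiplier at the highly expressed end; per-gene
#'   multipliers interpolate linearly in expression rank between the two,
#'   reflecting the larger relative residual overdispersion of lowly
#'   expressed genes in scRNA data.
#' @param cn_noise_rate fraction of cell-level CN entries perturbed by
#'   `+/-1` in tree datasets.
#' @param n_dna_per_clone scDNA cells per clone leaf in tree datasets.
#' @param seed random seed; identical seeds give identical outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cells = 1000, n_genes = 500, n_clones = 3,
                       frac_dosage = 0.6, n_snps = 0,
                       depth_mean = 5000, depth_size = 0.5,
                       snp_depth_mean = 0.2, noise_dim = 1,
                       mu0_loc = -1, mu1_loc = 2, mu_scale = 2.5,
                       cn_base_levels = c(2, 3, 4),
                       cn_base_probs = c(0.5, 0.3, 0.2),
                       cn_step_probs = c(0.6, 0.4),
                       noise_scale = 1, noise_scale_high = noise_scale,
                       cn_noise_rate = 0.01, n_dna_per_clone = 100,
                       seed = 1L) {
  stopifnot(frac_dosage >= 0, frac_dosage <= 1, n_clones >= 2)
  structure(as.list(environment()), class = "sim_config")
}

## gene x clone copy numbers: shared base, one clone deviates per gene
sample_clone_cn <- function(config) {
  G <- config$n_genes; C <- config$n_clones
  base <- sample(config$cn_base_levels, G, replace = TRUE,
                 prob = config$cn_base_probs)
  cn <- matrix(rep(base, C), G, C)
  dev_clone <- sample.int(C, G, replace = TRUE)
  step <- sample(c(1, 2), G, replace = TRUE, prob = config$cn_step_probs) *
    sample(c(-1, 1), G, replace = TRUE)
  cn[cbind(seq_len(G), dev_clone)] <- pmin(pmax(base + step, 0), 8)
  dimnames(cn) <- list(paste0("gene", seq_len(G)), LETTERS[seq_len(C)])
  cn
}

#' Simulate expression data with known ground truth
#'
#' Draws clone assignments uniformly, marks a `frac_dosage` share of genes
#' as dosage genes, samples expression rates and noise factors from the
#' model priors, and emits per-cell counts
#' \eqn{X_n \sim \mathrm{Multinomial}(l_n, Y_n)} with the expected profile
#' of the assigned clone.
#'
#' @param config a [sim_config()].
#' @param profile optional [clone_cn_profile()] to use instead of sampling
#'   one.
#' @return list with `expr` ([expression_matrix()]), `profile`
#'   ([clone_cn_profile()]) and `truth` (clone labels `z`, dosage indicator
#'   `k`, and all generative parameters).
#' @export
simulate_expression <- function(config = sim_config(), profile = NULL) {
  set.seed(config$seed)
  N <- config$n_cells; G <- config$n_genes; C <- config$n_clones; D <- config$noise_dim
  if (is.null(profile)) {
    profile <- clone_cn_profile(sample_clone_cn(config))
  } else {
    G <- nrow(profile$cn); C <- ncol(profile$cn)
  }
  genes <- rownames(profile$cn); clones <- colnames(profile$cn)
  z <- sample.int(C, N, replace = TRUE)
  k <- numeric(G)
  k[sample.int(G, round(config$frac_dosage * G))] <- 1
  mu0 <- softplus(stats::rnorm(G, config$mu0_loc, config$mu_scale))
  mu1 <- softplus(stats::rnorm(G, config$mu1_loc, config$mu_scale))
  if (D > 0) {
    chi <- stats::rgamma(D, shape = 2, rate = 1)
    ## per-gene noise multiplier: interpolate in expression rank from
    ## noise_scale (lowest expression) to noise_scale_high (highest)
    level <- mu0 * mean(profile$cn) * k + mu1 * (1 - k)
    rank_frac <- (rank(level, ties.method = "first") - 1) / max(G - 1, 1)
    s_g <- config$noise_scale +
      (config$noise_scale_high - config$noise_scale) * rank_frac
    w <- matrix(stats::rnorm(G * D, 0, rep(s_g, D) / sqrt(rep(chi, each = G))),
                G, D)
    psi <- matrix(stats::rnorm(N * D), N, D)
    eta <- psi %*% t(w)
  } else {
    chi <- numeric(); w <- matrix(0, G, 0); psi <- matrix(0, N, 0)
    eta <- matrix(0, N, G)
  }
  l <- stats::rnbinom(N, mu = config$depth_mean, size = config$depth_size)
  base <- mu0 * k              # per-copy part, to be scaled by lambda
  flat <- mu1 * (1 - k)
  X <- matrix(0L, N, G, dimnames = list(paste0("cell", seq_len(N)), genes))
  for (n in seq_len(N)) {
    num <- (base * profile$cn[, z[n]] + flat) * exp(eta[n, ])
    X[n, ] <- stats::rmultinom(1, l[n], num / sum(num))
  }
  truth <- list(z = stats::setNames(clones[z], rownames(X)),
                k = stats::setNames(k, genes),
                mu0 = mu0, mu1 = mu1, psi = psi, w = w, chi = chi, l = l)
  list(expr = expression_matrix(X), profile = profile, truth = truth)
}

#' Simulate allele-specific counts with known ground truth
#'
#' SNP allele indicators are Bernoulli(0.5); clone BAFs are drawn per SNP
#' from allelic-imbalance levels `{0, 1/3, 1/2, 2/3, 1}` with at least two
#' clones differing; per-cell coverage is Poisson and reference counts are
#' binomial with the expected reference fraction of the cell's true clone.
#'
#' @param config a [sim_config()] (`n_snps`, `snp_depth_mean` are used).
#' @param truth_z named clone labels per RNA cell (from
#'   [simulate_expression()]).
#' @param clone_ids clone identifiers (default: levels seen in `truth_z`).
#' @return list with `allele` ([allele_data()]) and `truth` (the allele
#'   indicator `a` per SNP and the BAF matrix).
#' @export
simulate_allele <- function(config, truth_z, clone_ids = NULL) {
  set.seed(derive_seed(config$seed, 17))
  S <- config$n_snps
  if (is.null(clone_ids)) clone_ids <- sort(unique(truth_z))
  C <- length(clone_ids); N <- length(truth_z)
  cells <- names(truth_z) %||% paste0("cell", seq_len(N))
  if (S == 0) {
    return(list(allele = empty_allele_data(cells, clone_ids),
                truth = list(a = numeric(), baf = NULL)))
  }
  levels <- c(0, 1 / 3, 0.5, 2 / 3, 1)
  b <- matrix(sample(levels, S * C, replace = TRUE), S, C)
  flat <- apply(b, 1L, function(r) max(r) - min(r) < 1e-9)
  while (any(flat)) {
    b[flat, ] <- sample(levels, sum(flat) * C, replace = TRUE)
    flat <- apply(b, 1L, function(r) max(r) - min(r) < 1e-9)
  }
  dimnames(b) <- list(paste0("snp", seq_len(S)), clone_ids)
  a <- stats::rbinom(S, 1, 0.5)
  zi <- match(truth_z, clone_ids)
  tot <- matrix(stats::rpois(N * S, config$snp_depth_mean), N, S,
                dimnames = list(cells, rownames(b)))
  f <- expected_ref_fraction(a, b)      # S x C
  fmat <- t(f)[zi, , drop = FALSE]      # N x S
  ref <- matrix(stats::rbinom(N * S, as.vector(tot), as.vector(fmat)), N, S,
                dimnames = dimnames(tot))
  list(allele = allele_data(b, ref, tot),
       truth = list(a = stats::setNames(a, rownames(b)), baf = b))
}

#' Simulate a phylogeny-structured dataset
#'
#' Builds a random rooted clone tree, expands each clone leaf into a clade
#' of scDNA cells, perturbs a small fraction of cell-level copy-number
#' entries by one copy, and emits matched expression data from the same
#' clone profile.
#'
#' @param config a [sim_config()].
#' @return list with `tree` (phylo over scDNA cells), `cn`
#'   ([cn_matrix()]), `expr`, `profile`, `truth` (including the scDNA
#'   cell-to-clone map `dna_clone`).
#' @export
simulate_tree_dataset <- function(config = sim_config()) {
  set.seed(derive_seed(config$seed, 29))
  C <- config$n_clones
  clone_ids <- LETTERS[seq_len(C)]
  clone_tree <- ape::rtree(C, tip.label = clone_ids)
  ## expand each clone tip into a polytomy of its scDNA cells
  nwk <- ape::write.tree(clone_tree)
  dna_cells <- lapply(clone_ids, function(cl) {
    paste0("dna_", cl, "_", seq_len(config$n_dna_per_clone))
  })
  names(dna_cells) <- clone_ids
  for (cl in clone_ids) {
    nwk <- sub(paste0(cl, ":"),
               paste0("(", paste(dna_cells[[cl]], collapse = ","), "):"),
               nwk, fixed = TRUE)
  }
  tree <- ape::read.tree(text = nwk)
  sim <- simulate_expression(config)
  profile <- sim$profile
  ## cell-level CN: clone profile plus sparse +/-1 noise
  all_dna <- unlist(dna_cells)
  dna_clone <- rep(clone_ids, vapply(dna_cells, length, integer(1)))
  cn <- t(profile$cn)[dna_clone, , drop = FALSE]
  cn <- round(cn)
  if (config$cn_noise_rate > 0) {
    flip <- which(stats::runif(length(cn)) < config$cn_noise_rate)
    cn[flip] <- pmax(cn[flip] + sample(c(-1, 1), length(flip), replace = TRUE), 0)
  }
  rownames(cn) <- all_dna
  truth <- sim$truth
  truth$dna_clone <- stats::setNames(dna_clone, all_dna)
  list(tree = tree, cn = cn_matrix(cn), expr = sim$expr, profile = profile,
       truth = truth)
}
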