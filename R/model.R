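## Generative-model kernels: the expected-expression map, the expected
## reference-allele fraction, the full joint log-density (used in tests and
## by the simulator), and parameter initialization.

## numerical floors shared across the package
PROB_FLOOR <- 1e-12      # multinomial probabilities clamped before log
BAF_FLOOR <- 1e-6        # binomial success fraction clamped to [f, 1 - f]
MEAN_EPS <- 1e-4         # softplus-inverse clamp for zero-mean genes

#' Default model hyperparameters
#'
#' @param G,N,S,C,D problem dimensions (genes, cells, SNPs, clones, noise
#'   dimensions).
#' @param mu_prime per-gene prior location for the softplus-normal expression
#'   prior (defaults to 0).
#' @param mu_prior_sd prior standard deviation of the pre-softplus expression
#'   parameters (default 10, a weak prior).
#' @param alpha Dirichlet concentration for clone proportions (default 1).
#' @param beta1,beta2 Beta hyperparameters for the per-gene dosage
#'   probability (default 1, 1).
#' @param beta1p,beta2p Beta hyperparameters for the per-SNP allele
#'   probability (default 1, 1).
#' @return a named list of hyperparameters.
#' @export
model_hyperparams <- function(G, N, S = 0, C = 2, D = 1,
                              mu_prime = rep(0, G), mu_prior_sd = 10,
                              alpha = 1, beta1 = 1, beta2 = 1,
                              beta1p = 1, beta2p = 1) {
  list(G = G, N = N, S = S, C = C, D = D, mu_prime = mu_prime,
       mu_prior_sd = mu_prior_sd, alpha = alpha, beta1 = beta1, beta2 = beta2,
       beta1p = beta1p, beta2p = beta2p)
}

#' Expected expression under the dosage model
#'
#' Computes the expected per-gene read counts for one cell assigned to a
#' given clone:
#' \deqn{y_{ng} = l_n \frac{[\mu_{g0}\lambda_{gc}k_g + \mu_{g1}(1-k_g)]
#'   e^{\psi_n \cdot w_g}}{\sum_{g'} [\ldots]}}
#' so the expected counts always sum to the cell's depth \eqn{l_n}, and are
#' invariant to jointly rescaling \eqn{(\mu_0, \mu_1)}.
#'
#' @param mu0 per-copy expression rates (positive, length G).
#' @param mu1 copy-number-independent base rates (positive, length G).
#' @param k per-gene dosage indicators in `[0, 1]` (0/1, or the marginal
#'   probability when the indicator is averaged out).
#' @param profile a [clone_cn_profile()].
#' @param clone clone identifier (a column of the profile).
#' @param cell_total the cell's depth \eqn{l_n}.
#' @param cell_psi the cell's noise factors (length D), or `NULL` for no
#'   noise term.
#' @param w G x D matrix of gene noise loadings (ignored when `cell_psi` is
#'   `NULL`).
#' @return named vector of expected counts, summing to `cell_total`.
#' @export
expected_expression <- function(mu0, mu1, k, profile, clone, cell_total,
                                cell_psi = NULL, w = NULL) {
  lam <- profile$cn[, as.character(clone)]
  stopifnot(length(mu0) == length(lam), length(mu1) == length(lam),
            all(mu0 > 0), all(mu1 > 0))
  num <- (mu0 * lam * k + mu1 * (1 - k))
  if (!is.null(cell_psi) && length(cell_psi) > 0) {
    stopifnot(!is.null(w))
    num <- num * exp(drop(as.matrix(w) %*% cell_psi))
  }
  tot <- sum(num)
  if (tot <= 0) stop_ca("expected expression has all-zero numerator")
  stats::setNames(cell_total * num / tot, rownames(profile$cn))
}

#' Expected reference-allele fraction
#'
#' \eqn{f_{ns} = a_s b_{sc} + (1 - a_s)(1 - b_{sc})}: if the scRNA reference
#' allele is the B haplotype (`a = 1`) the expected reference fraction equals
#' the clone BAF, otherwise its complement. Satisfies the relabeling symmetry
#' `f(a, b) = f(1 - a, 1 - b)`.
#'
#' @param a allele indicator(s) in `[0, 1]`.
#' @param b clone BAF(s) in `[0, 1]`.
#' @return expected reference fraction(s) in `[0, 1]`.
#' @export
expected_ref_fraction <- function(a, b) {
  stopifnot(all(b >= 0 & b <= 1))
  a * b + (1 - a) * (1 - b)
}

#' Initialize the pre-softplus expression locations
#'
#' Sets the per-gene prior location \eqn{\mu'_g} to the softplus-inverse of
#' the mean read count of the gene across cells, clamped below at
#' `1e-4` so genes with zero observed counts remain finite.
#'
#' @param expr an [expression_matrix()].
#' @return named numeric vector of length G.
#' @export
init_mu_prime <- function(expr) {
  m <- colMeans(expr$counts)
  softplus_inv(pmax(m, MEAN_EPS))
}

#' Joint log-density of the generative model
#'
#' Evaluates the full joint log-density at given values of the discrete
#' latents (clone assignments `z`, dosage indicators `k`, allele indicators
#' `a`) and continuous parameters: Dirichlet prior on clone proportions,
#' categorical assignments, Beta/Bernoulli terms for `k` and `a`,
#' softplus-normal priors on the expression rates, normal/ARD priors on the
#' noise factors, the multinomial likelihood of the counts and (when SNPs
#' are present) the binomial likelihood of the reference-allele counts.
#' Useful as a transparent reference for testing and simulation.
#'
#' @param expr an [expression_matrix()].
#' @param profile a [clone_cn_profile()] (genes must match `expr`).
#' @param params named list with elements `mu0`, `mu1`, `pi`, `p_k` and
#'   optionally `psi` (N x D), `w` (G x D), `chi` (D), `p_a` (S).
#' @param z integer or character clone assignment per cell.
#' @param k 0/1 vector of dosage indicators per gene.
#' @param a 0/1 vector of allele indicators per SNP (when `allele` given).
#' @param allele optional [allele_data()]; `NULL` or zero SNPs reduces the
#'   density to the total-copy-number model.
#' @param hyper hyperparameters from [model_hyperparams()] (defaults built
#'   from the data dimensions).
#' @return scalar log-density.
#' @export
joint_log_density <- function(expr, profile, params, z, k, a = NULL,
                              allele = NULL, hyper = NULL) {
  X <- expr$counts
  N <- nrow(X); G <- ncol(X); C <- ncol(profile$cn)
  S <- n_snps(allele)
  D <- if (is.null(params$psi)) 0L else ncol(as.matrix(params$psi))
  if (is.null(hyper)) {
    hyper <- model_hyperparams(G, N, S, C, D, mu_prime = init_mu_prime(expr))
  }
  if (is.character(z)) z <- match(z, colnames(profile$cn))
  stopifnot(length(z) == N, length(k) == G, all(k %in% c(0, 1)))

  terms <- list()
  pi <- params$pi
  terms$dirichlet_pi <- lgamma(C * hyper$alpha) - C * lgamma(hyper$alpha) +
    sum((hyper$alpha - 1) * log(pi))
  terms$categorical_z <- sum(log(pi[z]))
  terms$beta_pk <- sum(stats::dbeta(params$p_k, hyper$beta1, hyper$beta2,
                                    log = TRUE))
  terms$bernoulli_k <- sum(k * log(params$p_k) + (1 - k) * log1p(-params$p_k))
  m0 <- softplus_inv(params$mu0); m1 <- softplus_inv(params$mu1)
  ## softplus-normal prior density on mu includes the change-of-variables
  ## Jacobian |dm/dmu| = 1 / sigmoid(m)
  terms$prior_mu <- sum(stats::dnorm(m0, hyper$mu_prime, hyper$mu_prior_sd,
                                     log = TRUE) - log(sigmoid(m0))) +
    sum(stats::dnorm(m1, hyper$mu_prime, hyper$mu_prior_sd, log = TRUE) -
          log(sigmoid(m1)))
  if (D > 0) {
    psi <- as.matrix(params$psi); w <- as.matrix(params$w)
    chi <- params$chi
    terms$prior_psi <- sum(stats::dnorm(psi, 0, 1, log = TRUE))
    terms$prior_w <- sum(stats::dnorm(w, 0,
                                      rep(1 / sqrt(chi), each = nrow(w)),
                                      log = TRUE))
    terms$prior_chi <- sum(stats::dgamma(chi, shape = 2, rate = 1, log = TRUE))
  }
  ## multinomial likelihood
  ll <- 0
  for (n in seq_len(N)) {
    y <- expected_expression(params$mu0, params$mu1, k, profile,
                             colnames(profile$cn)[z[n]], 1,
                             cell_psi = if (D > 0) psi[n, ] else NULL,
                             w = if (D > 0) w else NULL)
    p <- pmax(y, PROB_FLOOR)
    ln <- expr$cell_totals[n]
    ll <- ll + lgamma(ln + 1) - sum(lgamma(X[n, ] + 1)) + sum(X[n, ] * log(p))
  }
  terms$multinomial_x <- ll
  if (S > 0) {
    stopifnot(length(a) == S, all(a %in% c(0, 1)))
    terms$beta_pa <- sum(stats::dbeta(params$p_a, hyper$beta1p, hyper$beta2p,
                                      log = TRUE))
    terms$bernoulli_a <- sum(a * log(params$p_a) +
                               (1 - a) * log1p(-params$p_a))
    f <- expected_ref_fraction(a, allele$baf_clone)        # S x C
    f <- pmin(pmax(f, BAF_FLOOR), 1 - BAF_FLOOR)
    lb <- 0
    for (n in seq_len(N)) {
      fn <- f[, z[n]]
      t_ns <- allele$total_counts[n, ]; r_ns <- allele$ref_counts[n, ]
      lb <- lb + sum(stats::dbinom(r_ns, t_ns, fn, log = TRUE))
    }
    terms$binomial_r <- lb
  }
  bad <- names(terms)[!vapply(terms, is.finite, logical(1))]
  if (length(bad)) {
    stop_ca("non-finite log-density contribution from term(s): %s",
            paste(bad, collapse = ", "))
  }
  sum(unlist(terms))
}
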