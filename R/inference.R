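## Model fitting: stochastic-gradient MAP with the clone assignment
## marginalized exactly, Adam optimizer (learning rate 0.1), ELBO-based
## convergence, and multiple restarts for consistency assessment.

#' Inference configuration
#'
#' @param learning_rate Adam learning rate (default 0.1).
#' @param rel_elbo_tol convergence tolerance on the relative ELBO change
#'   (default 1e-5), averaged over `elbo_window` iterations.
#' @param max_iterations iteration cap (default 1000).
#' @param n_restarts number of independently initialized runs (default 5);
#'   restart `i` uses `seed + i`.
#' @param seed base random seed.
#' @param elbo_window window (iterations) for the relative-change check.
#' @param model_variant `"total_cn"`, `"allele"` or `"integrated"`.
#' @param noise_dim dimension D of the per-cell noise factors (0 disables
#'   the noise term; default 1).
#' @param mu_prior_sd prior standard deviation for the pre-softplus
#'   expression parameters (default 10).
#' @param init_jitter_sd standard deviation of the random jitter applied to
#'   the initial parameter values so restarts explore distinct modes.
#' @return an `inference_config` list.
#' @export
inference_config <- function(learning_rate = 0.1, rel_elbo_tol = 1e-5,
                             max_iterations = 1000, n_restarts = 5,
                             seed = 1L, elbo_window = 10,
                             model_variant = c("integrated", "total_cn", "allele"),
                             noise_dim = 1, mu_prior_sd = 10,
                             init_jitter_sd = 0.1) {
  stopifnot(learning_rate > 0, rel_elbo_tol > 0, n_restarts >= 1,
            max_iterations >= 1, noise_dim >= 0)
  structure(list(learning_rate = learning_rate, rel_elbo_tol = rel_elbo_tol,
                 max_iterations = max_iterations, n_restarts = n_restarts,
                 seed = as.integer(seed), elbo_window = elbo_window,
                 model_variant = match.arg(model_variant),
                 noise_dim = as.integer(noise_dim),
                 mu_prior_sd = mu_prior_sd,
                 init_jitter_sd = init_jitter_sd),
            class = "inference_config")
}

## assemble the data matrices handed to the C++ core, aligning genes between
## expression and the clone profile (exact string match; mismatches dropped)
build_model_data <- function(expr, profile, allele, variant, verbose = TRUE) {
  use_expr <- variant %in% c("total_cn", "integrated") && !is.null(expr)
  use_allele <- variant %in% c("allele", "integrated") && n_snps(allele) > 0
  if (!use_expr && !use_allele) {
    stop_ca("model not applicable: no expression genes and no informative SNPs")
  }
  if (use_expr) {
    genes <- intersect(colnames(expr$counts), rownames(profile$cn))
    dropped <- length(union(colnames(expr$counts), rownames(profile$cn))) -
      length(genes)
    if (dropped > 0) {
      ca_log("gene matching: dropped %d genes absent from one modality",
             dropped, verbose = verbose)
    }
    if (length(genes) == 0) stop_ca("model not applicable: no shared genes")
    X <- expr$counts[, genes, drop = FALSE]
    lambda <- profile$cn[genes, , drop = FALSE]
    if (length(cscn_genes(clone_cn_profile(lambda))) == 0) {
      stop_ca("model not applicable: clone profiles are identical across clones")
    }
    cells <- rownames(X)
  } else {
    X <- matrix(0, nrow(allele$ref_counts), 0)
    lambda <- matrix(0, 0, ncol(profile$cn),
                     dimnames = list(NULL, colnames(profile$cn)))
    cells <- rownames(allele$ref_counts)
  }
  if (use_allele) {
    stopifnot(identical(colnames(allele$baf_clone), colnames(profile$cn)))
    Rr <- allele$ref_counts[cells, , drop = FALSE]
    Tt <- allele$total_counts[cells, , drop = FALSE]
    B <- allele$baf_clone
  } else {
    Rr <- matrix(0, length(cells), 0)
    Tt <- matrix(0, length(cells), 0)
    B <- matrix(0, 0, ncol(profile$cn))
  }
  list(X = X, l = rowSums(X), lambda = lambda, Rr = Rr, Tt = Tt, B = B,
       cells = cells, genes = colnames(X), snps = colnames(Rr),
       clones = colnames(profile$cn), use_expr = use_expr,
       use_allele = use_allele)
}

## parameter vector layout for one model instance
param_layout <- function(dat, D, fix_k) {
  G <- ncol(dat$X); N <- length(dat$cells); C <- length(dat$clones)
  S <- ncol(dat$Rr)
  if (!dat$use_expr) { G <- 0; D <- 0 }
  blocks <- list()
  if (G > 0) {
    blocks$m0 <- G; blocks$m1 <- G
    if (!fix_k) blocks$kappa <- G
  }
  blocks$rho <- C
  if (G > 0 && D > 0) {
    blocks$psi <- N * D; blocks$w <- G * D; blocks$cchi <- D
  }
  if (S > 0) blocks$xa <- S
  sizes <- unlist(blocks)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  list(starts = starts, ends = ends, total = sum(sizes), D = D,
       G = G, N = N, C = C, S = S, fix_k = fix_k)
}

init_params <- function(dat, layout, mu_prime, jitter_sd) {
  par <- numeric(layout$total)
  g <- function(nm) if (nm %in% names(layout$starts)) layout$starts[[nm]]:layout$ends[[nm]] else integer()
  if (layout$G > 0) {
    ## per-copy rate starts at mean count / mean copy number so that
    ## mu0 * lambda matches the observed scale from the first iteration
    mean_cn <- rowMeans(dat$lambda)
    m0_init <- softplus_inv(pmax(softplus(mu_prime) / pmax(mean_cn, 0.1),
                                 MEAN_EPS))
    par[g("m0")] <- m0_init + stats::rnorm(layout$G, 0, jitter_sd / 10)
    par[g("m1")] <- mu_prime + stats::rnorm(layout$G, 0, jitter_sd / 10)
    if (!layout$fix_k) par[g("kappa")] <- stats::rnorm(layout$G, 0, jitter_sd / 10)
  }
  par[g("rho")] <- stats::rnorm(layout$C, 0, jitter_sd / 10)
  if (layout$D > 0) {
    par[g("psi")] <- stats::rnorm(layout$N * layout$D, 0, jitter_sd)
    par[g("w")] <- stats::rnorm(layout$G * layout$D, 0, jitter_sd)
    par[g("cchi")] <- 0
  }
  if (layout$S > 0) par[g("xa")] <- stats::rnorm(layout$S, 0, jitter_sd / 10)
  par
}

## data-dependent constants of the likelihood (multinomial and binomial
## normalization); added to the objective so the ELBO trace is the actual
## log joint and the relative-change convergence rule sees the true scale
data_const <- function(dat) {
  const <- 0
  if (dat$use_expr) {
    const <- const + sum(lgamma(dat$l + 1)) - sum(lgamma(dat$X + 1))
  }
  if (dat$use_allele) {
    const <- const + sum(lchoose(dat$Tt, dat$Rr))
  }
  const
}

## single optimization run (Adam, full-batch gradients)
run_map <- function(dat, config, mu_prime, fix_k, seed) {
  set.seed(seed)
  const <- data_const(dat)
  layout <- param_layout(dat, config$noise_dim, fix_k)
  par <- init_params(dat, layout, mu_prime, config$init_jitter_sd)
  lr <- config$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m <- v <- numeric(length(par))
  elbo <- numeric(0)
  converged <- FALSE
  win <- config$elbo_window
  for (it in seq_len(config$max_iterations)) {
    res <- core_obj_grad(par, dat$X, dat$l, dat$lambda, dat$Rr, dat$Tt, dat$B,
                         mu_prime, config$mu_prior_sd, layout$D, fix_k,
                         TRUE, FALSE)
    if (!is.finite(res$objective)) {
      stop_ca("non-finite ELBO at iteration %d (seed %d)", it, seed)
    }
    elbo[it] <- res$objective + const
    g <- res$gradient
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^it)
    vhat <- v / (1 - b2^it)
    par <- par + lr * mhat / (sqrt(vhat) + eps)
    if (it > win) {
      recent <- elbo[(it - win):it]
      rel <- mean(abs(diff(recent))) / max(abs(elbo[it]), 1e-12)
      if (rel < config$rel_elbo_tol) { converged <- TRUE; break }
    }
  }
  fin <- core_obj_grad(par, dat$X, dat$l, dat$lambda, dat$Rr, dat$Tt, dat$B,
                       mu_prime, config$mu_prior_sd, layout$D, fix_k,
                       FALSE, TRUE)
  list(par = par, layout = layout, elbo = elbo, converged = converged,
       q = fin$q, objective = fin$objective + const, seed = seed)
}

unpack_params <- function(par, layout, dat, mu_prime) {
  g <- function(nm) if (nm %in% names(layout$starts)) par[layout$starts[[nm]]:layout$ends[[nm]]] else numeric()
  out <- list()
  if (layout$G > 0) {
    out$mu0 <- stats::setNames(softplus(g("m0")), dat$genes)
    out$mu1 <- stats::setNames(softplus(g("m1")), dat$genes)
    out$p_k <- if (layout$fix_k) {
      stats::setNames(rep(1, layout$G), dat$genes)
    } else stats::setNames(sigmoid(g("kappa")), dat$genes)
  } else {
    out$mu0 <- out$mu1 <- numeric()
    out$p_k <- numeric()
  }
  rho <- g("rho")
  out$pi <- stats::setNames(exp(rho - max(rho)) / sum(exp(rho - max(rho))),
                            dat$clones)
  if (layout$D > 0) {
    out$psi <- matrix(g("psi"), layout$N, layout$D,
                      dimnames = list(dat$cells, NULL))
    out$w <- matrix(g("w"), layout$G, layout$D,
                    dimnames = list(dat$genes, NULL))
    out$chi <- exp(g("cchi"))
  } else {
    out$psi <- matrix(0, layout$N, 0); out$w <- matrix(0, layout$G, 0)
    out$chi <- numeric()
  }
  out$p_a <- if (layout$S > 0) stats::setNames(sigmoid(g("xa")), dat$snps) else numeric()
  out
}

#' Fit the clone-assignment model
#'
#' Maximizes the marginal MAP objective (clone assignments summed out
#' exactly per cell; dosage and allele indicators handled through their
#' Bernoulli probabilities) with Adam at the configured learning rate, over
#' `n_restarts` independently initialized runs. The run with the best final
#' objective supplies the parameter estimates; agreement of the per-cell
#' argmax assignment across restarts gives the consistency fraction used for
#' labeling.
#'
#' @param expr an [expression_matrix()] (or `NULL` for the allele-only
#'   variant).
#' @param profile a [clone_cn_profile()] with at least two clones and at
#'   least one clone-differential gene.
#' @param allele optional [allele_data()]; zero SNPs reduces the integrated
#'   model to the total-CN model.
#' @param config an [inference_config()].
#' @param labeling a [labeling_config()] for the final per-cell labels.
#' @param verbose log progress.
#' @return a `fit_result` (see package overview) with the posterior clone
#'   assignment matrix, labels, per-gene `p_k`, per-SNP `p_a`, point
#'   estimates of all continuous parameters, the ELBO trace of the best
#'   restart, and the per-restart label matrix.
#' @export
fit_clone_model <- function(expr, profile, allele = NULL,
                            config = inference_config(),
                            labeling = labeling_config(), verbose = TRUE) {
  variant <- config$model_variant
  dat <- build_model_data(expr, profile, allele, variant, verbose = verbose)
  mu_prime <- if (dat$use_expr) {
    init_mu_prime(expression_matrix(dat$X))
  } else numeric()
  runs <- vector("list", config$n_restarts)
  for (i in seq_len(config$n_restarts)) {
    runs[[i]] <- run_map(dat, config, mu_prime, fix_k = FALSE,
                         seed = config$seed + i)
    ca_log("restart %d/%d: ELBO %.2f after %d iterations%s", i,
           config$n_restarts, utils::tail(runs[[i]]$elbo, 1),
           length(runs[[i]]$elbo),
           if (runs[[i]]$converged) "" else " (no convergence)",
           verbose = verbose)
  }
  finalize_fit(runs, dat, config, labeling, mu_prime, fix_k = FALSE)
}

finalize_fit <- function(runs, dat, config, labeling, mu_prime, fix_k,
                         baseline_r = NULL) {
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "objective"))]]
  pars <- unpack_params(best$par, best$layout, dat, mu_prime)
  q <- best$q
  dimnames(q) <- list(dat$cells, dat$clones)
  restart_labels <- vapply(runs, function(r) {
    dat$clones[max.col(r$q, ties.method = "first")]
  }, character(length(dat$cells)))
  restart_labels <- matrix(restart_labels, nrow = length(dat$cells),
                           dimnames = list(dat$cells, NULL))
  cons <- restart_consensus(restart_labels)
  labels <- assign_labels(q, cons$consistency, labeling)
  new_fit_result(clone_posterior = q, clone_label = labels,
                 consistency = cons$consistency,
                 p_k = pars$p_k, p_a = pars$p_a, mu0 = pars$mu0,
                 mu1 = pars$mu1, pi = pars$pi, psi = pars$psi, w = pars$w,
                 chi = pars$chi, elbo_trace = best$elbo,
                 converged = best$converged, seed = config$seed,
                 n_iter = length(best$elbo), baseline_r = baseline_r,
                 restart_labels = restart_labels)
}

#' Fit the dosage-only baseline (k fixed to 1 for every gene)
#'
#' The baseline assumes every gene follows its copy number, i.e. the model
#' with the per-gene dosage indicator pinned at 1 — the assumption made by
#' earlier clone-mapping methods. Additionally reports, per gene, the
#' Pearson correlation between normalized counts and the assigned clone's
#' copy number, a simple score for dosage effects.
#'
#' @inheritParams fit_clone_model
#' @return a `fit_result`; `baseline_r` holds the per-gene correlation and
#'   labels are the plain argmax assignment (this baseline has no
#'   unassigned state).
#' @export
fit_baseline_dosage <- function(expr, profile, allele = NULL,
                                config = inference_config(),
                                verbose = TRUE) {
  variant <- if (n_snps(allele) > 0) config$model_variant else "total_cn"
  dat <- build_model_data(expr, profile, allele, variant, verbose = verbose)
  mu_prime <- init_mu_prime(expression_matrix(dat$X))
  runs <- vector("list", config$n_restarts)
  for (i in seq_len(config$n_restarts)) {
    runs[[i]] <- run_map(dat, config, mu_prime, fix_k = TRUE,
                         seed = config$seed + i)
  }
  ## argmax labels, no posterior/consistency thresholding
  fit <- finalize_fit(runs, dat, config,
                      labeling_config(min_posterior = 1e-9,
                                      min_consistency = 1e-9),
                      mu_prime, fix_k = TRUE)
  ## per-gene Pearson R between normalized counts and assigned-clone CN
  lab <- fit$clone_label
  ok <- lab %in% dat$clones
  lam_assigned <- t(dat$lambda[, lab[ok], drop = FALSE])  # cells x genes
  norm_counts <- dat$X[ok, , drop = FALSE] /
    pmax(dat$l[ok], 1)
  r <- vapply(seq_len(ncol(norm_counts)), function(j) {
    x <- norm_counts[, j]; y <- lam_assigned[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }, numeric(1))
  fit$baseline_r <- stats::setNames(r, dat$genes)
  fit
}

#' Exact clone posterior at given parameter estimates
#'
#' \eqn{p(z_n = c \mid \cdot) \propto \pi_c \,
#'   \mathrm{Mult}(X_n \mid y_n(c)) \prod_s \mathrm{Binom}(r_{ns} \mid
#'   t_{ns}, f_{ns}(c))}, normalized exactly over clones. Reduces to
#' \eqn{\pi} for a cell with no reads.
#'
#' @param expr an [expression_matrix()] (rows are the cells to score), or
#'   `NULL`.
#' @param allele optional [allele_data()] over the same cells.
#' @param profile a [clone_cn_profile()].
#' @param params named list with `pi`, `mu0`, `mu1`, `p_k` and optionally
#'   `psi`, `w`, `p_a` (e.g. a fitted `fit_result`).
#' @return N x C row-stochastic matrix.
#' @export
clone_posterior_exact <- function(expr, allele, profile, params) {
  clones <- colnames(profile$cn)
  C <- length(clones)
  N <- if (!is.null(expr)) nrow(expr$counts) else nrow(allele$ref_counts)
  A <- matrix(rep(log(params$pi), each = N), N, C)
  if (!is.null(expr) && ncol(expr$counts) > 0) {
    genes <- colnames(expr$counts)
    D <- if (!is.null(params$psi)) ncol(as.matrix(params$psi)) else 0
    for (c in seq_len(C)) {
      for (n in seq_len(N)) {
        y <- expected_expression(params$mu0, params$mu1, params$p_k, profile,
                                 clones[c], 1,
                                 cell_psi = if (D > 0) as.matrix(params$psi)[n, ] else NULL,
                                 w = if (D > 0) params$w else NULL)
        p <- pmax(y[genes], PROB_FLOOR)
        A[n, c] <- A[n, c] + sum(expr$counts[n, ] * log(p))
      }
    }
  }
  if (n_snps(allele) > 0) {
    f <- expected_ref_fraction(params$p_a, allele$baf_clone)
    f <- pmin(pmax(f, BAF_FLOOR), 1 - BAF_FLOOR)
    for (c in seq_len(C)) {
      A[, c] <- A[, c] + allele$ref_counts %*% log(f[, c]) +
        (allele$total_counts - allele$ref_counts) %*% log1p(-f[, c])
    }
  }
  q <- exp(A - row_logsumexp(A))
  dimnames(q) <- list(if (!is.null(expr)) rownames(expr$counts) else rownames(allele$ref_counts),
                      clones)
  q
}

#' Consensus and consistency across restarts
#'
#' Given per-restart hard assignments over identical cells, computes for
#' each cell the fraction of runs agreeing with the majority label and the
#' consensus (majority) label; ties yield `"unassigned"`.
#'
#' @param labels cells x restarts character matrix, or a list of equal-length
#'   label vectors.
#' @return list with `consensus` (character) and `consistency` (numeric
#'   fraction in `[1/R, 1]`).
#' @export
restart_consensus <- function(labels) {
  if (is.list(labels)) {
    ns <- lengths(labels)
    if (length(unique(ns)) != 1) stop_ca("restarts cover different cell sets")
    nm <- lapply(labels, names)
    if (!is.null(nm[[1]]) &&
        !all(vapply(nm, identical, logical(1), nm[[1]]))) {
      stop_ca("restarts cover different cell sets")
    }
    labels <- do.call(cbind, labels)
  }
  cons <- apply(labels, 1L, function(r) {
    tab <- sort(table(r), decreasing = TRUE)
    top <- tab[1]
    tied <- names(tab)[tab == top]
    list(label = if (length(tied) > 1) "unassigned" else names(tab)[1],
         frac = as.numeric(top) / length(r))
  })
  list(consensus = vapply(cons, `[[`, character(1), "label"),
       consistency = stats::setNames(vapply(cons, `[[`, numeric(1), "frac"),
                                     rownames(labels)))
}
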