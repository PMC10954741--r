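test_that("exact clone posterior matches brute-force enumeration", {
  ## oracle: direct dmultinom/dbinom products over all clones
  set.seed(61)
  for (rep_i in 1:4) {
    N <- sample(2:5, 1); G <- sample(3:10, 1); C <- sample(2:3, 1)
    lam <- matrix(sample(1:5, G * C, TRUE), G, C,
                  dimnames = list(paste0("g", 1:G), LETTERS[1:C]))
    prof <- clone_cn_profile(lam)
    X <- matrix(rpois(N * G, 4), N, G,
                dimnames = list(paste0("c", 1:N), paste0("g", 1:G)))
    expr <- expression_matrix(X)
    S <- sample(0:4, 1)
    params <- list(pi = rdirichlet_unit(C),
                   mu0 = exp(rnorm(G)), mu1 = exp(rnorm(G)),
                   p_k = runif(G))
    allele <- NULL
    if (S > 0) {
      b <- matrix(runif(S * C), S, C,
                  dimnames = list(paste0("s", 1:S), LETTERS[1:C]))
      tot <- matrix(rpois(N * S, 2), N, S,
                    dimnames = list(rownames(X), rownames(b)))
      ref <- matrix(rbinom(N * S, as.vector(tot), 0.5), N, S,
                    dimnames = dimnames(tot))
      allele <- allele_data(b, ref, tot)
      params$p_a <- runif(S)
    }
    q <- clone_posterior_exact(expr, allele, prof, params)
    for (n in 1:N) {
      lik <- vapply(1:C, function(c) {
        num <- params$p_k * params$mu0 * lam[, c] +
          (1 - params$p_k) * params$mu1
        p <- num / sum(num)
        v <- params$pi[c] * dmultinom(X[n, ], prob = p)
        if (S > 0) {
          f <- params$p_a * b[, c] + (1 - params$p_a) * (1 - b[, c])
          v <- v * prod(dbinom(ref[n, ], tot[n, ], f))
        }
        v
      }, numeric(1))
      expect_equal(unname(q[n, ]), lik / sum(lik), tolerance = 1e-10)
    }
  }
})

test_that("uninformative likelihoods return the prior over clones", {
  prof <- clone_cn_profile(matrix(c(2, 3, 2, 3), 2, 2,
                                  dimnames = list(c("g1", "g2"), c("A", "B"))))
  expr <- expression_matrix(matrix(c(4, 1), 1, 2,
                                   dimnames = list("c1", c("g1", "g2"))))
  params <- list(pi = c(A = 0.3, B = 0.7), mu0 = c(1, 1), mu1 = c(1, 1),
                 p_k = c(1, 1))
  ## identical clone columns: posterior = pi
  q <- clone_posterior_exact(expr, NULL, prof, params)
  expect_equal(unname(q[1, ]), c(0.3, 0.7), tolerance = 1e-12)
  ## zero-depth cell with no SNP reads: posterior = pi
  prof2 <- clone_cn_profile(matrix(c(2, 3, 4, 1), 2, 2,
                                   dimnames = list(c("g1", "g2"),
                                                   c("A", "B"))))
  expr0 <- expression_matrix(matrix(c(0, 0), 1, 2,
                                    dimnames = list("c1", c("g1", "g2"))))
  q0 <- clone_posterior_exact(expr0, NULL, prof2, params)
  expect_equal(unname(q0[1, ]), c(0.3, 0.7), tolerance = 1e-12)
})

test_that("fitting recovers strong simulated structure and is deterministic", {
  s <- small_sim(seed = 71)
  cfg <- fast_inference(seed = 71)
  fit <- fit_clone_model(s$expr, s$profile, NULL, cfg, verbose = FALSE)
  expect_gte(clone_accuracy(fit$clone_label, s$truth$z), 0.95)
  validate_fit_result(fit)
  ## the model's own posterior agrees with the standalone exact computation
  q2 <- clone_posterior_exact(s$expr, NULL, s$profile,
                              list(pi = fit$pi, mu0 = fit$mu0, mu1 = fit$mu1,
                                   p_k = fit$p_k, psi = fit$psi, w = fit$w))
  expect_equal(fit$clone_posterior, q2[rownames(fit$clone_posterior), ],
               tolerance = 1e-6)
  ## deterministic given the seed
  fit2 <- fit_clone_model(s$expr, s$profile, NULL, cfg, verbose = FALSE)
  expect_identical(fit$clone_label, fit2$clone_label)
  expect_equal(fit$elbo_trace, fit2$elbo_trace)
})

test_that("ELBO increases and the trace never dips more than transiently", {
  s <- small_sim(seed = 73, n_cells = 120, n_genes = 80)
  fit <- fit_clone_model(s$expr, s$profile, NULL,
                         fast_inference(73, n_restarts = 1), verbose = FALSE)
  tr <- fit$elbo_trace
  expect_gt(tail(tr, 1), tr[1])
  dips <- diff(tr)
  expect_true(all(dips > -0.01 * abs(tr[-1])))
})

test_that("identical clone profiles raise a model-not-applicable error", {
  X <- matrix(rpois(40, 3), 4, 10,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:10)))
  prof <- clone_cn_profile(matrix(2, 10, 2,
                                  dimnames = list(paste0("g", 1:10),
                                                  c("A", "B"))))
  expect_error(fit_clone_model(expression_matrix(X), prof, NULL,
                               fast_inference(1), verbose = FALSE),
               "model not applicable")
})

test_that("integrated fit with empty allele data equals the total-CN fit", {
  s <- small_sim(seed = 75, n_cells = 100, n_genes = 60)
  cfg <- fast_inference(75, n_restarts = 1)
  f_tot <- fit_clone_model(s$expr, s$profile, NULL, cfg, verbose = FALSE)
  f_int <- fit_clone_model(s$expr, s$profile,
                           empty_allele_data(rownames(s$expr$counts),
                                             colnames(s$profile$cn)),
                           cfg, verbose = FALSE)
  expect_equal(f_tot$elbo_trace, f_int$elbo_trace)
  expect_identical(f_tot$clone_label, f_int$clone_label)
})

test_that("baseline with k fixed matches the dosage-only density and scores R", {
  ## a gene whose expression is exactly proportional to CN across clones
  ## earns a baseline correlation near 1
  s <- small_sim(seed = 77, n_cells = 150, n_genes = 80, frac_dosage = 1,
                 noise_dim = 0)
  cfg <- fast_inference(77)
  bl <- fit_baseline_dosage(s$expr, s$profile, NULL, cfg, verbose = FALSE)
  expect_true(all(bl$p_k == 1))
  expect_gte(clone_accuracy(bl$clone_label, s$truth$z), 0.95)
  ## genes with real clone CN spread and decent expression correlate
  spread <- apply(s$profile$cn, 1, function(r) max(r) - min(r))
  informative <- names(which(spread >= 1 & colMeans(s$expr$counts) > 5))
  expect_gt(mean(bl$baseline_r[informative]), 0.3)
})

test_that("more informative SNPs never hurt the integrated posterior", {
  ## accuracy is non-decreasing in SNP count on average (trend over seeds)
  accs <- sapply(c(0, 40, 120), function(S) {
    mean(sapply(1:3, function(sd0) {
      sc <- sim_config(n_cells = 80, n_genes = 40, n_clones = 2,
                       frac_dosage = 0.3, depth_mean = 150, depth_size = 0.8,
                       n_snps = S, snp_depth_mean = 0.5, seed = 80 + sd0)
      s <- simulate_expression(sc)
      al <- simulate_allele(sc, s$truth$z)
      fit <- fit_clone_model(s$expr, s$profile,
                             if (S > 0) al$allele else NULL,
                             fast_inference(80 + sd0, n_restarts = 1),
                             verbose = FALSE)
      mean(colnames(fit$clone_posterior)[max.col(fit$clone_posterior)] ==
             s$truth$z)
    }))
  })
  expect_true(all(diff(accs) > -0.02))
  expect_gt(accs[3], accs[1])
})
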