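test_that("expected expression normalizes to the cell depth and follows CN", {
  prof <- tiny_profile()
  ## G = 1: normalization forces y = l regardless of parameters
  prof1 <- clone_cn_profile(matrix(c(3, 5), 1, 2,
                                   dimnames = list("g", c("A", "B"))))
  y1 <- expected_expression(2, 7, 1, prof1, "A", cell_total = 42)
  expect_equal(unname(y1), 42)
  ## proportional-to-CN case: lambda (2, 4), all-dosage, no noise
  prof2 <- clone_cn_profile(matrix(c(2, 4, 2, 4), 2, 2,
                                   dimnames = list(c("g1", "g2"), c("A", "B"))))
  y2 <- expected_expression(c(1, 1), c(1, 1), c(1, 1), prof2, "A", 90)
  expect_equal(unname(y2), c(30, 60))
  ## rescaling (mu0, mu1) jointly by a positive constant cancels
  y3 <- expected_expression(c(7, 7), c(7, 7), c(1, 1), prof2, "A", 90)
  expect_equal(y2, y3)
})

test_that("expected expression matches an independent high-precision oracle", {
  set.seed(11)
  G <- 10; D <- 2
  lam <- matrix(sample(1:6, G * 2, TRUE), G, 2,
                dimnames = list(paste0("g", 1:G), c("A", "B")))
  prof <- clone_cn_profile(lam)
  mu0 <- exp(rnorm(G)); mu1 <- exp(rnorm(G)); k <- rbinom(G, 1, 0.5)
  w <- matrix(rnorm(G * D, 0, 0.5), G, D)
  psi <- rnorm(D)
  l <- 1234
  y <- expected_expression(mu0, mu1, k, prof, "B", l, cell_psi = psi, w = w)
  ## oracle: term-by-term scalar evaluation of the formula
  num <- numeric(G)
  for (g in 1:G) {
    num[g] <- (mu0[g] * lam[g, "B"] * k[g] + mu1[g] * (1 - k[g])) *
      exp(sum(psi * w[g, ]))
  }
  oracle <- l * num / sum(num)
  expect_equal(unname(y), oracle, tolerance = 1e-10)
  expect_equal(sum(y), l, tolerance = 1e-9)
})

test_that("expected reference fraction obeys the allele relabeling symmetry", {
  expect_equal(expected_ref_fraction(1, 0.8), 0.8)
  expect_equal(expected_ref_fraction(0, 0.8), 0.2)
  expect_equal(expected_ref_fraction(0, 0.5), 0.5)
  expect_equal(expected_ref_fraction(1, 0.5), 0.5)
  for (b in seq(0, 1, by = 0.1)) {
    expect_equal(expected_ref_fraction(1, b), expected_ref_fraction(0, 1 - b))
  }
  fr <- expected_ref_fraction(rbinom(20, 1, 0.5), runif(20))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("softplus-inverse initialization inverts the gene means", {
  expr <- expression_matrix(matrix(c(1, 1, 0, 0, 3, 5), 2, 3,
                                   dimnames = list(c("c1", "c2"),
                                                   c("g1", "g2", "g3"))))
  mp <- init_mu_prime(expr)
  expect_equal(unname(mp["g1"]), log(exp(1) - 1), tolerance = 1e-12)
  expect_equal(unname(mp["g2"]), softplus_inv(1e-4))  # clamped at epsilon
  expect_equal(unname(softplus(mp)),
               unname(pmax(colMeans(expr$counts), 1e-4)),
               tolerance = 1e-12)
})

test_that("joint log-density equals a hand-computed term-by-term sum", {
  ## 2 cells x 2 genes x 2 clones toy instance, no noise term
  expr <- expression_matrix(matrix(c(3, 1, 0, 4), 2, 2, byrow = TRUE,
                                   dimnames = list(c("c1", "c2"),
                                                   c("g1", "g2"))))
  prof <- clone_cn_profile(matrix(c(2, 2, 2, 4), 2, 2,
                                  dimnames = list(c("g1", "g2"), c("A", "B"))))
  params <- list(mu0 = c(0.5, 1.2), mu1 = c(0.8, 0.6), pi = c(0.3, 0.7),
                 p_k = c(0.9, 0.4))
  z <- c("A", "B"); k <- c(1, 0)
  hyper <- model_hyperparams(G = 2, N = 2, C = 2, D = 0,
                             mu_prime = init_mu_prime(expr))
  got <- joint_log_density(expr, prof, params, z, k, hyper = hyper)
  ## oracle: each term via base R distribution functions
  y1 <- c(0.5 * 2, 0.6); y1 <- y1 / sum(y1)       # cell 1 in clone A
  y2 <- c(0.5 * 2, 0.6); y2 <- y2 / sum(y2)       # cell 2 in clone B: g2 k=0
  want <- log(0.3) + log(0.7) +                    # categorical z
    dmultinom(c(3, 1), prob = y1, log = TRUE) +
    dmultinom(c(0, 4), prob = y2, log = TRUE) +
    sum(dbeta(params$p_k, 1, 1, log = TRUE)) +
    log(0.9) + log(1 - 0.4) +                      # Bernoulli k
    lgamma(2) - 2 * lgamma(1) +                    # Dirichlet(1, 1) on pi
    sum(dnorm(softplus_inv(params$mu0), hyper$mu_prime, 10, log = TRUE) -
          log(plogis(softplus_inv(params$mu0)))) +
    sum(dnorm(softplus_inv(params$mu1), hyper$mu_prime, 10, log = TRUE) -
          log(plogis(softplus_inv(params$mu1))))
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("allele terms change by the computable binomial amount", {
  expr <- expression_matrix(matrix(c(3, 1, 0, 4), 2, 2, byrow = TRUE,
                                   dimnames = list(c("c1", "c2"),
                                                   c("g1", "g2"))))
  prof <- tiny_profile(matrix(c(2, 2, 2, 4), 2, 2,
                              dimnames = list(c("g1", "g2"), c("A", "B"))))
  b <- matrix(0.5, 1, 2, dimnames = list("s1", c("A", "B")))
  tot1 <- matrix(c(2, 4), 2, 1, dimnames = list(c("c1", "c2"), "s1"))
  ref1 <- matrix(c(1, 2), 2, 1, dimnames = list(c("c1", "c2"), "s1"))
  ad1 <- allele_data(b, ref1, tot1)
  ad2 <- allele_data(b, 2 * ref1, 2 * tot1)
  params <- list(mu0 = c(0.5, 1.2), mu1 = c(0.8, 0.6), pi = c(0.3, 0.7),
                 p_k = c(0.9, 0.4), p_a = 0.5)
  z <- c("A", "B"); k <- c(1, 0)
  d1 <- joint_log_density(expr, prof, params, z, k, a = 1, allele = ad1)
  d2 <- joint_log_density(expr, prof, params, z, k, a = 1, allele = ad2)
  ## with f = 0.5 doubling (r, t) changes only the binomial log-pmfs
  delta <- sum(dbinom(c(2, 4), c(4, 8), 0.5, log = TRUE)) -
    sum(dbinom(c(1, 2), c(2, 4), 0.5, log = TRUE))
  expect_equal(d2 - d1, delta, tolerance = 1e-10)
  ## empty allele data reduces to the total-CN density
  d0 <- joint_log_density(expr, prof, params, z, k)
  dempty <- joint_log_density(expr, prof, params, z, k,
                              allele = empty_allele_data(c("c1", "c2"),
                                                         c("A", "B")))
  expect_equal(d0, dempty)
})
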