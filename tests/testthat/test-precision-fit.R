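test_that("MLE existence is equivalent to clique-wise positive definiteness", {
  set.seed(20)
  pat <- five_gene_pattern()
  cl <- maximal_cliques(pat)$cliques
  expect_equal(lapply(cl, unname), list(c(1, 2), c(1, 4), c(2, 3, 5), c(3, 4, 5)))

  # generic continuous data with n > largest clique: exists
  R <- matrix(rnorm(10 * 5), 10, 5)
  expect_true(mle_exists(crossprod(R) / 10, pattern = pat))
  # n = 2 samples cannot support a 3-clique
  R2 <- matrix(rnorm(2 * 5), 2, 5)
  expect_false(mle_exists(crossprod(R2) / 2, pattern = pat))
  # residual-bundle input computes the same blocks on demand
  rb <- residuals_under(R, matrix(1, 10, 1))
  S <- crossprod(rb$residuals) / 10
  expect_identical(mle_exists(rb, pattern = pat), mle_exists(S, pattern = pat))
})

test_that("unconstrained and diagonal patterns reduce to closed forms", {
  set.seed(21)
  S <- random_pd(4)
  full <- as_zero_pattern(matrix(1, 4, 4))
  f1 <- fit_precision(S, full, tol = 1e-10)
  expect_equal(as.matrix(f1$K), solve(S), tolerance = 1e-7, ignore_attr = TRUE)
  dia <- as_zero_pattern(diag(4))
  f2 <- fit_precision(S, dia, tol = 1e-10)
  expect_equal(as.matrix(f2$K), diag(1 / diag(S)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the fitted precision solves the likelihood equations and matches a dense optimiser", {
  set.seed(22)
  pat <- five_gene_pattern()
  Nm <- as.matrix(pat$N)
  for (rep in 1:3) {
    S <- random_pd(5)
    fit <- fit_precision(S, pat, tol = 1e-8)
    Sig <- solve(as.matrix(fit$K))
    # moment matching on the 8 edges + 5 diagonals
    expect_lt(max(abs((Sig - S)[Nm != 0])), 1e-6)
    # exact structural zeros at (1,3), (1,5), (2,4)
    expect_identical(as.matrix(fit$K)[Nm == 0], rep(0, 6))
    # symmetric positive definite
    expect_true(Matrix::isSymmetric(fit$K))
    expect_gt(min(eigen(as.matrix(fit$K), only.values = TRUE)$values), 0)
    # agrees with an independent constrained optimiser
    Kora <- dense_mle_oracle(S, pat)
    expect_lt(max(abs(as.matrix(fit$K) - Kora)), 1e-5)
    # log-likelihood never decreases over sweeps
    expect_true(all(diff(fit$report$loglik_trace) > -1e-9))
  }
})

test_that("fitting refuses patterns whose MLE does not exist", {
  set.seed(23)
  pat <- five_gene_pattern()
  R2 <- matrix(rnorm(10), 2, 5)
  expect_error(fit_precision(crossprod(R2) / 2, pat), "MLE does not exist")
})

test_that("conditional regressions invert the precision parameterisation", {
  # 2x2 hand computation: K = [[2, -1], [-1, 2]]
  K <- matrix(c(2, -1, -1, 2), 2)
  cr <- conditional_regressions(K)
  expect_equal(cr$beta[1, 2], 1 / 2)
  expect_equal(cr$resid_var, c(1 / 2, 1 / 2))
  expect_equal(Matrix::diag(cr$beta), c(0, 0))
  # diagonal K: no neighbours
  crd <- conditional_regressions(diag(c(2, 4)))
  expect_equal(Matrix::nnzero(crd$beta), 0)
  expect_equal(crd$resid_var, c(1 / 2, 1 / 4))

  # dense oracle: regression coefficients of the implied joint normal
  set.seed(24)
  gm <- generate_precision(8, m = 3, seed = 3)
  K8 <- as.matrix(gm$K)
  cr8 <- conditional_regressions(gm$K)
  Sig <- solve(K8)
  for (i in 1:8) {
    others <- setdiff(1:8, i)
    b_oracle <- solve(Sig[others, others], Sig[others, i])
    b_mine <- as.numeric(cr8$beta[i, others])
    expect_equal(b_mine, as.numeric(b_oracle), tolerance = 1e-10)
    expect_equal(cr8$resid_var[i],
                 drop(Sig[i, i] - Sig[i, others] %*% b_oracle),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("regression-only estimates approximate the MLE and the truth", {
  set.seed(25)
  gm <- generate_precision(15, m = 3, seed = 4)
  # empty pattern reduces to diag(1/s_ii)
  x <- sample_mvn(gm, 300)
  xc <- scale(x, scale = FALSE)
  ra0 <- regression_approx_precision(x, as_zero_pattern(diag(15)))
  expect_equal(as.matrix(ra0$K), diag(300 / colSums(xc^2)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # at large n with the true pattern the approximation nears the truth
  xl <- sample_mvn(gm, 20000, seed = 5)
  ral <- regression_approx_precision(xl, gm$pattern)
  expect_lt(max(abs(as.matrix(ral$K - gm$K))), 0.15)
  expect_lt(ral$asymmetry, 0.2)
  # and is close to the likelihood fit on the same data
  Sl <- crossprod(scale(xl, scale = FALSE)) / nrow(xl)
  fit <- fit_precision(Sl, gm$pattern)
  expect_lt(max(abs(as.matrix(ral$K - fit$K))), 0.1)
})

test_that("the profile log-likelihood matches dense evaluation", {
  set.seed(26)
  p <- 6; n <- 40
  expect_equal(log_likelihood(diag(p), diag(p), n), (n / 2) * (0 - p))
  gm <- generate_precision(p, m = 2, seed = 7)
  S <- random_pd(p)
  ll <- log_likelihood(gm$K, S, n)
  K <- as.matrix(gm$K)
  expect_equal(ll, (n / 2) * (determinant(K)$modulus[1] - sum(K * S)),
               ignore_attr = TRUE)
  # scaling identity: L(cK) - L(K) = (n/2)(p log c - (c-1) tr(KS))
  c0 <- 1.7
  expect_equal(log_likelihood(gm$K * c0, S, n) - ll,
               (n / 2) * (p * log(c0) - (c0 - 1) * sum(K * S)),
               ignore_attr = TRUE)
})

test_that("precision recovery sharpens with sample size at the true pattern", {
  set.seed(27)
  gm <- generate_precision(30, m = 4, seed = 8)
  err <- vapply(c(100, 800), function(n) {
    x <- sample_mvn(gm, n, seed = n)
    S <- crossprod(scale(x, scale = FALSE)) / n
    max(abs(as.matrix(fit_precision(S, gm$pattern)$K - gm$K)))
  }, numeric(1))
  expect_lt(err[2], err[1])
})
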