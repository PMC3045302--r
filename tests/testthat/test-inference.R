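test_that("orthogonal completion reproduces the two-group rotation", {
  oc <- orthogonal_complete(matrix(c(1, -1) / sqrt(2), 2, 1))
  expect_equal(oc$Q, matrix(c(1, 1, 1, -1) / sqrt(2), 2, 2))
  # identity-tail contrasts leave an identity head
  C <- diag(4)[, 3:4]
  oc2 <- orthogonal_complete(C)
  expect_equal(oc2$Q, diag(4)[, c(1, 2, 3, 4)])
  # random orthonormal contrasts complete to an orthogonal matrix
  set.seed(30)
  for (rep in 1:5) {
    C <- qr.Q(qr(matrix(rnorm(5 * 2), 5, 2)))
    Q <- orthogonal_complete(C)$Q
    expect_equal(crossprod(Q), diag(5), tolerance = 1e-12)
    expect_equal(Q[, 4:5], C)
  }
  # a full-rank but non-orthonormal contrast is orthonormalised first
  oc3 <- orthogonal_complete(matrix(c(2, -2), 2, 1))
  expect_true(oc3$orthonormalised)
  expect_equal(crossprod(oc3$Q), diag(2), tolerance = 1e-12)
  expect_error(orthogonal_complete(diag(2)), "s < r")
})

test_that("the contrast frame is the rotated least-squares fit", {
  set.seed(31)
  n <- 18; p <- 7
  x <- matrix(rnorm(n * p), n, p)
  D <- cbind(rep(c(1, 0), c(10, 8)), rep(c(0, 1), c(10, 8)))
  C <- matrix(c(1, -1) / sqrt(2), 2, 1)
  fr <- contrast_frame(x, D, C)
  expect_equal(fr$D_tilde, D %*% fr$Q)
  expect_equal(fr$Gamma_hat, t(fr$Q) %*% estimate_coefficients(x, D),
               ignore_attr = TRUE)
  # G22 for the two-group design: (1/2)(1/n1 + 1/n2); balanced gives 2/n
  expect_equal(drop(fr$G22), (1 / 10 + 1 / 8) / 2)
  expect_equal(drop(tcrossprod(fr$L)), 1 / drop(fr$G22))
  frb <- contrast_frame(x[1:16, ], D[c(1:8, 11:18), ], C)
  expect_equal(drop(frb$G22), 2 / 16)
})

test_that("the three forms of the statistic agree on random instances", {
  set.seed(32)
  for (rep in 1:50) {
    n <- sample(10:30, 1); p <- sample(5:60, 1); r <- sample(2:4, 1)
    s <- sample(seq_len(r - 1), 1)
    x <- matrix(rnorm(n * p), n, p)
    D <- cbind(1, matrix(rnorm(n * (r - 1)), n))
    C <- qr.Q(qr(matrix(rnorm(r * s), r, s)))
    K <- random_pd(p)
    fr <- contrast_frame(x, D, C)
    st <- statistic_T(fr, K)
    # quadratic form in Gamma2 with the G22 weight
    T17 <- sum(diag(solve(fr$G22) %*% fr$Gamma2_hat %*% K %*%
                      t(fr$Gamma2_hat)))
    # whitened trace form
    Gt <- t(fr$L) %*% fr$Gamma2_hat
    T18 <- sum(diag(Gt %*% K %*% t(Gt)))
    # gene-wise components sigma^ii gamma_i (gamma_N)_i
    T19 <- sum(st$components)
    expect_equal(st$T_obs, T17, tolerance = 1e-10)
    expect_equal(st$T_obs, T18, tolerance = 1e-10)
    expect_equal(st$T_obs, T19, tolerance = 1e-10)
  }
})

test_that("identity precision removes the neighbour correction", {
  set.seed(33)
  x <- matrix(rnorm(20 * 6), 20, 6)
  D <- cbind(rep(1:0, each = 10), rep(0:1, each = 10))
  fr <- contrast_frame(x, D, matrix(c(1, -1) / sqrt(2), 2, 1))
  st <- statistic_T(fr, diag(6))
  expect_equal(st$gamma_nb, st$gamma)
  expect_equal(st$T_obs, sum(st$gamma^2))
})

test_that("the two-group statistic is the scaled precision distance of group means", {
  set.seed(34)
  for (rep in 1:5) {
    n1 <- sample(5:12, 1); n2 <- sample(5:12, 1)
    p <- 10
    gm <- generate_precision(p, m = 3, seed = rep)
    x <- sample_mvn(gm, n1 + n2)
    lab <- rep(c("t", "c"), c(n1, n2))
    tt <- two_group_test(x, lab, gm$K, n_perm = 3, seed = 1)
    d <- colMeans(x[lab == "t", , drop = FALSE]) -
      colMeans(x[lab == "c", , drop = FALSE])
    Tclosed <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% as.matrix(gm$K) %*% d)
    expect_equal(tt$T_obs, Tclosed, tolerance = 1e-10)
    # label swap leaves T unchanged
    tt2 <- two_group_test(x, ifelse(lab == "t", "c", "t"), gm$K,
                          n_perm = 3, seed = 1)
    expect_equal(tt2$T_obs, tt$T_obs, tolerance = 1e-10)
  }
})

test_that("two-group wrapper agrees exactly with the general contrast path", {
  set.seed(35)
  gm <- generate_precision(8, m = 2, seed = 2)
  x <- sample_mvn(gm, 14)
  lab <- rep(c("a", "b"), c(6, 8))
  D <- cbind(as.numeric(lab == "a"), as.numeric(lab == "b"))
  C <- matrix(c(1, -1) / sqrt(2), 2, 1)
  t1 <- two_group_test(x, lab, gm$K, n_perm = 40, seed = 9)
  t2 <- permutation_test(x, D, C, gm$K, n_perm = 40, seed = 9)
  expect_identical(t1$T_obs, t2$T_obs)
  expect_identical(t1$null_T, t2$null_T)
  expect_identical(t1$pvalues_de, t2$pvalues_de)
})

test_that("with an intercept null block the procedure permutes rows of X", {
  set.seed(36)
  n <- 12; p <- 5
  x <- matrix(rnorm(n * p), n, p)
  D <- cbind(rep(1:0, each = 6), rep(0:1, each = 6))
  C <- matrix(c(1, -1) / sqrt(2), 2, 1)
  fr <- contrast_frame(x, D, C)
  # D_tilde1 is proportional to the ones vector, so the null projector is
  # row centring and permuting residuals is permuting rows of X up to the
  # projector; the residual covariance (permuted or not) coincides
  expect_equal(fr$D_tilde1 / fr$D_tilde1[1, 1], matrix(1, n, 1),
               ignore_attr = TRUE)
  P1 <- fr$D_tilde1 %*% solve(crossprod(fr$D_tilde1), t(fr$D_tilde1))
  perm <- sample(n)
  Pk <- diag(n)[perm, ]
  expect_equal(diag(n) - P1, Pk %*% (diag(n) - P1) %*% t(Pk))
  # and the reassembled null data are exactly row-permuted X
  Fhat <- P1 %*% x
  R <- x - Fhat
  expect_equal(Fhat + R[perm, ], x[perm, ], tolerance = 1e-12)
})

test_that("permutation p-values are reproducible and respect the add-one convention", {
  set.seed(37)
  gm <- generate_precision(6, m = 2, seed = 3)
  x <- sample_mvn(gm, 10)
  lab <- rep(c("a", "b"), each = 5)
  t1 <- two_group_test(x, lab, gm$K, n_perm = 25, seed = 4)
  t2 <- two_group_test(x, lab, gm$K, n_perm = 25, seed = 4)
  expect_identical(t1$null_T, t2$null_T)
  expect_identical(t1$pvalues_dc, t2$pvalues_dc)
  # q = 1: p-value can only be 1/2 or 1
  tq1 <- two_group_test(x, lab, gm$K, n_perm = 1, seed = 5)
  expect_true(tq1$pvalues_T %in% c(1 / 2, 1))
  expect_true(all(tq1$pvalues_de %in% c(1 / 2, 1)))
  # p-values always in (0, 1]
  expect_true(all(t1$pvalues_de > 0 & t1$pvalues_de <= 1))
})

test_that("modified Bonferroni thresholds are alpha/m with alpha > 1 allowed", {
  r <- modified_bonferroni(c(.0001, .001, .5), alpha_expected_fp = 8,
                           m_tests = 40000)
  expect_equal(r$threshold, 2e-4)
  expect_equal(r$rejected, 1L)
  # alpha = m rejects everything below 1
  r2 <- modified_bonferroni(c(.2, .999, 1), alpha_expected_fp = 3, m_tests = 3)
  expect_equal(r2$rejected, c(1L, 2L))
  # all p = 1: nothing rejected
  expect_length(modified_bonferroni(rep(1, 5), 8, 10)$rejected, 0)
  expect_error(modified_bonferroni(.5, 0), "alpha")
})

test_that("neighbour-corrected contrasts are standard normal under the null", {
  # with gamma ~ N(0, Sigma), (gamma_N)_i * sqrt(sigma^ii) has unit variance
  set.seed(38)
  gm <- generate_precision(12, m = 3, seed = 6)
  n <- 30
  lab <- rep(c("a", "b"), each = n / 2)
  z <- replicate(300, {
    x <- sample_mvn(gm, n)
    fr <- contrast_frame(x, cbind(lab == "a", lab == "b") * 1,
                         matrix(c(1, -1) / sqrt(2), 2, 1))
    st <- statistic_T(fr, gm$K)
    st$gamma_nb[1, 1] * sqrt(st$sigma_ii[1])
  })
  expect_lt(abs(mean(z)), 3 / sqrt(300))
  expect_lt(abs(var(z) - 1), 3 * sqrt(2 / 299))
})

test_that("tidy and glance summarise a test", {
  set.seed(39)
  gm <- generate_precision(7, m = 2, seed = 7)
  x <- sample_mvn(gm, 12)
  tt <- two_group_test(x, rep(c("a", "b"), each = 6), gm$K, n_perm = 19,
                       seed = 8)
  td <- tidy(tt)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 7)
  expect_equal(sum(td$component), tt$T_obs)
  gl <- glance(tt)
  expect_equal(gl$n_perm, 19)
  expect_s3_class(autoplot(tt), "ggplot")
})
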