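test_that("forward selection is greedy on RSS reduction", {
  set.seed(10)
  n <- 40
  # exact linear dependence: the matching column is found first, perfectly
  Z <- matrix(rnorm(n * 8), n, 8)
  path <- forward_stepwise(Z[, 3], Z, kmax = 3)
  expect_equal(path$selected[1], 3L)
  expect_equal(path$resid_var[2], 0)

  # greedy choice agrees with an exhaustive refit oracle, step by step
  for (rep in 1:5) {
    Z <- matrix(rnorm(30 * 12), 30, 12)
    y <- rnorm(30)
    path <- forward_stepwise(y, Z, kmax = 5, standardize = FALSE)
    oracle <- greedy_oracle(y, Z, 5)
    expect_equal(path$selected, oracle$selected)
    expect_equal(path$resid_var, oracle$rss / 30)
    expect_true(all(diff(path$resid_var) <= 1e-12))
  }
})

test_that("stepwise rejects saturation and flags constant columns", {
  Z <- matrix(rnorm(20), 5, 4)
  expect_error(forward_stepwise(rnorm(5), Z, kmax = 5), "saturation|sample size")
  Zc <- cbind(Z, 7)
  path <- forward_stepwise(rnorm(5), Zc, kmax = 2)
  expect_equal(path$skipped, 5L)
  expect_false(5L %in% path$selected)
})

test_that("modified BIC matches direct log-gamma evaluation", {
  # k = 0: both penalty terms vanish
  expect_equal(bic_gamma(50, 0, 1000, 2, gamma = 1), 50 * log(2))
  expect_equal(bic_2p(50, 0, 1000, 2), 50 * log(2))
  # gamma = 0 is the usual BIC
  expect_equal(bic_gamma(100, 4, 500, 0.7, gamma = 0),
               100 * log(0.7) + 4 * log(100))
  # direct evaluation via lgamma, independently of lchoose
  lbinom <- lgamma(1001) - lgamma(4) - lgamma(998)
  expect_equal(bic_gamma(100, 3, 1000, 0.5, gamma = 1),
               100 * log(0.5) + 3 * log(100) + 2 * lbinom)
  expect_equal(bic_2p(100, 3, 1000, 0.5),
               100 * log(0.5) + 6 * log(1000))
  # algebraic relation between the two variants
  expect_equal(bic_2p(100, 3, 1000, 0.5),
               bic_gamma(100, 3, 1000, 0.5, gamma = 0) +
                 (2 * log(1000) - log(100)) * 3)
  # perfect fit dominates
  expect_equal(bic_gamma(100, 2, 50, 0), -Inf)
})

test_that("model-size selection minimises the criterion and recovers planted supports", {
  set.seed(11)
  # a path whose criterion increases monotonically selects size 0
  n <- 200
  noise <- forward_stepwise(rnorm(n), matrix(rnorm(n * 10), n), kmax = 5)
  # strong signal with 3 true predictors is recovered at gamma = 1
  Z <- matrix(rnorm(n * 10), n, 10)
  y <- Z[, 1] + Z[, 2] - Z[, 3] + rnorm(n, sd = 0.3)
  sig <- forward_stepwise(y, Z, kmax = 6)
  expect_equal(select_size(sig, p_choices = 10, criterion = "bic1.0"), 3L)
  expect_setequal(sig$selected[1:3], 1:3)
  # pure-noise responses almost always select the empty model
  k0 <- replicate(40, {
    select_size(forward_stepwise(rnorm(100), matrix(rnorm(100 * 50), 100),
                                 kmax = 4),
                p_choices = 50, criterion = "bic1.0")
  })
  expect_gte(mean(k0 == 0), 0.8)
})

test_that("selected sizes shrink as the penalty grows", {
  set.seed(12)
  x <- sample_mvn(generate_precision(60, m = 4, seed = 5), 120)
  paths <- lapply(seq_len(12), function(i) {
    forward_stepwise(x[, i], x[, -i, drop = FALSE], kmax = 6)
  })
  k_soft <- vapply(paths, select_size, integer(1), p_choices = 59,
                   criterion = "bic0.0")
  k_hard <- vapply(paths, select_size, integer(1), p_choices = 59,
                   criterion = "bic1.0")
  expect_true(all(k_hard <= k_soft))
})

test_that("the zero pattern is symmetric with unit diagonal and contains A", {
  set.seed(13)
  gm <- generate_precision(40, m = 4, seed = 6)
  x <- sample_mvn(gm, 200)
  pat <- find_pattern(x, kmax = 5)
  N <- pat$N; A <- pat$A
  expect_true(Matrix::isSymmetric(N))
  expect_true(all(Matrix::diag(N) == 1))
  expect_true(all((A != 0) * 1 <= (N != 0) * 1))  # support(A) within N
  expect_true(all(pat$neighbour_sizes == Matrix::rowSums(N != 0) - 1))
  # a duplicated gene is its twin's first selection
  xd <- cbind(x, x[, 2])
  colnames(xd) <- c(colnames(x), "twin")
  patd <- find_pattern(xd, kmax = 3)
  expect_equal(patd$A[ncol(xd), 2], 1)
  expect_equal(patd$A[2, ncol(xd)], 1)
})

test_that("independent genes yield a near-empty pattern under BIC_1.0", {
  set.seed(14)
  x <- matrix(rnorm(150 * 60), 150, 60)
  pat <- find_pattern(x, kmax = 5, criterion = "bic1.0")
  n_edges <- (Matrix::nnzero(pat$N) - 60) / 2
  expect_lte(n_edges, 3)
})

test_that("the pattern search warns above the kmax/n guidance and needs p >= 2", {
  set.seed(15)
  x <- matrix(rnorm(40 * 10), 40, 10)
  expect_warning(find_pattern(x, kmax = 4), "1/20")
  expect_silent(pat <- find_pattern(x, kmax = 2))
  expect_error(find_pattern(x[, 1, drop = FALSE], kmax = 1), "two genes")
})

test_that("selection runs on design residuals by default", {
  set.seed(16)
  n <- 100
  gm <- generate_precision(20, m = 3, seed = 8)
  x <- sample_mvn(gm, n)
  # a strong two-group mean shift on all genes induces spurious marginal
  # correlation; residualising the design removes it
  shift <- rep(c(0, 6), each = n / 2)
  xs <- x + shift
  D <- cbind(as.numeric(shift == 0), as.numeric(shift > 0))
  p_res <- find_pattern(xs, design = D, kmax = 4)
  p_raw <- find_pattern(xs, design = D, kmax = 4, use_residuals = FALSE)
  e_res <- (Matrix::nnzero(p_res$N) - 20) / 2
  e_raw <- (Matrix::nnzero(p_raw$N) - 20) / 2
  expect_lt(e_res, e_raw)  # the shift inflates the raw-column pattern
})
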