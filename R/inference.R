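# Testing linear contrasts of treatment effects, conditional on the fitted
# precision matrix. The hypothesis C'B = 0 is reparameterised through an
# orthogonal completion Q = [A C] so it reads "the last s rows of Gamma =
# Q'B vanish"; the test statistic is the quadratic form
#   T = trace{(G22)^{-1} Gamma2 K Gamma2'},  K = Sigma^{-1},
# which decomposes gene-wise into sigma^{ii} * gamma_i * (gamma_N)_i with
# (gamma_N)_i = gamma_i - sum_j beta_ij gamma_j, the neighbour-corrected
# contrast. Significance comes from a residual-permutation null.

set_local_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible()
}

#' Orthogonal completion of a contrast matrix
#'
#' Expands an (r x s) matrix of orthonormal contrasts `C` into an orthogonal
#' (r x r) matrix `Q = [A C]` whose last `s` columns are `C`. A merely
#' full-rank `C` is orthonormalised first (recorded in the result). The
#' complement columns are canonicalised so each has a positive first
#' non-zero entry, making the completion deterministic.
#'
#' @param C contrast matrix ((r x s), `s < r`) or a length-`r` vector.
#' @param r number of design columns; defaults to `nrow(C)`.
#' @return list with `Q`, `C` (as used, orthonormal), `orthonormalised`
#'   (logical).
#' @export
orthogonal_complete <- function(C, r = NRROW(C)) {
  if (is.null(dim(C))) C <- matrix(C, ncol = 1)
  if (missing(r)) r <- nrow(C)
  s <- ncol(C)
  if (s >= r) stop("need s < r contrasts", call. = FALSE)
  if (qr(C)$rank < s) stop("contrast matrix is rank deficient", call. = FALSE)
  ortho <- !isTRUE(all.equal(crossprod(C), diag(s), tolerance = 1e-8))
  if (ortho) C <- qr.Q(qr(C))
  Qfull <- qr.Q(qr(C), complete = TRUE)
  A <- Qfull[, (s + 1):r, drop = FALSE]
  # deterministic sign: first non-zero entry of each complement column > 0
  for (j in seq_len(ncol(A))) {
    nz <- which(abs(A[, j]) > 1e-12)[1]
    if (A[nz, j] < 0) A[, j] <- -A[, j]
  }
  list(Q = cbind(A, C), C = C, orthonormalised = ortho)
}

NRROW <- function(x) if (is.null(dim(x))) length(x) else nrow(x)

#' Build the reparameterised contrast frame
#'
#' Computes all ingredients of the test: `D_tilde = D Q`, `Gamma_hat =
#' (D_tilde' D_tilde)^{-1} D_tilde' X` (so `Gamma_hat = Q' B_hat`), the
#' `s x s` block `G22` of `(D_tilde' D_tilde)^{-1}`, and a factor `L` with
#' `L L' = (G22)^{-1}` used to whiten the contrast rows.
#'
#' @param x expression matrix (`n x p`).
#' @param design design matrix (`n x r`), full column rank.
#' @param contrast (r x s) contrast matrix (orthonormalised if needed).
#' @return object of class `contrast_frame`.
#' @export
contrast_frame <- function(x, design, contrast) {
  x <- as_expression_matrix(x)
  D <- check_design(design, nrow(x))
  r <- ncol(D)
  oc <- orthogonal_complete(contrast, r)
  Q <- oc$Q; s <- ncol(oc$C)
  Dt <- D %*% Q
  Dt1 <- Dt[, seq_len(r - s), drop = FALSE]
  G <- solve(crossprod(Dt))
  Gamma <- G %*% crossprod(Dt, x)
  G22 <- G[(r - s + 1):r, (r - s + 1):r, drop = FALSE]
  L <- t(chol(solve(G22)))
  structure(
    list(D = D, C = oc$C, Q = Q, D_tilde = Dt, D_tilde1 = Dt1,
         Gamma_hat = Gamma,
         Gamma2_hat = Gamma[(r - s + 1):r, , drop = FALSE],
         G = G, G22 = G22, L = L, r = r, s = s, n = nrow(x),
         genes = colnames(x), x = x,
         orthonormalised = oc$orthonormalised),
    class = "contrast_frame")
}

#' @method print contrast_frame
#' @export
print.contrast_frame <- function(x, ...) {
  cat(sprintf("<contrast_frame> n = %d, r = %d design columns, s = %d contrast(s)\n",
              x$n, x$r, x$s))
  invisible(x)
}

precision_matrix_of <- function(K) {
  if (inherits(K, "sparse_precision")) K$K else
    Matrix::forceSymmetric(methods::as(K, "CsparseMatrix"))
}

# Observed statistic and its gene-wise decomposition for whitened contrast
# rows G2t (s x p): T = sum_k gamma_k' K gamma_k.
decompose_T <- function(G2t, Km) {
  kdiag <- unname(Matrix::diag(Km))
  Kg <- unname(as.matrix(Matrix::tcrossprod(Km, G2t)))  # p x s, cols K gamma_k
  gam <- unname(t(as.matrix(G2t)))                      # p x s
  components <- rowSums(gam * Kg)                  # sigma^ii gamma (gamma_N)
  gamma_nb <- Kg / kdiag
  list(T = sum(components), components = components,
       gamma = gam, gamma_nb = gamma_nb)
}

#' Multivariate contrast statistic and its DE/DC decomposition
#'
#' Computes `T = trace{(G22)^{-1} Gamma2 K Gamma2'}` through the whitened
#' form `T = trace(Gt K Gt')`, `Gt = L' Gamma2`, using sparse products only,
#' together with the gene-wise decomposition `T = sum_i sigma^{ii} gamma_i
#' (gamma_N)_i` (summed over contrast rows when `s > 1`).
#'
#' @param frame a [contrast_frame()].
#' @param precision fitted `sparse_precision` (or PD matrix).
#' @return list with `T_obs`, `gamma` (`p x s`, whitened contrast values),
#'   `gamma_nb` (`p x s` neighbour-corrected values), `components`
#'   (length-`p`, summing to `T_obs`), `sigma_ii` (diagonal of the
#'   precision).
#' @export
statistic_T <- function(frame, precision) {
  Km <- precision_matrix_of(precision)
  if (nrow(Km) != ncol(frame$x)) stop("dimension mismatch", call. = FALSE)
  G2t <- t(frame$L) %*% frame$Gamma2_hat
  d <- decompose_T(G2t, Km)
  list(T_obs = d$T, gamma = d$gamma, gamma_nb = d$gamma_nb,
       components = d$components, sigma_ii = Matrix::diag(Km))
}

#' Permutation test of a linear contrast with DE/DC decomposition
#'
#' Implements the residual-permutation procedure: fit the mean model under
#' the null (design reduced to `D_tilde1`), permute the residual rows,
#' reassemble data, and recompute the contrast statistic, holding the fitted
#' precision matrix fixed throughout. Empirical null distributions are
#' accumulated for the overall `T`, for each gene's contrast value `gamma_i`
#' (differential expression) and for its neighbour-corrected value
#' `(gamma_N)_i` (differential connection). Empirical p-values use the
#' add-one convention `(1 + #{null >= obs})/(q + 1)`; per-gene tests are
#' two-sided via absolute values for `s = 1` (for `s > 1` the per-gene
#' statistics are sums of squares over contrast rows, one-sided).
#'
#' Multiplicity over the combined family of `2p` DE and DC tests is handled
#' with the modified Bonferroni rule `p < alpha/m` where `alpha` bounds the
#' expected number of false rejections (see [modified_bonferroni()]).
#'
#' @inheritParams contrast_frame
#' @param precision fitted `sparse_precision` (held fixed across
#'   permutations).
#' @param n_perm number of permutations `q`.
#' @param seed integer seed for reproducible permutations.
#' @param alpha_expected_fp bound on the expected number of false rejections
#'   across the `2p` DE + DC tests.
#' @param keep_null keep the per-gene null matrices (`q x p`); the overall
#'   `T` null is always kept.
#' @return object of class `ggm_test`; see [tidy.ggm_test()] and
#'   [glance.ggm_test()].
#' @export
permutation_test <- function(x, design, contrast, precision, n_perm = 1000,
                             seed = NULL, alpha_expected_fp = 8,
                             keep_null = TRUE) {
  set_local_seed(seed)
  frame <- contrast_frame(x, design, contrast)
  Km <- precision_matrix_of(precision)
  p <- ncol(frame$x); n <- frame$n; s <- frame$s
  obs <- statistic_T(frame, precision)

  qr1 <- qr(frame$D_tilde1)
  Fhat <- qr.fitted(qr1, frame$x)
  R <- frame$x - Fhat
  M <- solve(crossprod(frame$D_tilde), t(frame$D_tilde))  # r x n
  rows2 <- (frame$r - s + 1):frame$r
  MF2 <- (M %*% Fhat)[rows2, , drop = FALSE]
  Lt <- t(frame$L)

  de_stat <- function(gam) if (s == 1) abs(gam[, 1]) else rowSums(gam^2)
  obs_de <- de_stat(obs$gamma)
  obs_dc <- de_stat(obs$gamma_nb)

  null_T <- numeric(n_perm)
  cnt_T <- 0; cnt_de <- numeric(p); cnt_dc <- numeric(p)
  null_de <- if (keep_null) matrix(NA_real_, n_perm, p) else NULL
  null_dc <- if (keep_null) matrix(NA_real_, n_perm, p) else NULL
  for (k in seq_len(n_perm)) {
    perm <- sample.int(n)
    G2k <- MF2 + (M[rows2, , drop = FALSE] %*% R[perm, , drop = FALSE])
    d <- decompose_T(Lt %*% G2k, Km)
    null_T[k] <- d$T
    sde <- de_stat(d$gamma); sdc <- de_stat(d$gamma_nb)
    cnt_T <- cnt_T + (d$T >= obs$T_obs)
    cnt_de <- cnt_de + (sde >= obs_de)
    cnt_dc <- cnt_dc + (sdc >= obs_dc)
    if (keep_null) { null_de[k, ] <- sde; null_dc[k, ] <- sdc }
  }

  p_T <- (1 + cnt_T) / (n_perm + 1)
  p_de <- (1 + cnt_de) / (n_perm + 1)
  p_dc <- (1 + cnt_dc) / (n_perm + 1)
  mult <- modified_bonferroni(c(p_de, p_dc), alpha_expected_fp,
                              m_tests = 2L * p)
  rej <- mult$rejected
  genes <- frame$genes

  structure(
    list(frame = frame, T_obs = obs$T_obs, gamma = obs$gamma,
         gamma_nb = obs$gamma_nb, components = obs$components,
         sigma_ii = obs$sigma_ii, genes = genes,
         null_T = null_T, null_de = null_de, null_dc = null_dc,
         pvalues_T = p_T, pvalues_de = p_de, pvalues_dc = p_dc,
         n_perm = n_perm, seed = seed,
         alpha_expected_fp = alpha_expected_fp,
         threshold = mult$threshold,
         rejected_de = which(p_de < mult$threshold),
         rejected_dc = which(p_dc < mult$threshold),
         null_quantiles = stats::quantile(
           null_T, c(.90, .95, .99, .99995), names = TRUE)),
    class = "ggm_test")
}

#' Modified Bonferroni multiplicity rule
#'
#' Rejects every hypothesis with `p < alpha/m`. Unlike the usual Bonferroni
#' rule, `alpha` may exceed 1, in which case it is an upper bound on the
#' expected number of false rejections (per-family error rate), valid under
#' any dependence between the p-values.
#'
#' @param pvalues numeric vector.
#' @param alpha_expected_fp bound on the expected number of false rejections
#'   (`> 0`, may exceed 1).
#' @param m_tests size of the testing family; defaults to
#'   `length(pvalues)`.
#' @return list with `threshold` (`alpha/m`), `rejected` (indices),
#'   `m_tests`, `alpha_expected_fp`.
#' @examples
#' modified_bonferroni(runif(10), alpha_expected_fp = 8, m_tests = 40000)$threshold
#' @export
modified_bonferroni <- function(pvalues, alpha_expected_fp,
                                m_tests = length(pvalues)) {
  if (alpha_expected_fp <= 0) stop("alpha_expected_fp must be > 0",
                                   call. = FALSE)
  threshold <- alpha_expected_fp / m_tests
  list(threshold = threshold, rejected = which(pvalues < threshold),
       m_tests = as.integer(m_tests), alpha_expected_fp = alpha_expected_fp)
}

#' Two-group comparison
#'
#' Convenience wrapper for comparing two groups of samples: builds the block
#' design `D = [1 0; 0 1]` from the labels and the contrast `C' = (1, -1)/
#' sqrt(2)`, then runs [permutation_test()]. In this case the permutation
#' procedure reduces to permuting the rows of `X`, and `T` equals
#' `n1 n2/(n1 + n2) * d' K d` with `d` the difference of group mean vectors.
#'
#' @inheritParams permutation_test
#' @param labels length-`n` vector with exactly two distinct values; the
#'   first level (factor order) is the "treatment" column.
#' @return a `ggm_test` (with `labels` attached).
#' @export
two_group_test <- function(x, labels, precision, n_perm = 1000, seed = NULL,
                           alpha_expected_fp = 8, keep_null = TRUE) {
  f <- factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly two levels", call. = FALSE)
  D <- cbind(as.numeric(f == levels(f)[1]), as.numeric(f == levels(f)[2]))
  colnames(D) <- levels(f)
  C <- matrix(c(1, -1) / sqrt(2), ncol = 1)
  out <- permutation_test(x, D, C, precision, n_perm = n_perm, seed = seed,
                          alpha_expected_fp = alpha_expected_fp,
                          keep_null = keep_null)
  out$labels <- f
  out
}

#' @method print ggm_test
#' @export
print.ggm_test <- function(x, ...) {
  cat(sprintf("<ggm_test> %d genes, %d permutations\n",
              length(x$genes), x$n_perm))
  cat(sprintf("  T = %.4g, p = %.4g\n", x$T_obs, x$pvalues_T))
  cat(sprintf("  null T quantiles (90/95/99/99.995%%): %s\n",
              paste(signif(x$null_quantiles, 5), collapse = " ")))
  cat(sprintf("  rejected at p < %g: %d DE, %d DC genes\n", x$threshold,
              length(x$rejected_de), length(x$rejected_dc)))
  invisible(x)
}

#' Tidy per-gene results of a contrast test
#'
#' @param x a `ggm_test`.
#' @param ... unused.
#' @return tibble with one row per gene: whitened contrast value `gamma`,
#'   neighbour-corrected `gamma_nb`, the component `sigma^{ii} gamma
#'   (gamma_N)` (these sum to `T`), two-sided permutation p-values `p_de`,
#'   `p_dc`, and rejection flags at the modified-Bonferroni threshold.
#' @method tidy ggm_test
#' @export
tidy.ggm_test <- function(x, ...) {
  p <- length(x$genes)
  tibble::tibble(
    gene = x$genes,
    gamma = if (ncol(x$gamma) == 1) x$gamma[, 1] else rowSums(x$gamma^2),
    gamma_nb = if (ncol(x$gamma_nb) == 1) x$gamma_nb[, 1] else
      rowSums(x$gamma_nb^2),
    component = x$components,
    p_de = x$pvalues_de, p_dc = x$pvalues_dc,
    de = seq_len(p) %in% x$rejected_de,
    dc = seq_len(p) %in% x$rejected_dc)
}

#' One-row summary of a contrast test
#'
#' @param x a `ggm_test`.
#' @param ... unused.
#' @return tibble with `T_obs`, `p_value`, permutation count, gene counts and
#'   the multiplicity threshold.
#' @method glance ggm_test
#' @export
glance.ggm_test <- function(x, ...) {
  tibble::tibble(
    T_obs = x$T_obs, p_value = x$pvalues_T, n_perm = x$n_perm,
    n_genes = length(x$genes),
    n_de = length(x$rejected_de), n_dc = length(x$rejected_dc),
    threshold = x$threshold)
}

#' Null-distribution plot for the overall statistic
#'
#' Histogram of the permutation null of `T` with the observed value marked.
#'
#' @param object a `ggm_test`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ggm_test
#' @export
autoplot.ggm_test <- function(object, ...) {
  df <- data.frame(T = object$null_T)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$T)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$T_obs, colour = "red") +
    ggplot2::labs(x = "T under permutation null", y = "count",
                  title = sprintf("T = %.3g, p = %.3g", object$T_obs,
                                  object$pvalues_T))
}

#' @importFrom ggplot2 .data
NULL
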