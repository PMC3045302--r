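# Maximum-likelihood fitting of the sparse precision matrix given a zero
# pattern. At the MLE the likelihood equations say: fitted covariances match
# the sample covariances on every edge (and the diagonal) while precision
# entries are exactly zero off the pattern. We solve them by clique-wise
# iterative proportional scaling (IPS), the classical covariance-selection
# fixpoint, which increases the likelihood at every step and converges for
# decomposable and non-decomposable patterns alike.

# Resolve S access: accept a dense/sparse matrix or a residual_bundle.
s_accessor <- function(S) {
  if (inherits(S, "residual_bundle")) {
    R <- S$residuals
    list(block = function(idx) sample_cov_block(R, idx),
         diag = colSums(R^2) / nrow(R), p = ncol(R))
  } else {
    S <- as.matrix(S)
    list(block = function(idx) S[idx, idx, drop = FALSE],
         diag = diag(S), p = nrow(S))
  }
}

#' Does the pattern-constrained MLE exist?
#'
#' The MLE of the precision matrix under a zero pattern exists if and only if
#' the sample covariance restricted to each maximal clique of the pattern
#' graph is positive definite — essentially, every clique must be smaller
#' than the sample size for continuous data.
#'
#' @param S sample covariance: a `p x p` matrix or a [residuals_under()]
#'   bundle (blocks are then computed on demand).
#' @param cliques list of integer vertex sets, the maximal cliques of the
#'   pattern graph (see [maximal_cliques()]); computed from `pattern` if
#'   omitted.
#' @param pattern a `zero_pattern`, used when `cliques` is missing.
#' @param tol positive-definiteness tolerance on the smallest eigenvalue,
#'   relative to the largest clique-block diagonal.
#' @return `TRUE` if every clique block is positive definite.
#' @export
mle_exists <- function(S, cliques = NULL, pattern = NULL, tol = 1e-10) {
  acc <- s_accessor(S)
  if (is.null(cliques)) {
    if (is.null(pattern)) stop("supply cliques or pattern", call. = FALSE)
    cliques <- maximal_cliques(pattern)$cliques
  }
  for (cl in cliques) {
    B <- acc$block(as.integer(cl))
    ev <- min(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= tol * max(diag(B), 1e-300)) return(FALSE)
  }
  TRUE
}

#' Fit the sparse precision matrix by maximum likelihood
#'
#' Solves the likelihood equations for a Gaussian graphical model with the
#' given zero pattern: at convergence the implied covariance matches `S` on
#' every edge and diagonal (`max_edge_gap <= tol`, measured on the
#' correlation scale) and the precision matrix is exactly zero off the
#' pattern support. Iteration is clique-wise proportional scaling starting
#' from `diag(1/s_ii)`; the log-likelihood is non-decreasing across sweeps.
#'
#' The iteration maintains a dense copy of the implied covariance, so the
#' practical range is patterns up to a few thousand genes.
#'
#' @inheritParams mle_exists
#' @param pattern a `zero_pattern` fixing the support.
#' @param tol convergence tolerance for the maximum covariance gap on the
#'   support, correlation scale.
#' @param max_iter maximum number of IPS sweeps.
#' @param n sample size; when supplied the report's `loglik` is the profile
#'   log-likelihood `(n/2)(log det K - tr(K S))`, otherwise just the
#'   bracketed kernel.
#' @return object of class `sparse_precision`: list with `K` (sparse
#'   symmetric positive-definite precision matrix on the pattern support),
#'   `pattern`, and `report` (`loglik`, `max_edge_gap`, `iterations`,
#'   `converged`, `loglik_trace`).
#' @export
fit_precision <- function(S, pattern, tol = 1e-6, max_iter = 500, n = NULL) {
  acc <- s_accessor(S)
  p <- length(pattern$genes)
  if (acc$p != p) stop("S dimension does not match pattern", call. = FALSE)
  cliques <- maximal_cliques(pattern)$cliques
  if (!mle_exists(S, cliques = cliques))
    stop(paste("MLE does not exist: a clique submatrix of S is singular.",
               "Reduce the pattern (smaller kmax) or use more samples."),
         call. = FALSE)

  edges <- pattern_edges(pattern)
  sdiag <- acc$diag
  scale_ij <- function(i, j) sqrt(sdiag[i] * sdiag[j])

  # S on the support, assembled once (edges + diagonal only).
  s_edge <- if (nrow(edges) > 0)
    vapply(seq_len(nrow(edges)),
           function(e) acc$block(c(edges[e, 1], edges[e, 2]))[1, 2],
           numeric(1)) else numeric(0)

  K <- diag(1 / sdiag, p)
  Sigma <- diag(sdiag, p)
  ll_kernel <- function() {
    ch <- chol(K)
    tr <- sum(diag(K) * sdiag) + 2 * sum(K[edges] * s_edge)
    2 * sum(log(diag(ch))) - tr
  }
  ll_trace <- ll_kernel()

  s_blocks <- lapply(cliques, function(cl) acc$block(as.integer(cl)))
  gap <- Inf
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    for (ci in seq_along(cliques)) {
      cl <- as.integer(cliques[[ci]])
      Scc <- s_blocks[[ci]]
      Sig_cc <- Sigma[cl, cl, drop = FALSE]
      Delta <- chol2inv(chol(Scc)) - chol2inv(chol(Sig_cc))
      Delta <- (Delta + t(Delta)) / 2
      step <- 1
      repeat {
        Kc <- K
        Kc[cl, cl] <- Kc[cl, cl] + step * Delta
        # Woodbury update of Sigma; (I + D Sig_cc)^{-1} D avoids inverting D
        M <- tryCatch(
          solve(diag(length(cl)) + step * Delta %*% Sig_cc, step * Delta),
          error = function(e) NULL)
        ok <- !is.null(M) && all(diag(Sigma) - rowSums((Sigma[, cl] %*% M) *
                                                         Sigma[, cl]) > 0)
        if (ok) {
          K <- Kc
          A <- Sigma[, cl, drop = FALSE]
          Sigma <- Sigma - A %*% M %*% t(A)
          break
        }
        step <- step / 2
        if (step < 1e-8) break  # degenerate; keep current iterate
      }
    }
    # refresh Sigma from K once per sweep to stop roundoff accumulating
    Sigma <- chol2inv(chol(K))
    ll_trace <- c(ll_trace, ll_kernel())
    gap <- max(abs(diag(Sigma) - sdiag) / sdiag,
               if (nrow(edges) > 0)
                 abs(Sigma[edges] - s_edge) /
                   scale_ij(edges[, 1], edges[, 2]) else 0)
    if (gap <= tol) break
  }

  Ksp <- support_sparse(K, pattern, edges)
  report <- list(
    loglik = if (is.null(n)) ll_trace[length(ll_trace)] else
      (n / 2) * ll_trace[length(ll_trace)],
    max_edge_gap = gap, iterations = it, converged = gap <= tol,
    loglik_trace = ll_trace)
  if (!report$converged)
    warning(sprintf("IPS did not converge in %d sweeps (gap %.2e)", it, gap),
            call. = FALSE)
  new_sparse_precision(Ksp, pattern, report)
}

# Dense symmetric K restricted exactly to the pattern support -> dsCMatrix.
support_sparse <- function(K, pattern, edges = pattern_edges(pattern)) {
  p <- length(pattern$genes)
  i <- c(seq_len(p), edges[, 1])
  j <- c(seq_len(p), edges[, 2])
  Ksp <- Matrix::sparseMatrix(i = i, j = j, x = K[cbind(i, j)],
                              dims = c(p, p), symmetric = TRUE)
  dimnames(Ksp) <- list(pattern$genes, pattern$genes)
  Ksp
}

new_sparse_precision <- function(K, pattern, report = NULL) {
  structure(list(K = K, pattern = pattern, report = report),
            class = "sparse_precision")
}

#' Wrap a precision matrix as a fitted object
#'
#' Accepts any symmetric positive-definite sparse/dense matrix (e.g. a truth
#' from [generate_precision()]) so it can be used where a fitted
#' `sparse_precision` is expected.
#'
#' @param K symmetric positive-definite matrix.
#' @param genes optional labels.
#' @return a `sparse_precision` object whose pattern is the support of `K`.
#' @export
as_sparse_precision <- function(K, genes = NULL) {
  K <- Matrix::forceSymmetric(methods::as(K, "CsparseMatrix"))
  pattern <- as_zero_pattern((K != 0) * 1, genes = genes)
  dimnames(K) <- list(pattern$genes, pattern$genes)
  new_sparse_precision(K, pattern)
}

#' @method print sparse_precision
#' @export
print.sparse_precision <- function(x, ...) {
  p <- nrow(x$K)
  cat(sprintf("<sparse_precision> %d genes, %d edges\n", p,
              (Matrix::nnzero(x$K) - p) / 2))
  if (!is.null(x$report))
    cat(sprintf("  converged: %s after %d sweeps (max edge gap %.2e)\n",
                x$report$converged, x$report$iterations, x$report$max_edge_gap))
  invisible(x)
}

#' @method glance sparse_precision
#' @export
glance.sparse_precision <- function(x, ...) {
  p <- nrow(x$K)
  tibble::tibble(
    p = p, edges = (Matrix::nnzero(x$K) - p) / 2,
    loglik = if (is.null(x$report)) NA_real_ else x$report$loglik,
    max_edge_gap = if (is.null(x$report)) NA_real_ else x$report$max_edge_gap,
    iterations = if (is.null(x$report)) NA_integer_ else x$report$iterations,
    converged = if (is.null(x$report)) NA else x$report$converged)
}

#' Conditional-regression view of a precision matrix
#'
#' In a Gaussian graphical model the regression of gene `i` on all others has
#' coefficients `beta_ij = -K_ij / K_ii` (non-zero exactly on the neighbours
#' of `i`) and residual variance `1 / K_ii`.
#'
#' @param K a `sparse_precision` or a symmetric positive-definite matrix.
#' @return list with `beta` (sparse `p x p`, zero diagonal) and `resid_var`.
#' @export
conditional_regressions <- function(K) {
  Km <- if (inherits(K, "sparse_precision")) K$K else
    Matrix::forceSymmetric(methods::as(K, "CsparseMatrix"))
  d <- Matrix::diag(Km)
  if (any(d <= 0)) stop("precision matrix must have positive diagonal",
                        call. = FALSE)
  beta <- -Km / d            # row-scale: beta[i, j] = -K[i, j]/K[i, i]
  Matrix::diag(beta) <- 0
  list(beta = Matrix::drop0(beta), resid_var = 1 / d)
}

#' Regression-only approximation of the precision matrix
#'
#' Estimates precision entries without solving the likelihood equations: each
#' gene is regressed (OLS) on its pattern neighbours, then the identities
#' `beta_ij = -K_ij/K_ii`, `v_i^2 = 1/K_ii` are inverted to fill in the
#' entries. The assembled matrix need not be symmetric nor positive definite,
#' so it is symmetrised by averaging and returned together with the
#' asymmetry magnitude and a definiteness flag. Consistent when the
#' neighbour structure is correct and `n` grows, and useful as a cheap
#' large-scale alternative to [fit_precision()].
#'
#' @param x data matrix (`n x p`), typically residuals after the design.
#' @param pattern a `zero_pattern`.
#' @return list with `K` (symmetrised sparse estimate), `asymmetry`
#'   (max absolute difference between `K` and its transpose before
#'   averaging), `positive_definite` (logical).
#' @export
regression_approx_precision <- function(x, pattern) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (p != length(pattern$genes)) stop("dimension mismatch", call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  Ng <- pattern$N
  trip <- vector("list", p)
  for (i in seq_len(p)) {
    nb <- setdiff(which(Ng[i, ] != 0), i)
    if (length(nb) >= n)
      stop(sprintf("gene %d has %d neighbours but only %d samples", i,
                   length(nb), n), call. = FALSE)
    if (length(nb) == 0) {
      kii <- 1 / (sum(xc[, i]^2) / n)
      trip[[i]] <- cbind(i, i, kii)
    } else {
      fit <- lm.fit(xc[, nb, drop = FALSE], xc[, i])
      v2 <- sum(fit$residuals^2) / n
      kii <- 1 / v2
      trip[[i]] <- rbind(cbind(i, i, kii), cbind(i, nb, -fit$coefficients * kii))
    }
  }
  trip <- do.call(rbind, trip)
  Kraw <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                               dims = c(p, p))
  asym <- max(abs(Kraw - Matrix::t(Kraw)))
  K <- Matrix::forceSymmetric((Kraw + Matrix::t(Kraw)) / 2)
  pd <- tryCatch({ Matrix::chol(K); TRUE }, error = function(e) FALSE)
  list(K = K, asymmetry = asym, positive_definite = pd)
}

#' Profile log-likelihood of a precision matrix
#'
#' `L = (n/2) (log det K - tr(K S))`; the trace uses only entries of `S` on
#' the support of `K`, and the log-determinant comes from a sparse Cholesky
#' factorisation.
#'
#' @param K `sparse_precision` or symmetric positive-definite matrix.
#' @param S sample covariance matrix or [residuals_under()] bundle.
#' @param n sample size.
#' @return log-likelihood value (scalar).
#' @export
log_likelihood <- function(K, S, n) {
  Km <- if (inherits(K, "sparse_precision")) K$K else
    Matrix::forceSymmetric(methods::as(K, "CsparseMatrix"))
  acc <- s_accessor(S)
  Kt <- methods::as(methods::as(Km, "TsparseMatrix"), "generalMatrix")
  up <- Kt@i < Kt@j
  tr <- sum(Matrix::diag(Km) * acc$diag)
  if (any(up)) {
    ii <- Kt@i[up] + 1L; jj <- Kt@j[up] + 1L
    sij <- vapply(seq_along(ii),
                  function(e) acc$block(c(ii[e], jj[e]))[1, 2], numeric(1))
    tr <- tr + 2 * sum(Kt@x[up] * sij)
  }
  ld <- as.numeric(Matrix::determinant(Km, logarithm = TRUE)$modulus)
  (n / 2) * (ld - tr)
}
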