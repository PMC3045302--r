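#' Validate an expression matrix
#'
#' The model works on an `n x p` matrix `X` of expression values with samples
#' in rows and genes in columns: each row is multivariate normal with mean
#' determined by the design and common covariance `Sigma`. This helper checks
#' the invariants every downstream step relies on (numeric, no missing values,
#' at least two samples, unique gene identifiers) and fills in identifiers
#' when absent.
#'
#' @param x numeric matrix, samples in rows and genes in columns.
#' @param genes_in_rows if `TRUE`, `x` is transposed first.
#' @return the validated matrix with `dimnames` set (samples `s1..sn`, genes
#'   `g1..gp` when unnamed).
#' @export
as_expression_matrix <- function(x, genes_in_rows = FALSE) {
  x <- as.matrix(x)
  if (genes_in_rows) x <- t(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric", call. = FALSE)
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value in expression matrix at row %d, column %d",
                 idx[1], idx[2]), call. = FALSE)
  }
  if (nrow(x) < 2) stop("need at least two samples", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("g", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  if (anyDuplicated(colnames(x)))
    stop("duplicate gene identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  x
}

check_design <- function(D, n) {
  D <- as.matrix(D)
  if (!is.numeric(D)) stop("design matrix must be numeric", call. = FALSE)
  if (nrow(D) != n)
    stop(sprintf("design has %d rows but expression has %d samples", nrow(D), n),
         call. = FALSE)
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    dep <- setdiff(seq_len(ncol(D)), qd$pivot[seq_len(qd$rank)])
    lab <- if (!is.null(colnames(D))) colnames(D)[dep] else as.character(dep)
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(lab, collapse = ", "), call. = FALSE)
  }
  D
}

#' Maximum-likelihood estimate of the treatment-effect matrix
#'
#' For the model `vec(X) ~ N(vec(DB), I (x) Sigma)` the MLE of the (r x p)
#' coefficient matrix is `B = (D'D)^{-1} D'X`, i.e. each gene (column of `X`)
#' is regressed on the design separately; the estimate does not depend on
#' `Sigma`. Computed via the QR decomposition of `D`.
#'
#' @param x expression matrix (`n x p`, samples by genes).
#' @param design design matrix (`n x r`), full column rank.
#' @return an (r x p) coefficient matrix.
#' @examples
#' x <- matrix(rnorm(20), 5, 4)
#' estimate_coefficients(x, cbind(1, rnorm(5)))
#' @export
estimate_coefficients <- function(x, design) {
  x <- as_expression_matrix(x)
  D <- check_design(design, nrow(x))
  B <- qr.coef(qr(D), x)
  rownames(B) <- colnames(D)
  B
}

#' Residuals after projecting out a design
#'
#' Computes fitted values `F = D1 (D1'D1)^{-1} D1' X` (the orthogonal
#' projection of each gene onto the column space of `design`) and residuals
#' `R = X - F`. These are the building blocks of the sample covariance
#' `S = R'R/n` and of the residual-permutation null.
#'
#' @inheritParams estimate_coefficients
#' @return an object of class `residual_bundle`: list with `residuals` (R),
#'   `fitted` (F), `n`, and `scov(i, j)`, a function returning entries of
#'   `S = R'R/n` on demand so the dense `p x p` matrix is never required.
#' @export
residuals_under <- function(x, design) {
  x <- as_expression_matrix(x)
  D <- check_design(design, nrow(x))
  qd <- qr(D)
  Fhat <- qr.fitted(qd, x)
  R <- x - Fhat
  structure(
    list(residuals = R, fitted = Fhat, n = nrow(x),
         scov = function(i, j) sample_cov_entry(R, i, j)),
    class = "residual_bundle")
}

#' @method print residual_bundle
#' @export
print.residual_bundle <- function(x, ...) {
  cat(sprintf("<residual_bundle> %d samples x %d genes (S divisor n = %d)\n",
              nrow(x$residuals), ncol(x$residuals), x$n))
  invisible(x)
}

#' Entries of the sample covariance S = R'R/n
#'
#' The maximum-likelihood sample covariance uses divisor `n` (not `n - 1`),
#' matching the likelihood equations the precision fit solves. `i` and `j`
#' may be vectors; a cross-block is returned.
#'
#' @param R residual matrix (`n x p`).
#' @param i,j gene indices (integer vectors).
#' @return matrix of `S[i, j]` values (scalar if both are scalars).
#' @export
sample_cov_entry <- function(R, i, j) {
  p <- ncol(R)
  if (any(i < 1 | i > p) || any(j < 1 | j > p))
    stop("gene index out of range", call. = FALSE)
  out <- crossprod(R[, i, drop = FALSE], R[, j, drop = FALSE]) / nrow(R)
  if (length(i) == 1L && length(j) == 1L) drop(out) else out
}

# S restricted to a set of genes, as a dense block.
sample_cov_block <- function(R, idx) {
  crossprod(R[, idx, drop = FALSE]) / nrow(R)
}
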