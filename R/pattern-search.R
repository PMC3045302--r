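#' Forward-stepwise regression path for one gene
#'
#' Greedy forward selection: at each step the predictor giving the largest
#' reduction in residual sum of squares (equivalently, largest squared
#' correlation with the current residual) is added, up to `kmax` terms. Ties
#' are broken towards the lowest column index. Constant (zero-variance)
#' columns are skipped and reported. The path records the maximum-likelihood
#' residual variance `sigma2(k) = RSS(k)/n` for `k = 0..kmax`, the quantity
#' the BIC criteria are computed from.
#'
#' @param y response vector, length `n`.
#' @param z predictor matrix `n x m`; columns are centred internally (and the
#'   response too) so the fit is with intercept.
#' @param kmax maximum model size; must satisfy `1 <= kmax < n`.
#' @param standardize scale predictor columns to unit variance before
#'   selection (selection only; residual variances are unaffected by scaling).
#' @return object of class `stepwise_path`: list with `selected` (indices in
#'   selection order, possibly shorter than `kmax` if the path stops early),
#'   `resid_var` (length `kmax + 1`, `NA` beyond the stopping point), `n`,
#'   `kmax`, and `skipped` (indices of constant columns).
#' @export
forward_stepwise <- function(y, z, kmax, standardize = TRUE) {
  z <- as.matrix(z)
  n <- length(y)
  if (nrow(z) != n) stop("nrow(z) must equal length(y)", call. = FALSE)
  if (kmax < 1) stop("kmax must be >= 1", call. = FALSE)
  if (kmax >= n) stop("kmax must be smaller than the sample size (saturation)",
                      call. = FALSE)
  yc <- y - mean(y)
  zc <- sweep(z, 2, colMeans(z))
  ss <- colSums(zc^2)
  skipped <- which(ss <= 1e-12 * max(ss, 1))
  if (standardize) {
    sc <- sqrt(ss / n)
    sc[sc == 0] <- 1
    zc <- sweep(zc, 2, sc, "/")
  }
  eng <- .fs_single(zc, yc, as.integer(kmax), 1e-12)
  sel <- as.integer(eng$selected)[!is.na(eng$selected)]
  rv <- as.numeric(eng$rss) / n
  structure(
    list(selected = as.integer(sel), resid_var = rv, n = n,
         kmax = as.integer(kmax), skipped = as.integer(skipped)),
    class = "stepwise_path")
}

#' @method print stepwise_path
#' @export
print.stepwise_path <- function(x, ...) {
  cat(sprintf("<stepwise_path> n = %d, kmax = %d, selected: %s\n",
              x$n, x$kmax, paste(x$selected, collapse = " ")))
  invisible(x)
}

#' Modified BIC for high-dimensional variable selection
#'
#' `bic_gamma()` is `n log sigma2(k) + k log n + 2 gamma log C(p, k)`, the
#' usual BIC (`gamma = 0`) plus a penalty proportional to the log of the
#' number of size-`k` subsets of the `p` candidate predictors; `gamma = 1` is
#' the recommended setting when `p >> n`, as it controls false selections.
#' `bic_2p()` is the variant `n log sigma2(k) + 2 k log p`. The log-binomial
#' term uses [lchoose()] (log-gamma), never factorials. A zero residual
#' variance (perfect fit) yields `-Inf`: a perfect fit cannot be beaten.
#'
#' @param n sample size.
#' @param k model size (number of predictors), `0 <= k < p_choices`.
#' @param p_choices number of candidate predictors `p`.
#' @param resid_var_k maximum-likelihood residual variance at size `k`.
#' @param gamma penalty weight in `[0, 1]`.
#' @return the criterion value (scalar; vectorised over `k`/`resid_var_k`).
#' @export
bic_gamma <- function(n, k, p_choices, resid_var_k, gamma = 1) {
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]", call. = FALSE)
  ifelse(resid_var_k <= 0, -Inf,
         n * log(resid_var_k) + k * log(n) + 2 * gamma * lchoose(p_choices, k))
}

#' @rdname bic_gamma
#' @export
bic_2p <- function(n, k, p_choices, resid_var_k) {
  ifelse(resid_var_k <= 0, -Inf,
         n * log(resid_var_k) + 2 * k * log(p_choices))
}

criterion_fun <- function(criterion) {
  criterion <- match.arg(criterion, c("bic1.0", "bic0.5", "bic0.0", "bic2p"))
  switch(criterion,
    bic1.0 = function(n, k, p, rv) bic_gamma(n, k, p, rv, gamma = 1),
    bic0.5 = function(n, k, p, rv) bic_gamma(n, k, p, rv, gamma = 0.5),
    bic0.0 = function(n, k, p, rv) bic_gamma(n, k, p, rv, gamma = 0),
    bic2p  = function(n, k, p, rv) bic_2p(n, k, p, rv))
}

#' Choose a model size along a stepwise path
#'
#' Evaluates the criterion at every size `k = 0..kmax` reached by the path and
#' returns the minimiser; ties go to the smallest `k`. A size with zero
#' residual variance scores `-Inf` and is therefore selected (smallest such
#' `k` wins).
#'
#' @param path a [forward_stepwise()] result.
#' @param p_choices number of candidate predictors the path chose from.
#' @param criterion `"bic1.0"`, `"bic0.5"`, `"bic0.0"` or `"bic2p"`.
#' @return the selected size `k*` (integer scalar).
#' @export
select_size <- function(path, p_choices, criterion = "bic1.0") {
  crit <- criterion_fun(criterion)
  rv <- path$resid_var
  ks <- which(!is.na(rv)) - 1L
  vals <- crit(path$n, ks, p_choices, rv[ks + 1L])
  ks[which.min(vals)]
}

#' Determine the zero pattern of the precision matrix
#'
#' For each gene in turn, runs forward-stepwise selection of the other genes
#' as predictors up to `kmax` terms, picks the model size minimising the
#' chosen BIC variant, and records the selected predictors in the neighbour
#' matrix `A` (`A[i, j] = 1` iff gene `j` predicts gene `i`). The zero
#' pattern is the symmetrisation `N = A + A'` with unit diagonal: gene pairs
#' off the support of `N` are the entries of the inverse covariance matrix
#' constrained to zero.
#'
#' When a design matrix is supplied the selection runs on the residuals after
#' projecting out the mean structure (the covariance model describes residual
#' variation); set `use_residuals = FALSE` to select on the raw columns.
#'
#' @param x expression matrix (`n x p`).
#' @param design optional design matrix whose mean structure is removed first.
#' @param kmax maximum neighbours per gene; default `floor(n/20)` (at least
#'   1), following the guidance of at most one parameter per 20 observations.
#'   A warning is issued when `kmax/n > 1/20`.
#' @param criterion BIC variant, see [select_size()].
#' @param standardize standardise columns before selection (default `TRUE`).
#' @param use_residuals project out `design` before selection.
#' @return object of class `zero_pattern`: list with `N` (p x p sparse
#'   symmetric 0/1 pattern with unit diagonal), `A` (the asymmetric neighbour
#'   matrix), `neighbour_sizes` (off-diagonal row counts of `N`), `genes`,
#'   `kmax`, `criterion`, `sizes` (per-gene selected model size).
#' @export
find_pattern <- function(x, design = NULL, kmax = NULL,
                         criterion = "bic1.0", standardize = TRUE,
                         use_residuals = TRUE) {
  x <- as_expression_matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (p < 2) stop("need at least two genes", call. = FALSE)
  if (!is.null(design) && use_residuals)
    x <- residuals_under(x, design)$residuals
  if (is.null(kmax)) kmax <- max(1L, floor(n / 20))
  kmax <- as.integer(kmax)
  if (kmax >= n) stop("kmax must be smaller than the sample size", call. = FALSE)
  if (kmax / n > 1 / 20 + 1e-12)
    warning(sprintf("kmax/n = %.3f exceeds the recommended 1/20", kmax / n),
            call. = FALSE)
  paths <- stepwise_all(x, kmax, standardize)
  sizes <- select_sizes_from(paths, p_choices = p - 1L, criterion = criterion)
  pattern_from_sizes(paths$selected, sizes, genes = colnames(x),
                     kmax = kmax, criterion = criterion)
}

# Run the C++ all-genes stepwise engine on centred (optionally standardised)
# columns; returns the raw selection and RSS matrices plus n.
stepwise_all <- function(x, kmax, standardize = TRUE) {
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  if (standardize) {
    sc <- sqrt(colSums(xc^2) / n)
    sc[sc == 0] <- 1
    xc <- sweep(xc, 2, sc, "/")
  }
  eng <- .fs_all(xc, as.integer(kmax), 1e-12)
  list(selected = eng$selected, rss = eng$rss, n = n, kmax = kmax)
}

select_sizes_from <- function(paths, p_choices, criterion) {
  crit <- criterion_fun(criterion)
  n <- paths$n
  rv <- paths$rss / n
  vapply(seq_len(nrow(rv)), function(i) {
    ks <- which(!is.na(rv[i, ])) - 1L
    ks[which.min(crit(n, ks, p_choices, rv[i, ks + 1L]))]
  }, integer(1))
}

pattern_from_sizes <- function(selected, sizes, genes, kmax, criterion) {
  p <- nrow(selected)
  ii <- rep.int(seq_len(p), sizes)
  jj <- unlist(lapply(seq_len(p), function(i) {
    if (sizes[i] > 0) selected[i, seq_len(sizes[i])] else integer(0)
  }), use.names = FALSE)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(p, p))
  new_zero_pattern(A, genes = genes, kmax = kmax, criterion = criterion,
                   sizes = sizes)
}

new_zero_pattern <- function(A, genes = NULL, kmax = NA_integer_,
                             criterion = NA_character_, sizes = NULL) {
  p <- nrow(A)
  N <- A + Matrix::t(A) + Matrix::Diagonal(p)
  N <- methods::as(Matrix::forceSymmetric((N != 0) * 1), "CsparseMatrix")
  if (is.null(genes)) genes <- paste0("g", seq_len(p))
  dimnames(N) <- list(genes, genes)
  structure(
    list(N = N, A = A, genes = genes,
         neighbour_sizes = Matrix::rowSums(N != 0) - 1L,
         sizes = sizes, kmax = kmax, criterion = criterion),
    class = "zero_pattern")
}

#' Build a zero pattern from a symmetric support matrix
#'
#' @param N symmetric `p x p` matrix (any non-zero entry is an edge); the
#'   diagonal is forced to 1.
#' @param genes optional gene labels.
#' @return a `zero_pattern` object.
#' @export
as_zero_pattern <- function(N, genes = NULL) {
  N <- methods::as(N, "CsparseMatrix")
  if (!Matrix::isSymmetric(N))
    stop("pattern support must be symmetric", call. = FALSE)
  A <- Matrix::tril((N != 0) * 1, k = -1)
  new_zero_pattern(A + Matrix::t(A), genes = genes)
}

#' @method print zero_pattern
#' @export
print.zero_pattern <- function(x, ...) {
  ns <- x$neighbour_sizes
  cat(sprintf("<zero_pattern> %d genes, %d edges (criterion %s, kmax %s)\n",
              length(x$genes), (Matrix::nnzero(x$N) - length(x$genes)) / 2,
              x$criterion, x$kmax))
  cat(sprintf("  neighbour sizes: median %g, 90%% in [%g, %g], max %g\n",
              stats::median(ns), stats::quantile(ns, .05), stats::quantile(ns, .95),
              max(ns)))
  invisible(x)
}

# Off-diagonal edge list (i < j) of a zero_pattern.
pattern_edges <- function(pattern) {
  Nt <- methods::as(methods::as(pattern$N, "TsparseMatrix"), "generalMatrix")
  keep <- Nt@i < Nt@j
  cbind(i = Nt@i[keep] + 1L, j = Nt@j[keep] + 1L)
}
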