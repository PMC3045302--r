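# Simulator for sparse precision matrices with controlled median neighbour
# size, multivariate-normal sampling through the sparse Cholesky factor, and
# pattern-recovery scoring. The generating recipe:
#   1. pick ~q off-diagonal slots per row of a neighbour matrix A and
#      symmetrise to a support N = A + A' (neighbour sizes therefore vary
#      around q);
#   2. draw edge values with magnitudes in [0.5, 1] (sign-symmetric by
#      default, excluding near-zero values);
#   3. set diagonal i to d * sum_j |K_ij|, stepping d down from 1 by 0.05 and
#      keeping the smallest d for which the matrix is still positive
#      definite (improves the signal-to-noise ratio of a merely diagonally
#      dominant matrix).

# Strict positive definiteness via sparse Cholesky, with a small relative
# margin so matrices that are singular up to roundoff (e.g. exactly balanced
# components at d = 1) are rejected rather than accepted on cancellation
# noise.
pd_chol_ok <- function(K, margin = 1e-8) {
  delta <- margin * max(Matrix::diag(K))
  Ks <- K - Matrix::Diagonal(nrow(K), delta)
  !inherits(tryCatch(Matrix::Cholesky(Ks, perm = TRUE, LDL = FALSE,
                                      super = FALSE),
                     error = function(e) e, warning = function(w) w),
            c("error", "warning"))
}

sim_support <- function(p, q) {
  qi <- rep.int(floor(q), p) + stats::rbinom(p, 1, q - floor(q))
  jj <- unlist(lapply(seq_len(p), function(i) {
    if (qi[i] == 0) return(integer(0))
    s <- sample.int(p - 1L, qi[i])
    s + (s >= i)  # skip the diagonal slot
  }), use.names = FALSE)
  ii <- rep.int(seq_len(p), qi)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(p, p))
  new_zero_pattern(A)
}

#' Generate a sparse precision matrix with controlled neighbour sizes
#'
#' @param p number of genes.
#' @param q expected number of off-diagonal slots drawn per row before
#'   symmetrisation; may be fractional (each row uses `floor(q)` plus a
#'   Bernoulli remainder). Ignored when `m` is given.
#' @param m target median neighbour size; when supplied, `q` is calibrated by
#'   a small pilot search over the support-generation step alone.
#' @param interval `"sign_symmetric"` draws magnitudes uniformly in
#'   `[0.5, 1]` with a random sign; `"printed"` draws uniformly over
#'   `[-1, 0.5] U [0.5, 1]`.
#' @param d_step step for the diagonal-scaling search (from 1 downwards).
#' @param seed optional integer seed.
#' @return object of class `sim_model`: list with `K` (sparse symmetric
#'   positive-definite precision), `pattern` (`zero_pattern` of its support),
#'   `d_used`, `q`, and `neighbour_sizes`.
#' @export
generate_precision <- function(p, q = NULL, m = NULL,
                               interval = c("sign_symmetric", "printed"),
                               d_step = 0.05, seed = NULL) {
  set_local_seed(seed)
  interval <- match.arg(interval)
  if (is.null(q)) {
    if (is.null(m)) stop("supply q or m", call. = FALSE)
    q <- calibrate_q(p, m)
  }
  if (q < 0.5) stop("q must be at least 0.5", call. = FALSE)
  pattern <- sim_support(p, q)
  edges <- pattern_edges(pattern)
  ne <- nrow(edges)
  vals <- if (interval == "sign_symmetric") {
    sample(c(-1, 1), ne, replace = TRUE) * runif(ne, 0.5, 1)
  } else {
    u <- runif(ne, 0, 2)
    ifelse(u < 1.5, -1 + u, 0.5 + (u - 1.5))
  }
  off <- Matrix::sparseMatrix(i = edges[, 1], j = edges[, 2], x = vals,
                              dims = c(p, p), symmetric = TRUE)
  rowabs <- Matrix::rowSums(abs(off))
  rowabs[rowabs == 0] <- 1  # isolated gene: unit variance
  d_grid <- rev(seq(d_step, 1, by = d_step))
  d_used <- NA_real_
  K <- NULL
  for (d in d_grid) {
    Kd <- off + Matrix::Diagonal(p, d * rowabs)
    if (pd_chol_ok(Kd)) { d_used <- d; K <- Kd } else break
  }
  if (is.na(d_used)) {
    # d = 1 gives only weak diagonal dominance; a connected component whose
    # signs can be flipped all-negative (any tree, e.g. an isolated pair) is
    # exactly singular there. Inflate the diagonal upwards until PD.
    for (d in seq(1 + d_step, 3, by = d_step)) {
      Kd <- off + Matrix::Diagonal(p, d * rowabs)
      if (pd_chol_ok(Kd)) { d_used <- d; K <- Kd; break }
    }
  }
  if (is.na(d_used))
    stop("no positive-definite diagonal scaling found", call. = FALSE)
  K <- Matrix::forceSymmetric(K)
  dimnames(K) <- list(pattern$genes, pattern$genes)
  structure(
    list(K = K, pattern = pattern, d_used = d_used, q = q,
         neighbour_sizes = pattern$neighbour_sizes),
    class = "sim_model")
}

#' @method print sim_model
#' @export
print.sim_model <- function(x, ...) {
  ns <- x$neighbour_sizes
  cat(sprintf("<sim_model> p = %d, q = %g, d = %g\n", nrow(x$K), x$q,
              x$d_used))
  cat(sprintf("  neighbour sizes: median %g, 90%% in [%g, %g], max %d\n",
              stats::median(ns), stats::quantile(ns, .05),
              stats::quantile(ns, .95), max(ns)))
  invisible(x)
}

# Pilot search for the q giving median neighbour size m; only the support
# step is generated, at a capped dimension, so this is cheap.
calibrate_q <- function(p, m, reps = 3, p_pilot = min(p, 2000)) {
  grid <- seq(max(0.5, m / 2 - 1), m, by = 0.25)
  meds <- vapply(grid, function(q) {
    stats::median(vapply(seq_len(reps), function(r) {
      stats::median(sim_support(p_pilot, q)$neighbour_sizes)
    }, numeric(1)))
  }, numeric(1))
  grid[which.min(abs(meds - m))]
}

#' Sample multivariate-normal data from a precision matrix
#'
#' Draws `n` i.i.d. rows from `N(0, K^{-1})` by solving sparse triangular
#' systems against standard-normal vectors through the permuted Cholesky
#' factor of `K`; the dense inverse is never formed.
#'
#' @param K a `sim_model`, `sparse_precision`, or symmetric positive-definite
#'   (sparse) matrix.
#' @param n number of samples.
#' @param seed optional integer seed.
#' @return `n x p` matrix with gene column names.
#' @export
sample_mvn <- function(K, n, seed = NULL) {
  set_local_seed(seed)
  if (inherits(K, "sim_model")) K <- K$K
  Km <- precision_matrix_of(K)
  p <- nrow(Km)
  ch <- Matrix::Cholesky(Km, perm = TRUE, LDL = FALSE, super = FALSE)
  z <- matrix(rnorm(p * n), p, n)
  # K = P' L L' P  =>  x = P' L^{-T} z  has covariance K^{-1}
  y <- Matrix::solve(ch, z, system = "Lt")
  x <- t(as.matrix(Matrix::solve(ch, y, system = "Pt")))
  colnames(x) <- if (!is.null(rownames(Km))) rownames(Km) else
    paste0("g", seq_len(p))
  rownames(x) <- paste0("s", seq_len(n))
  x
}

#' Confusion matrix between an estimated and a true zero pattern
#'
#' Counts over unordered off-diagonal gene pairs: true/false positives and
#' negatives of edge recovery, plus the derived rates
#' `fp_rate = fp/(fp + tn)` and `fn_rate = fn/(fn + tp)`.
#'
#' @param estimate,truth `zero_pattern` objects (or symmetric support
#'   matrices) of the same dimension.
#' @return one-row tibble with `tp`, `fp`, `fn`, `tn`, `fp_rate`, `fn_rate`.
#' @export
evaluate_pattern <- function(estimate, truth) {
  Ne <- if (inherits(estimate, "zero_pattern")) estimate$N else
    methods::as(estimate, "CsparseMatrix")
  Nt <- if (inherits(truth, "zero_pattern")) truth$N else
    methods::as(truth, "CsparseMatrix")
  p <- nrow(Ne)
  if (nrow(Nt) != p) stop("patterns have different dimensions", call. = FALSE)
  eh <- (Ne != 0); et <- (Nt != 0)
  Matrix::diag(eh) <- FALSE; Matrix::diag(et) <- FALSE
  n_e <- Matrix::nnzero(eh) / 2
  n_t <- Matrix::nnzero(et) / 2
  tp <- Matrix::nnzero(eh & et) / 2
  fp <- n_e - tp
  fn <- n_t - tp
  tn <- p * (p - 1) / 2 - tp - fp - fn
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn,
                 fp_rate = if (fp + tn > 0) fp / (fp + tn) else 0,
                 fn_rate = if (fn + tp > 0) fn / (fn + tp) else 0)
}

#' Pattern-recovery simulation study
#'
#' For each replicate: generate a sparse precision matrix with target median
#' neighbour size `m`, draw multivariate-normal samples at each size in `n`,
#' run the stepwise pattern search once per data set (the path is shared
#' across BIC variants, so variants are compared on identical data), and
#' score the recovered pattern against the truth.
#'
#' @param p number of genes.
#' @param m target median neighbour size.
#' @param n vector of sample sizes.
#' @param criteria BIC variants to compare (see [select_size()]).
#' @param reps number of replicates.
#' @param kmax maximum neighbours per gene in the search; default
#'   `floor(n/20)` for each sample size.
#' @param seed integer seed.
#' @return object of class `ggm_study`: tibble with one row per
#'   rep x n x criterion (`tp`, `fp`, `fn`, `tn`, rates, `d_used`).
#'   `summary()` gives Table-style means with standard deviations.
#' @export
run_study <- function(p, m = 5, n = c(100, 200, 500),
                      criteria = c("bic0.0", "bic0.5", "bic1.0", "bic2p"),
                      reps = 10, kmax = NULL, seed = 1) {
  set_local_seed(seed)
  q <- calibrate_q(p, m)
  rows <- list()
  for (rep in seq_len(reps)) {
    model <- generate_precision(p, q = q)
    for (ni in n) {
      x <- sample_mvn(model, ni)
      km <- if (is.null(kmax)) max(1L, floor(ni / 20)) else kmax
      paths <- stepwise_all(x, kmax = km)
      for (crit in criteria) {
        sizes <- select_sizes_from(paths, p_choices = p - 1L, criterion = crit)
        pat <- pattern_from_sizes(paths$selected, sizes, genes = colnames(x),
                                  kmax = km, criterion = crit)
        cm <- evaluate_pattern(pat, model$pattern)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          rep = rep, n = ni, criterion = crit, kmax = km,
          d_used = model$d_used, cm)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ggm_study", class(out))
  attr(out, "p") <- p; attr(out, "m") <- m; attr(out, "q") <- q
  out
}

#' @method summary ggm_study
#' @export
summary.ggm_study <- function(object, ...) {
  df <- as.data.frame(object)
  agg <- stats::aggregate(df[c("tp", "fp", "fn", "tn", "fp_rate", "fn_rate")],
                          by = df[c("n", "criterion")],
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  out <- data.frame(agg[c("n", "criterion")])
  for (col in c("tp", "fp", "fn", "tn", "fp_rate", "fn_rate")) {
    out[[paste0(col, "_mean")]] <- agg[[col]][, "mean"]
    out[[paste0(col, "_sd")]] <- agg[[col]][, "sd"]
  }
  tibble::as_tibble(out)
}

#' Error-rate trends across sample sizes and BIC variants
#'
#' @param object a `ggm_study`.
#' @param ... unused.
#' @return a ggplot: mean false-negative and false-positive rates (log scale
#'   for the latter) against sample size, one line per criterion.
#' @method autoplot ggm_study
#' @export
autoplot.ggm_study <- function(object, ...) {
  s <- summary(object)
  long <- rbind(
    data.frame(n = s$n, criterion = s$criterion, rate = s$fn_rate_mean,
               which = "false negative rate"),
    data.frame(n = s$n, criterion = s$criterion, rate = pmax(s$fp_rate_mean,
               1e-12), which = "false positive rate (log)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$rate,
                                     colour = .data$criterion)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~which, scales = "free_y") +
    ggplot2::labs(x = "sample size n", y = "rate")
}
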