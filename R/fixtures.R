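# Synthetic two-group datasets with known truth, and the end-to-end pipeline
# binding pattern search, precision fitting and contrast testing together.

#' Generate a two-group dataset with known network and effect truth
#'
#' Draws a sparse precision matrix, samples `n1 + n2` multivariate-normal
#' rows, and shifts the group-1 means so the differential-expression and
#' differential-connection truths are known. With a two-group design and
#' contrast `(1, -1)/sqrt(2)`, the whitened contrast mean is
#' `gamma0 = sqrt(n1 n2 / N) * delta` (with `delta` the mean-difference
#' vector) and the neighbour-corrected mean is `gamma0_i - sum_j beta_ij
#' gamma0_j = (K gamma0)_i / K_ii`.
#'
#' Two effect constructions are available: `"direct"` puts `delta` on the
#' selected genes (those genes are differentially expressed, and generally
#' also differentially connected unless isolated); `"smooth"` sets
#' `delta = Sigma w` with `w` supported on the selected genes, so the
#' contrast field is a weighted neighbour combination everywhere else —
#' many genes are differentially expressed but only the selected ones are
#' differentially connected.
#'
#' @param p number of genes.
#' @param m target median neighbour size for the generated network.
#' @param n1,n2 group sizes.
#' @param effect_genes indices of genes carrying the effect (default none:
#'   a pure-null dataset for calibration).
#' @param delta effect magnitude.
#' @param effect_type `"direct"` or `"smooth"`.
#' @param seed integer seed.
#' @param dir optional directory; when given, expression/design/contrast
#'   TSVs, true pattern and precision (Matrix Market) and a truth table are
#'   written there.
#' @return list with `x`, `labels`, `design`, `contrast`, `model`
#'   (the `sim_model`), `delta_vec`, and `truth` (tibble: `gene`, `gamma0`,
#'   `gamma_nb0`, `de_true`, `dc_true`).
#' @export
make_fixture <- function(p = 50, m = 5, n1 = 20, n2 = 20,
                         effect_genes = integer(0), delta = 1,
                         effect_type = c("direct", "smooth"),
                         seed = NULL, dir = NULL) {
  set_local_seed(seed)
  effect_type <- match.arg(effect_type)
  model <- generate_precision(p, m = m)
  n <- n1 + n2
  x <- sample_mvn(model, n)
  labels <- factor(rep(c("treatment", "control"), c(n1, n2)),
                   levels = c("treatment", "control"))
  delta_vec <- numeric(p)
  if (length(effect_genes) > 0) {
    if (effect_type == "direct") {
      delta_vec[effect_genes] <- delta
    } else {
      w <- numeric(p); w[effect_genes] <- delta
      delta_vec <- as.numeric(Matrix::solve(model$K, w))
    }
    x[seq_len(n1), ] <- sweep(x[seq_len(n1), , drop = FALSE], 2, delta_vec, "+")
  }
  design <- cbind(treatment = as.numeric(labels == "treatment"),
                  control = as.numeric(labels == "control"))
  contrast <- matrix(c(1, -1) / sqrt(2), ncol = 1)
  gamma0 <- sqrt(n1 * n2 / n) * delta_vec
  kg <- as.numeric(model$K %*% gamma0)
  gamma_nb0 <- kg / Matrix::diag(model$K)
  tolz <- 1e-10
  truth <- tibble::tibble(
    gene = colnames(x), gamma0 = gamma0, gamma_nb0 = gamma_nb0,
    de_true = abs(gamma0) > tolz, dc_true = abs(gamma_nb0) > tolz)
  out <- list(x = x, labels = labels, design = design, contrast = contrast,
              model = model, delta_vec = delta_vec, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_expression(x, file.path(dir, "expression.tsv"))
    utils::write.table(design, file.path(dir, "design.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(contrast, file.path(dir, "contrast.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_sparse_symmetric(model$pattern, file.path(dir, "pattern_true.mtx"))
    write_sparse_symmetric(model$K, file.path(dir, "precision_true.mtx"))
    utils::write.table(as.data.frame(truth), file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Sequences the three stages on one dataset: (1) zero-pattern search by
#' stepwise selection on the residuals, (2) maximum-likelihood precision
#' fit, (3) permutation contrast test with DE/DC decomposition. Artifacts
#' are written under `out_dir` when given (pattern and precision as Matrix
#' Market, per-gene results and null quantiles as TSV).
#'
#' @param x expression matrix or path to a TSV.
#' @param design design matrix or path.
#' @param contrast contrast matrix or path.
#' @param out_dir optional output directory.
#' @param kmax,criterion pattern-search settings (see [find_pattern()]).
#' @param tol,max_iter precision-fit settings (see [fit_precision()]).
#' @param n_perm,seed,alpha_expected_fp test settings (see
#'   [permutation_test()]).
#' @return list with `pattern`, `precision`, `test` (a `ggm_test`).
#' @export
run_pipeline <- function(x, design, contrast, out_dir = NULL,
                         kmax = NULL, criterion = "bic1.0",
                         tol = 1e-6, max_iter = 500,
                         n_perm = 1000, seed = 1, alpha_expected_fp = 8) {
  if (is.character(x)) x <- read_expression(x)
  if (is.character(design)) design <- read_design(design)
  if (is.character(contrast)) contrast <- read_design(contrast)
  x <- as_expression_matrix(x)

  message(sprintf("ggmdx %s | p = %d genes, n = %d samples",
                  as.character(utils::packageVersion("ggmdx")),
                  ncol(x), nrow(x)))
  t0 <- Sys.time()
  pattern <- find_pattern(x, design = design, kmax = kmax,
                          criterion = criterion)
  message(sprintf("[pattern] %d edges, kmax = %d (kmax/n = %.3f) [%.1fs]",
                  (Matrix::nnzero(pattern$N) - ncol(x)) / 2, pattern$kmax,
                  pattern$kmax / nrow(x), as.numeric(Sys.time() - t0, "secs")))
  rb <- residuals_under(x, design)
  t0 <- Sys.time()
  prec <- fit_precision(rb, pattern, tol = tol, max_iter = max_iter,
                        n = nrow(x))
  message(sprintf("[fit] converged = %s after %d sweeps [%.1fs]",
                  prec$report$converged, prec$report$iterations,
                  as.numeric(Sys.time() - t0, "secs")))
  t0 <- Sys.time()
  test <- permutation_test(x, design, contrast, prec, n_perm = n_perm,
                           seed = seed,
                           alpha_expected_fp = alpha_expected_fp)
  message(sprintf("[test] %d permutations, seed %d, T = %.4g (p = %.4g) [%.1fs]",
                  n_perm, seed, test$T_obs, test$pvalues_T,
                  as.numeric(Sys.time() - t0, "secs")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sparse_symmetric(pattern, file.path(out_dir, "pattern.mtx"))
    write_neighbour_histogram(pattern, file.path(out_dir,
                                                 "neighbour_sizes.tsv"))
    write_sparse_symmetric(prec, file.path(out_dir, "precision.mtx"))
    utils::write.table(as.data.frame(tidy(test)),
                       file.path(out_dir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(percentile = names(test$null_quantiles),
                 quantile = as.numeric(test$null_quantiles)),
      file.path(out_dir, "null_quantiles.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(sprintf("T\t%.10g", test$T_obs),
                 sprintf("p_value\t%.10g", test$pvalues_T),
                 sprintf("converged\t%s", prec$report$converged),
                 sprintf("max_edge_gap\t%.3e", prec$report$max_edge_gap)),
               file.path(out_dir, "summary.tsv"))
  }
  list(pattern = pattern, precision = prec, test = test)
}
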