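---
title: "Sparse precision networks for expression data: model, estimation, and testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse precision networks for expression data: model, estimation, and testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggmdx)
library(Matrix)
```

## The model

`ggmdx` analyses an n x p expression matrix X (samples by genes) under the
multivariate normal model

    vec(X) ~ N(vec(D B), I (x) Sigma),

where D is an n x r design matrix, B an r x p matrix of treatment effects,
and Sigma the common p x p covariance of a sample's expression profile. The
distinctive assumption is that the *precision matrix* K = Sigma^-1 is
sparse. Zeroes in K have a direct interpretation: K[i, j] = 0 means genes i
and j are conditionally independent given all other genes, and the
regression of gene i on the rest has coefficient beta_ij = -K[i, j]/K[i, i]
on gene j with residual variance 1/K[i, i]. The support of K is therefore an
undirected gene network, and the genes j with K[i, j] != 0 are the
*neighbours* of gene i.

Three estimation/testing stages follow, each with its own function surface.

## Stage 1: finding the zero pattern

With p in the thousands and n around a hundred, the support of K must be
discovered before anything can be fitted. `find_pattern()` runs, for each
gene in turn, greedy forward-stepwise regression on all other genes
(residualised on the design first, since Sigma describes residual
variation; `use_residuals = FALSE` switches to raw columns). The model size
along each path is chosen by a modified BIC,

    BIC_gamma(k) = n log sigma2(k) + k log n + 2 gamma log C(p, k),

where sigma2(k) is the maximum-likelihood residual variance (divisor n)
after k terms and C(p, k) counts the size-k subsets of the candidate pool.
`gamma = 0` is the usual BIC; `gamma = 1` (the default, `"bic1.0"`) adds a
penalty that controls false selections when p >> n. The variant
`"bic2p"` with penalty 2 k log p is also available. The log-binomial term is
computed with `lchoose()`, so p = 20000 poses no overflow problem. The
selections form a neighbour matrix A (A[i, j] = 1 when j predicts i), and
the pattern is the symmetrisation N = A + A' with unit diagonal.

Tunable parameters:

* `kmax` — maximum neighbours per gene, default `floor(n/20)`. The ratio
  kmax/n is the number of parameters per observation in the largest
  regression; above 1/20 the search warns but proceeds. Smaller `kmax`
  always yields a sub-model of a larger one.
* `standardize` — columns are centred always and scaled to unit variance by
  default, so selection is scale-free. Whether to standardise is genuinely
  open (selection on correlations versus covariances); we default to
  standardising because expression platforms mix scales, and expose the
  switch.
* Tie-breaks in the greedy step go to the lowest column index, making the
  search fully deterministic; results do not depend on any parallel
  scheduling because each gene's path is an independent pure computation.
* A perfect fit (zero residual variance, e.g. a duplicated gene) makes the
  criterion -Inf at that size: a perfect fit cannot be beaten, and the path
  stops there.

```{r}
set.seed(1)
gm <- generate_precision(60, m = 4)
x <- sample_mvn(gm, n = 200)
pat <- find_pattern(x, kmax = 6)
pat
evaluate_pattern(pat, gm$pattern)
```

## Stage 2: fitting the precision matrix

Given the pattern, the non-zero entries are estimated by maximum
likelihood. Writing S = R'R/n for the sample covariance of the residuals
(divisor n, matching the likelihood), the profile log-likelihood is

    L = (n/2) { log det K - tr(K S) },

and at its maximum the *likelihood equations* hold: the fitted covariance
equals S entry-wise on every edge and diagonal, while K is exactly zero off
the support. The MLE exists if and only if S restricted to each maximal
clique of the pattern graph is positive definite (`mle_exists()`), which in
practice requires every clique to be small relative to n.

`fit_precision()` solves the equations by clique-wise **iterative
proportional scaling**: cycling over the maximal cliques c, the update
K[c, c] += S[c,c]^-1 - Sigma[c,c]^-1 forces the implied covariance to match
S on that clique. The iteration starts from diag(1/s_ii) (positive definite
and inside the model), increases the likelihood at every step, and
converges for decomposable and non-decomposable patterns alike. Numerical
choices:

* Convergence is declared when the maximum covariance gap on the support,
  measured on the correlation scale (`|sigma_ij - s_ij| / sqrt(s_ii s_jj)`),
  drops below `tol` (default 1e-6).
* Structural zeroes are enforced by the parameterisation itself — entries
  off the support are never touched, so they are exactly zero, not merely
  small.
* Each clique update is applied to a maintained dense copy of the implied
  covariance by a Woodbury identity in the form `(I + Delta Sigma_cc)^{-1}
  Delta`, which stays stable as the update Delta tends to zero; the dense
  copy is refreshed from K once per sweep to stop roundoff accumulating.
  Should an update overshoot (it cannot in exact arithmetic), it is
  step-halved rather than returned.
* Maintaining a dense implied covariance makes the fitter practical for
  patterns up to a few thousand genes. For larger problems
  `regression_approx_precision()` offers the regression-only shortcut —
  OLS of each gene on its neighbours, entries assembled from
  beta_ij = -K_ij/K_ii — which is consistent when the neighbour structure
  is correct but need not be symmetric or positive definite; its asymmetry
  is reported.

```{r}
rb <- residuals_under(x, matrix(1, nrow(x), 1))
fit <- fit_precision(rb, pat, n = nrow(x))
glance(fit)
```

## Stage 3: testing contrasts, DE and DC

A hypothesis C'B = 0 about treatment effects (C an r x s contrast matrix)
is rotated through an orthogonal completion Q = [A C], so that with
Gamma = Q'B the hypothesis reads Gamma_2 = 0 (the last s rows). With
G22 the corresponding block of (D~'D~)^-1, D~ = DQ, the statistic is

    T = trace{ (G22)^-1 Gamma2_hat K Gamma2_hat' },

computed in whitened form T = trace(Gt K Gt'), Gt = L' Gamma2_hat with
L L' = (G22)^-1. Its gene-wise decomposition is the heart of the method:

    T = sum_i  sigma^ii * gamma_i * (gamma_N)_i,

where gamma is a whitened contrast row and (gamma_N)_i = gamma_i - sum_j
beta_ij gamma_j subtracts the weighted combination of the *neighbours'*
contrast values. Large |gamma_i| is differential expression (a marginal
statement); large |(gamma_N)_i| is **differential connection** — the gene's
contrast departs from what its network neighbourhood predicts (a
conditional statement). A gene can be strongly DE yet not DC when its
shift is "smooth" across the network, and vice versa.

Significance comes from a residual permutation null
(`permutation_test()`): fit the mean model under the null (design reduced
to D~_1), permute the rows of the residual matrix, reassemble the data, and
recompute everything, holding K fixed ("conditional on the fitted
precision"). When D~_1 is proportional to the ones vector — any
equal-means null, e.g. the two-group case — the procedure reduces exactly
to permuting the rows of X.

Conventions where the procedure itself leaves choices open:

* Empirical p-values use the add-one convention (1 + #{null >= obs})/(q+1),
  so they are never zero and are valid at any q.
* Per-gene DE and DC tests are two-sided (absolute values) for s = 1; for
  s > 1 the per-gene statistics are sums of squares over contrast rows,
  matching the trace structure of T, and one-sided.
* Permutations are sampled uniformly with replacement from the permutation
  group; q is typically far below n!.
* Multiplicity is controlled over the combined family of 2p DE + DC tests
  with the modified Bonferroni rule p < alpha/m, where alpha may exceed 1
  and bounds the expected number of false rejections under any dependence.
  With p = 20000 genes and alpha = 8 the working threshold is
  8/40000 = .0002.

```{r}
fx <- make_fixture(p = 40, m = 4, n1 = 20, n2 = 20,
                   effect_genes = 1:3, delta = 1.5, seed = 2)
tt <- two_group_test(fx$x, fx$labels, fit_precision(
  residuals_under(fx$x, fx$design), fx$model$pattern, n = 40),
  n_perm = 500, seed = 3)
glance(tt)
head(tidy(tt))
```

The fitted network is also a graph to query: `maximal_cliques()`
(Bron–Kerbosch via igraph), `neighbourhood()` (the ball of radius r around
a gene), `flagged_clusters()` (components of the subgraph induced by, say,
the DE genes), and `shortest_gene_path()`/`nearest_flagged()` for
path queries, with `write_gene_graph()` exporting GraphML or edge lists.

## The simulator and what it does (and does not) emulate

`generate_precision()` builds ground-truth precision matrices by the
three-step recipe: (1) draw ~q off-diagonal support slots per row and
symmetrise, so realised neighbour sizes vary around q; (2) give each edge a
magnitude uniform in [0.5, 1] with random sign, excluding near-zero values
that would make edges undetectable in principle (an option draws from the
asymmetric interval [-1, 0.5] U [0.5, 1] instead); (3) set diagonal i to
d times the absolute off-diagonal row sum, stepping d down from 1 in steps
of 0.05 and keeping the smallest value that is still positive definite —
full diagonal dominance (d = 1) has a poor signal-to-noise ratio, and
shrinking d sharpens it. Positive definiteness is tested by sparse Cholesky
with a small relative margin, so matrices singular to machine precision
(exactly balanced components, which occur at d = 1 for tree-shaped
components in small graphs) are rejected; if d = 1 itself fails in such a
degenerate small case, the diagonal is inflated upwards instead. The target
*median* neighbour size m is hit by calibrating q with a cheap pilot search
over the support step alone; q may be fractional (rows draw floor(q) plus a
Bernoulli remainder) because integer q moves the median in jumps of about
two. At p = 5000 and m = 5 the calibration lands on q = 2.5, the realised
median is 5, and roughly 90% of neighbour sizes fall in [3, 8].

`sample_mvn()` draws N(0, K^-1) rows by back-solving the permuted sparse
Cholesky factor of K against standard normal vectors; the dense inverse is
never formed. The generated data are exactly multivariate normal with zero
mean: the simulator exercises structure recovery and test calibration, not
heavy tails, outliers, batch effects, or platform noise — passing tests on
it says the algorithms are correct under the model, not that real
microarray data satisfy the model. Transformation toward normality is out
of scope.

`run_study()` orchestrates generate → sample → search → score over
replicates, sharing each gene's stepwise path across BIC variants so the
criteria are compared on identical data, and reports Table-style mean (sd)
confusion cells over unordered gene pairs. The full factorial at p up to
20000 is an opt-in long-running mode; the packaged tests run the identical
code path at p = 500 (10 replicates, n in {100, 500}), where the
qualitative conclusions — false negatives fall sharply with n, the plain
BIC buys its lower false-negative rate with a flood of false positives —
reproduce in about a minute. Problem sizes used elsewhere in the suite:
null calibration uses 200 datasets of 40 samples by 30 genes at 200
permutations each; precision recovery uses p = 50 with n in
{100, 500, 2000} over 10 seeds.

## Known limitations

* The IPS fitter keeps a dense p x p implied covariance: memory is the
  binding constraint beyond a few thousand genes. The regression
  approximation and the pattern search itself scale much further.
* The permutation null conditions on the fitted K; uncertainty in the
  pattern and in K is not propagated into the test.
* Chi-square asymptotics for T are deliberately not offered — with an
  estimated, possibly misspecified K the permutation null is the honest
  reference.
* Gene labels are opaque strings; annotation, normalisation and missing
  values are upstream concerns.
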