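Package: ggmdx
Title: Sparse Gaussian Graphical Models for Differential Expression and
    Differential Connection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate analysis of gene expression data using sparse
    inverse covariance (precision) matrices. Determines the zero pattern of
    the precision matrix by per-gene forward-stepwise regression with a
    modified BIC, fits the non-zero entries by maximum likelihood (clique-wise
    iterative proportional scaling), and tests linear contrasts of treatment
    effects with a residual-permutation null that decomposes gene-wise into
    differential-expression and differential-connection components. Includes
    a simulator for sparse precision matrices with controlled median
    neighbour size, pattern-recovery scoring, and graph queries (maximal
    cliques, neighbourhoods, clusters of flagged genes, shortest paths) on
    the fitted gene network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    stats,
    methods,
    utils,
    tibble,
    generics,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
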