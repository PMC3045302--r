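# Shared fixtures and independent oracles used across the suite.

# The worked 5-gene pattern: edges 1-2, 1-4, 2-3, 2-5, 3-4, 3-5, 4-5,
# whose maximal cliques are {1,2}, {1,4}, {2,3,5}, {3,4,5}.
five_gene_pattern <- function() {
  N <- matrix(0, 5, 5)
  edges <- rbind(c(1, 2), c(1, 4), c(2, 3), c(2, 5), c(3, 4), c(3, 5), c(4, 5))
  N[edges] <- 1
  as_zero_pattern(N + t(N) + diag(5))
}

# Random symmetric positive-definite matrix.
random_pd <- function(p, jitter = 0.5) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + jitter * diag(p)
}

# Greedy forward selection oracle: refit OLS for every candidate at every
# step, picking the minimum RSS (lowest index on ties).
greedy_oracle <- function(y, Z, kmax) {
  yc <- y - mean(y)
  Zc <- sweep(Z, 2, colMeans(Z))
  active <- integer(0)
  rss <- sum(yc^2)
  for (k in seq_len(kmax)) {
    cand <- setdiff(seq_len(ncol(Zc)), active)
    r <- vapply(cand, function(j) {
      sum(lm.fit(Zc[, c(active, j), drop = FALSE], yc)$residuals^2)
    }, numeric(1))
    best <- cand[which.min(r)]
    active <- c(active, best)
    rss <- c(rss, min(r))
  }
  list(selected = active, rss = rss)
}

# Dense MLE oracle for a pattern-constrained precision matrix: BFGS on the
# free entries of K, maximising log det K - tr(K S).
dense_mle_oracle <- function(S, pattern, reltol = 1e-14) {
  p <- nrow(S)
  Nm <- as.matrix(pattern$N)
  up <- which(upper.tri(Nm) & Nm != 0, arr.ind = TRUE)
  build <- function(theta) {
    K <- diag(theta[seq_len(p)], p)
    if (nrow(up) > 0) {
      K[up] <- theta[p + seq_len(nrow(up))]
      K[up[, c(2, 1), drop = FALSE]] <- theta[p + seq_len(nrow(up))]
    }
    K
  }
  negll <- function(theta) {
    K <- build(theta)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    -(2 * sum(log(diag(ch))) - sum(K * S))
  }
  grad <- function(theta) {
    K <- build(theta)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(theta)))
    Sig <- chol2inv(ch)
    gd <- -(diag(Sig) - diag(S))
    ge <- if (nrow(up) > 0) -2 * (Sig[up] - S[up]) else numeric(0)
    c(gd, ge)
  }
  theta0 <- c(1 / diag(S), rep(0, nrow(up)))
  fit <- optim(theta0, negll, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = reltol))
  build(fit$par)
}

# Exhaustive maximal-clique enumeration for tiny graphs.
brute_cliques <- function(adj) {
  p <- nrow(adj)
  subsets <- lapply(seq_len(2^p) - 1L, function(m) which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) {
    length(s) > 0 && all(adj[s, s][upper.tri(diag(length(s)))] == 1)
  }, logical(1))
  cl <- subsets[is_clique]
  maximal <- vapply(seq_along(cl), function(i) {
    !any(vapply(cl, function(o) length(o) > length(cl[[i]]) &&
                  all(cl[[i]] %in% o), logical(1)))
  }, logical(1))
  cl[maximal]
}
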