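// Greedy forward-stepwise regression by successive orthogonalisation.
// At each step the predictor giving the largest reduction in residual sum of
// squares is added; with the active set orthogonalised out, that reduction is
// (z_j' r)^2 / ||z_j||^2 for the residualised candidate column z_j.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// One response, candidate matrix Z (columns residualised in place).
// exclude is a 0/1 vector marking columns never eligible (e.g. the response
// itself when Z is the full data matrix). Returns 1-based selection order and
// the RSS path of length kmax+1 (RSS(0) = ||y||^2; y assumed centred upstream
// when an intercept is wanted).
static void fs_one(arma::mat& W, arma::vec& r, const arma::uvec& exclude,
                   int kmax, double eps,
                   arma::ivec& selected, arma::vec& rss) {
  const arma::uword p = W.n_cols;
  arma::vec d = arma::sum(arma::square(W), 0).t();  // residual norms^2
  arma::vec d0 = d;
  std::vector<bool> active(p, true);
  for (arma::uword j = 0; j < p; ++j)
    if (exclude[j] || d0[j] <= eps) active[j] = false;

  rss[0] = arma::dot(r, r);
  int k = 0;
  for (; k < kmax; ++k) {
    arma::vec c = W.t() * r;
    double best = -1.0;
    int jbest = -1;
    for (arma::uword j = 0; j < p; ++j) {
      if (!active[j] || d[j] <= eps * d0[j]) continue;
      double sc = c[j] * c[j] / d[j];
      if (sc > best) { best = sc; jbest = (int)j; }  // strict > : lowest index wins ties
    }
    if (jbest < 0) break;
    arma::vec u = W.col(jbest) / std::sqrt(d[jbest]);
    r -= u * arma::dot(u, r);
    arma::vec w = W.t() * u;
    W -= u * w.t();
    d -= arma::square(w);
    d.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    active[jbest] = false;
    selected[k] = jbest + 1;
    double cur = arma::dot(r, r);
    if (cur < 0) cur = 0;
    // monotone guard against roundoff
    rss[k + 1] = std::min(cur, rss[k]);
    if (rss[k + 1] <= eps * std::max(rss[0], 1.0)) { ++k; break; }
  }
  for (int kk = k; kk < kmax; ++kk) selected[kk] = NA_INTEGER;
  for (int kk = k + 1; kk <= kmax; ++kk) rss[kk] = NA_REAL;
}

// [[Rcpp::export(name = ".fs_single")]]
List fs_single(const arma::mat& Z, const arma::vec& y, int kmax, double eps) {
  arma::mat W = Z;
  arma::vec r = y;
  arma::uvec excl(Z.n_cols, arma::fill::zeros);
  arma::ivec sel(kmax, arma::fill::zeros);
  arma::vec rss(kmax + 1, arma::fill::zeros);
  fs_one(W, r, excl, kmax, eps, sel, rss);
  return List::create(_["selected"] = sel, _["rss"] = rss);
}

// All-genes pass: each column of X in turn is the response, the remaining
// columns are candidates. Returns p x kmax selection matrix (1-based, NA
// padded) and p x (kmax+1) RSS paths.
// [[Rcpp::export(name = ".fs_all")]]
List fs_all(const arma::mat& X, int kmax, double eps) {
  const arma::uword p = X.n_cols;
  arma::imat sel(p, kmax);
  arma::mat rss(p, kmax + 1);
  arma::mat W(X.n_rows, p);
  for (arma::uword i = 0; i < p; ++i) {
    W = X;
    arma::vec r = X.col(i);
    arma::uvec excl(p, arma::fill::zeros);
    excl[i] = 1;
    arma::ivec s(kmax);
    arma::vec q(kmax + 1);
    fs_one(W, r, excl, kmax, eps, s, q);
    sel.row(i) = s.t();
    rss.row(i) = q.t();
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["selected"] = sel, _["rss"] = rss);
}
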