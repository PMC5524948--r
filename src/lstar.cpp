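// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// LSTAR grid search: for every (c, gamma) pair, weight the low-regime
// design by (1 - G) and the high-regime design by G, where
// G = 1 / (1 + exp(-gamma * (Y - c))), solve the least-squares problem,
// and record the residual sum of squares.  Returns the RSS grid and the
// coefficients at the best grid point.
// [[Rcpp::export(name = ".lstar_grid")]]
List lstar_grid(const arma::mat& Xlow, const arma::mat& Xhigh,
                const arma::vec& y, const arma::vec& Y,
                const arma::vec& c_grid, const arma::vec& g_grid) {
  int nc = c_grid.n_elem, ng = g_grid.n_elem;
  int T = y.n_elem;
  int p1 = Xlow.n_cols, p2 = Xhigh.n_cols;
  arma::mat rss(nc, ng);
  rss.fill(arma::datum::inf);
  double best = arma::datum::inf;
  int best_i = 0, best_j = 0;
  arma::vec best_beta(p1 + p2, arma::fill::zeros);
  arma::mat Z(T, p1 + p2);
  for (int i = 0; i < nc; ++i) {
    for (int j = 0; j < ng; ++j) {
      arma::vec G = 1.0 / (1.0 + arma::exp(-g_grid[j] * (Y - c_grid[i])));
      for (int k = 0; k < p1; ++k) Z.col(k) = Xlow.col(k) % (1.0 - G);
      for (int k = 0; k < p2; ++k) Z.col(p1 + k) = Xhigh.col(k) % G;
      arma::vec beta;
      bool ok = arma::solve(beta, Z, y, arma::solve_opts::fast);
      if (!ok || !beta.is_finite()) continue;
      arma::vec r = y - Z * beta;
      double s = arma::dot(r, r);
      rss(i, j) = s;
      if (s < best) {
        best = s; best_i = i; best_j = j; best_beta = beta;
      }
    }
  }
  return List::create(_["rss"] = rss, _["best_c_index"] = best_i + 1,
                      _["best_g_index"] = best_j + 1,
                      _["best_beta"] = best_beta, _["best_rss"] = best);
}
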