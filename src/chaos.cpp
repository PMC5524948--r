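#include <Rcpp.h>
using namespace Rcpp;

// Delay-embedding helpers shared by the distance-heavy kernels.  Vectors are
// addressed implicitly: coordinate k of vector i is x[i + k*tau], so no
// embedding matrix is materialised.

static inline double dist_euclid(const NumericVector& x, int i, int j,
                                 int m, int tau) {
  double s = 0.0;
  for (int k = 0; k < m; ++k) {
    double d = x[i + k * tau] - x[j + k * tau];
    s += d * d;
  }
  return std::sqrt(s);
}

static inline double dist_max(const NumericVector& x, int i, int j,
                              int m, int tau) {
  double s = 0.0;
  for (int k = 0; k < m; ++k) {
    double d = std::fabs(x[i + k * tau] - x[j + k * tau]);
    if (d > s) s = d;
  }
  return s;
}

// Cao's E(m) and E*(m) for m = 1..m_max.  E(m) is the mean ratio of
// (m+1)- to m-dimensional distances to the m-dimensional nearest
// neighbour (max norm, as in Cao's formulation); E*(m) is the mean
// absolute gap between the extrapolated coordinates x_{i+m*tau} of a
// point and its neighbour, Cao's statistic for separating deterministic
// from stochastic data.  Neighbours at zero m-dimensional distance are
// skipped.
// [[Rcpp::export(name = ".cao_e_profile")]]
List cao_e_profile(NumericVector x, int tau, int m_max) {
  int n = x.size();
  NumericVector E(m_max), Estar(m_max);
  for (int m = 1; m <= m_max; ++m) {
    int T = n - m * tau;  // vectors usable in both m and m+1 dims
    if (T < 2) stop("series too short for Cao dimension %d", m);
    double acc = 0.0, accs = 0.0;
    int cnt = 0;
    for (int i = 0; i < T; ++i) {
      double best = R_PosInf;
      int bj = -1;
      for (int j = 0; j < T; ++j) {
        if (j == i) continue;
        double d = dist_max(x, i, j, m, tau);
        if (d > 0.0 && d < best) { best = d; bj = j; }
      }
      if (bj < 0) continue;
      double dnum = dist_max(x, i, bj, m + 1, tau);
      acc += dnum / best;
      accs += std::fabs(x[i + m * tau] - x[bj + m * tau]);
      ++cnt;
    }
    if (cnt == 0) stop("no valid neighbours at dimension %d", m);
    E[m - 1] = acc / cnt;
    Estar[m - 1] = accs / cnt;
  }
  return List::create(_["E"] = E, _["Estar"] = Estar);
}

// Grassberger-Procaccia correlation sums C(r) over a radius grid, with a
// Theiler window excluding temporally close pairs.
// [[Rcpp::export(name = ".corr_sum")]]
NumericVector corr_sum(NumericVector x, int m, int tau, NumericVector radii,
                       int theiler) {
  int n = x.size();
  int T = n - (m - 1) * tau;
  if (T < 2) stop("series too short to embed");
  int nr = radii.size();
  std::vector<double> counts(nr, 0.0);
  double npairs = 0.0;
  for (int i = 0; i < T; ++i) {
    for (int j = i + theiler + 1; j < T; ++j) {
      double d = dist_euclid(x, i, j, m, tau);
      ++npairs;
      for (int k = 0; k < nr; ++k) {
        if (d < radii[k]) counts[k] += 1.0;
      }
    }
  }
  if (npairs == 0) stop("Theiler window leaves no admissible pairs");
  NumericVector out(nr);
  for (int k = 0; k < nr; ++k) out[k] = counts[k] / npairs;
  return out;
}

// Quantiles of the pairwise embedded distances on a subsample, used by the
// radius-grid selection.
// [[Rcpp::export(name = ".dist_sample")]]
NumericVector dist_sample(NumericVector x, int m, int tau, int theiler,
                          int stride) {
  int n = x.size();
  int T = n - (m - 1) * tau;
  std::vector<double> d;
  for (int i = 0; i < T; i += stride) {
    for (int j = i + theiler + 1; j < T; j += stride) {
      d.push_back(dist_euclid(x, i, j, m, tau));
    }
  }
  return wrap(d);
}

// Rosenstein divergence curve: S(k) = mean over reference points of
// log(d_k / d_0), where d_k is the distance after k steps between a point
// and its (Theiler-excluded) nearest neighbour.
// [[Rcpp::export(name = ".rosenstein_curve")]]
NumericVector rosenstein_curve(NumericVector x, int m, int tau, int theiler,
                               int kmax) {
  int n = x.size();
  int T = n - (m - 1) * tau;
  int usable = T - kmax;
  if (usable < theiler + 2) stop("series too short for divergence curve");
  std::vector<double> acc(kmax + 1, 0.0);
  std::vector<int> cnt(kmax + 1, 0);
  for (int i = 0; i < usable; ++i) {
    double best = R_PosInf;
    int bj = -1;
    for (int j = 0; j < usable; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d = dist_euclid(x, i, j, m, tau);
      if (d > 0.0 && d < best) { best = d; bj = j; }
    }
    if (bj < 0) continue;
    for (int k = 0; k <= kmax; ++k) {
      double d = dist_euclid(x, i + k, bj + k, m, tau);
      if (d > 0.0) { acc[k] += std::log(d / best); ++cnt[k]; }
    }
  }
  NumericVector out(kmax + 1);
  for (int k = 0; k <= kmax; ++k) {
    if (cnt[k] == 0) stop("too few neighbour pairs for divergence curve");
    out[k] = acc[k] / cnt[k];
  }
  return out;
}

// Phase-space denoising kernel: embed at delay 1, replace each vector by
// the mean of all vectors within `radius` (Euclidean), then reconstruct by
// averaging the overlapping coordinates.
// [[Rcpp::export(name = ".denoise_phase")]]
NumericVector denoise_phase_cpp(NumericVector x, int m, double radius) {
  int n = x.size();
  int T = n - (m - 1);
  if (T < 1) stop("series too short to embed at dimension %d", m);
  NumericVector num(n), den(n);
  std::vector<double> mean_vec(m);
  for (int i = 0; i < T; ++i) {
    for (int k = 0; k < m; ++k) mean_vec[k] = 0.0;
    int cnt = 0;
    for (int j = 0; j < T; ++j) {
      double d = dist_euclid(x, i, j, m, 1);
      if (d <= radius) {
        for (int k = 0; k < m; ++k) mean_vec[k] += x[j + k];
        ++cnt;
      }
    }
    for (int k = 0; k < m; ++k) {
      num[i + k] += mean_vec[k] / cnt;
      den[i + k] += 1.0;
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = num[i] / den[i];
  return out;
}
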