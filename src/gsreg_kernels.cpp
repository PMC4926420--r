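// Numeric kernels: Kraskov kNN mutual information and inversion-calibrated
// adjacent-transposition permutations. Both use R's RNG / digamma so results
// are reproducible from set.seed() on any platform.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger estimator, variant 1, Chebyshev metric.
// MI(x, y) = digamma(k) + digamma(N) - < digamma(nx+1) + digamma(ny+1) >
// where nx_i counts points with |x_j - x_i| < eps_i, eps_i the distance to
// the k-th nearest neighbour of point i in the joint (max-norm) space.
// O(N^2); inputs are assumed tie-free (callers jitter deterministically).
// [[Rcpp::export(name = ".ksg1_mi")]]
double ksg1_mi(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (k < 1 || n < 2 * k + 2) stop("need length >= 2k + 2");
  std::vector<double> dj(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = std::abs(x[j] - x[i]);
      double dy = std::abs(y[j] - y[i]);
      dj[j] = dx > dy ? dx : dy;
    }
    dj[i] = R_PosInf;  // exclude self
    std::vector<double> d(dj);
    std::nth_element(d.begin(), d.begin() + (k - 1), d.end());
    double eps = d[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::abs(x[j] - x[i]) < eps) ++nx;
      if (std::abs(y[j] - y[i]) < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  double mi = R::digamma((double) k) + R::digamma((double) n) - acc / n;
  return mi;
}

// Draw a permutation of 1..m at Kendall (inversion) distance exactly d from
// the identity, by d adjacent transpositions each applied at a uniformly
// chosen ascent (a position where the permutation is still increasing), so
// every step adds exactly one inversion and none cancels. Uses R's RNG.
// [[Rcpp::export(name = ".perm_with_inversions")]]
IntegerVector perm_with_inversions(int m, int d) {
  if (m < 1) stop("m must be >= 1");
  long maxd = (long) m * (m - 1) / 2;
  if (d < 0 || d > maxd) stop("d out of range [0, m(m-1)/2]");
  IntegerVector p(m);
  for (int i = 0; i < m; ++i) p[i] = i + 1;
  std::vector<int> asc;
  asc.reserve(m);
  for (int t = 0; t < d; ++t) {
    asc.clear();
    for (int i = 0; i + 1 < m; ++i)
      if (p[i] < p[i + 1]) asc.push_back(i);
    size_t idx = (size_t) (unif_rand() * asc.size());
    if (idx >= asc.size()) idx = asc.size() - 1;
    int pick = asc[idx];
    std::swap(p[pick], p[pick + 1]);
  }
  return p;
}
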