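#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double ptdist(const NumericMatrix& a, int i,
                            const NumericMatrix& b, int j) {
  double dx = a(i, 0) - b(j, 0);
  double dy = a(i, 1) - b(j, 1);
  return std::sqrt(dx * dx + dy * dy);
}

// Cumulative DTW cost D(n, m) with local cost = Euclidean point distance:
// D(i,j) = d(i,j) + min(D(i-1,j-1), D(i-1,j), D(i,j-1)),
// out-of-range terms +Inf, D(1,1) = d(1,1).
// [[Rcpp::export(name = ".dtw_cost_cpp")]]
double dtw_cost_cpp(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow(), m = b.nrow();
  std::vector<double> prev(m), cur(m);
  for (int j = 0; j < m; ++j) {
    double d = ptdist(a, 0, b, j);
    prev[j] = d + (j > 0 ? prev[j - 1] : 0.0);
  }
  for (int i = 1; i < n; ++i) {
    cur[0] = ptdist(a, i, b, 0) + prev[0];
    for (int j = 1; j < m; ++j) {
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = ptdist(a, i, b, j) + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Discrete Frechet distance: minimum over monotone couplings of the
// maximum pointwise Euclidean distance.
// [[Rcpp::export(name = ".frechet_cpp")]]
double frechet_cpp(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow(), m = b.nrow();
  std::vector<double> prev(m), cur(m);
  prev[0] = ptdist(a, 0, b, 0);
  for (int j = 1; j < m; ++j)
    prev[j] = std::max(prev[j - 1], ptdist(a, 0, b, j));
  for (int i = 1; i < n; ++i) {
    cur[0] = std::max(prev[0], ptdist(a, i, b, 0));
    for (int j = 1; j < m; ++j) {
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = std::max(best, ptdist(a, i, b, j));
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
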