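#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// symmetric (edge-repeating) reflection; valid for arbitrary overshoot
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  int m = 2 * n;
  i %= m;
  if (i < 0) i += m;
  return (i < n) ? i : m - 1 - i;
}

// Local mean and population standard deviation over the circular window of
// the given radius (pixels whose centre distance <= radius), boundaries by
// reflection. Returns matrices "mean" and "sd" on the image grid.
// [[Rcpp::export]]
List cc_local_stats(NumericMatrix x, int radius) {
  if (radius < 1) stop("'radius' must be >= 1");
  const int nr = x.nrow(), nc = x.ncol();
  std::vector<int> dr, dc;
  const int r2 = radius * radius;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= r2) { dr.push_back(a); dc.push_back(b); }
  const int m = (int) dr.size();
  NumericMatrix mu(nr, nc), sd(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0, s2 = 0.0;
      for (int k = 0; k < m; ++k) {
        const int ii = reflect_index(i + dr[k], nr);
        const int jj = reflect_index(j + dc[k], nc);
        const double v = x(ii, jj);
        s += v;
        s2 += v * v;
      }
      const double mean = s / m;
      double var = s2 / m - mean * mean;
      if (var < 0.0) var = 0.0;  // guard against roundoff
      mu(i, j) = mean;
      sd(i, j) = std::sqrt(var);
    }
  }
  return List::create(_["mean"] = mu, _["sd"] = sd, _["windowSize"] = m);
}

// 8-connected component labelling of a logical mask (TRUE = foreground).
// Labels are positive integers in scan order; background is 0. The number of
// components is attached as attribute "nComponents".
// [[Rcpp::export]]
IntegerMatrix cc_label8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);  // zero-initialized
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == TRUE && lab(i, j) == 0) {
        ++next;
        lab(i, j) = next;
        stack.push_back(i + j * nr);
        while (!stack.empty()) {
          const int p = stack.back();
          stack.pop_back();
          const int pi = p % nr, pj = p / nr;
          for (int k = 0; k < 8; ++k) {
            const int qi = pi + dr8[k], qj = pj + dc8[k];
            if (qi >= 0 && qi < nr && qj >= 0 && qj < nc &&
                mask(qi, qj) == TRUE && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  lab.attr("nComponents") = next;
  return lab;
}
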