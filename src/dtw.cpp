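#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Banded dynamic time warping with absolute-difference pointwise cost and
// steps {(1,1),(1,0),(0,1)}. The band is a Sakoe-Chiba corridor of half
// width `window` samples around the length-scaled diagonal; it is widened
// automatically when the length difference alone exceeds it, so a feasible
// path always exists. Returns the accumulated cost along the optimal path
// (each cell counted once) and the path itself, 1-based.
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericVector x, NumericVector y, int window) {
  const int n = x.size(), m = y.size();
  if (n < 2 || m < 2) stop("dtw: both sequences need length >= 2");
  int w = window;
  const int mind = std::abs(n - m);
  if (w < mind + 1) w = mind + 1;
  const int width = 2 * w + 1;
  const double inf = std::numeric_limits<double>::infinity();

  // banded cost rows; column j of row i lives at slot j - lo(i)
  std::vector<double> prev(width, inf), curr(width, inf);
  std::vector<signed char> move(static_cast<size_t>(n) * width, -1);
  std::vector<int> lo(n), hi(n);
  for (int i = 0; i < n; ++i) {
    const int center = (n == 1) ? 0 : (int)std::lround((double)i * (m - 1) / (n - 1));
    lo[i] = std::max(0, center - w);
    hi[i] = std::min(m - 1, center + w);
  }

  for (int i = 0; i < n; ++i) {
    std::fill(curr.begin(), curr.end(), inf);
    for (int j = lo[i]; j <= hi[i]; ++j) {
      const double c = std::fabs(x[i] - y[j]);
      double best = inf;
      signed char mv = -1;
      if (i == 0 && j == 0) {
        best = 0.0;
        mv = 0;  // origin
      } else {
        if (i > 0 && j > 0 && j - 1 >= lo[i - 1] && j - 1 <= hi[i - 1]) {
          const double v = prev[j - 1 - lo[i - 1]];
          if (v < best) { best = v; mv = 1; }  // diagonal
        }
        if (i > 0 && j >= lo[i - 1] && j <= hi[i - 1]) {
          const double v = prev[j - lo[i - 1]];
          if (v < best) { best = v; mv = 2; }  // from (i-1, j)
        }
        if (j > lo[i]) {
          const double v = curr[j - 1 - lo[i]];
          if (v < best) { best = v; mv = 3; }  // from (i, j-1)
        }
      }
      if (mv < 0) continue;  // unreachable cell
      curr[j - lo[i]] = best + c;
      move[static_cast<size_t>(i) * width + (j - lo[i])] = mv;
    }
    prev.swap(curr);
  }

  const double dist = prev[m - 1 - lo[n - 1]];
  if (!std::isfinite(dist)) stop("dtw: no feasible path inside the band");

  // backtrack
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  while (true) {
    pi.push_back(i + 1);
    pj.push_back(j + 1);
    const signed char mv = move[static_cast<size_t>(i) * width + (j - lo[i])];
    if (mv == 0) break;
    if (mv == 1) { --i; --j; }
    else if (mv == 2) { --i; }
    else { --j; }
  }
  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return List::create(_["distance"] = dist, _["path"] = path);
}
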