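#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Approximate entropy, classic definition: Chebyshev distance, self-matches
// included. phi(m) = mean_i log( C_i^m ), ApEn = phi(m) - phi(m+1).
// O(N^2 * m); hour-scale RR series (~5e3 intervals) need the compiled loop.
static double phi(const NumericVector& x, int m, double r) {
  const int n = x.size();
  const int nw = n - m + 1;
  if (nw <= 0) return NA_REAL;
  double acc = 0.0;
  for (int i = 0; i < nw; ++i) {
    int cnt = 0;
    for (int j = 0; j < nw; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) ++cnt;
    }
    acc += std::log(static_cast<double>(cnt) / nw);
  }
  return acc / nw;
}

// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  if (n < m + 2) return NA_REAL;
  double p1 = phi(x, m, r);
  double p2 = phi(x, m + 1, r);
  return p1 - p2;
}
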