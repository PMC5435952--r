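#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Average fuzzy similarity phi^m(n, r) of a scalar series at embedding
// dimension m.
//
// Windows are the N - m sliding m-tuples, each centered by its own mean
// (local baseline removal). Distance between two windows is the Chebyshev
// (max absolute componentwise) distance; similarity is
//   exp(-d^n / r)        (as-printed form)
//   exp(-(d / r)^n)      (normalized form)
// phi is the mean over windows i of the mean similarity to all j != i.
// The kernel exploits symmetry (D_ij = D_ji) and visits each unordered
// pair once; results are identical to the naive double loop because the
// row means all share the same denominator (M - 1).
// [[Rcpp::export]]
double fuzzyen_phi_cpp(NumericVector x, int m, double n, double r,
                       bool normalized) {
  const int N = x.size();
  const int M = N - m;  // number of windows entering the sums
  if (M < 2) stop("need at least 2 embedded windows (N - m >= 2)");
  if (r <= 0) stop("similarity tolerance r must be > 0");

  // centered windows, stored window-major
  std::vector<double> w((size_t)M * m);
  for (int i = 0; i < M; ++i) {
    double mu = 0.0;
    for (int k = 0; k < m; ++k) mu += x[i + k];
    mu /= m;
    for (int k = 0; k < m; ++k) w[(size_t)i * m + k] = x[i + k] - mu;
  }

  // d^n by repeated multiplication when n is a small integer (the common
  // case, n = 4); exp() is skipped when its argument is below the double
  // underflow threshold, which dominates for microvolt-scale data under the
  // exp(-d^n / r) form
  const bool int_n = (n == std::floor(n) && n >= 1 && n <= 64);
  const int ni = (int)n;
  double total = 0.0;  // sum over unordered pairs of similarities
  for (int i = 0; i < M; ++i) {
    const double* wi = &w[(size_t)i * m];
    for (int j = i + 1; j < M; ++j) {
      const double* wj = &w[(size_t)j * m];
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(wi[k] - wj[k]);
        if (a > d) d = a;
      }
      double base = normalized ? d / r : d;
      double arg;  // exponent magnitude: (d/r)^n or d^n / r
      if (int_n) {
        double p = base;
        for (int q = 1; q < ni; ++q) p *= base;
        arg = normalized ? p : p / r;
      } else {
        arg = normalized ? std::pow(base, n) : std::pow(base, n) / r;
      }
      if (arg < 745.0) total += std::exp(-arg);
    }
  }
  // mean_i [ (1/(M-1)) * sum_{j != i} D_ij ] = 2 * total / (M * (M - 1))
  return 2.0 * total / ((double)M * (M - 1));
}
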