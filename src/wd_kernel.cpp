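#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted-degree string kernel on positionally encoded sequences.
// Codes 1..4 = A,C,G,T; code 5 = N, which never matches (not even another N).
// k(x, y) = sum_{d=1..D} beta_d * #{i : x[i..i+d-1] == y[i..i+d-1]},
// beta_d = 2 (D - d + 1) / (D (D + 1)).
//
// A maximal run of r matching positions contains (r - d + 1) matching
// d-mers, so its contribution is sum_{d=1..min(r,D)} beta_d (r - d + 1),
// which we tabulate once per call.

// [[Rcpp::export]]
NumericMatrix wd_kernel_matrix_cpp(IntegerMatrix X, IntegerMatrix Y, int D) {
  const int nx = X.nrow(), ny = Y.nrow(), L = X.ncol();
  if (Y.ncol() != L) stop("sequence lengths differ between the two sets");
  if (D < 1 || D > L) stop("degree D must satisfy 1 <= D <= window length");

  std::vector<double> beta(D);
  const double denom = (double)D * (D + 1);
  for (int d = 1; d <= D; ++d) beta[d - 1] = 2.0 * (D - d + 1) / denom;

  // contribution of a maximal match run of length r, r = 0..L
  std::vector<double> runval(L + 1, 0.0);
  for (int r = 1; r <= L; ++r) {
    double s = 0.0;
    const int m = std::min(r, D);
    for (int d = 1; d <= m; ++d) s += beta[d - 1] * (r - d + 1);
    runval[r] = s;
  }

  NumericMatrix K(nx, ny);
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      double acc = 0.0;
      int run = 0;
      for (int p = 0; p < L; ++p) {
        const int a = X(i, p), b = Y(j, p);
        if (a == b && a != 5) {
          ++run;
        } else if (run > 0) {
          acc += runval[run];
          run = 0;
        }
      }
      if (run > 0) acc += runval[run];
      K(i, j) = acc;
    }
  }
  return K;
}
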