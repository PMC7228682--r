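#include <Rcpp.h>
#include <cmath>
#include <vector>

// Approximate-entropy counting kernel.
//
// Phi^m = (1 / n_vec) * sum_i log( N_i / denom ), where N_i counts the
// template vectors X(j) whose Chebyshev distance to X(i) is <= r.  The
// self comparison (j == i) is included by default, which guarantees
// N_i >= 1 and hence a finite logarithm even for r = 0.
//
// Matches are symmetric, so each unordered pair is evaluated once; the
// length-(m+1) comparison extends the length-m distance by one
// coordinate instead of recomputing it.

// [[Rcpp::export]]
double apen_kernel(Rcpp::NumericVector x, int m, double r,
                   bool include_self, bool phi1_full_count) {
  const int n = x.size();
  const int nvm = n - m + 1;    // template count at length m
  const int nvm1 = n - m;       // template count at length m + 1
  const int self = include_self ? 1 : 0;
  std::vector<int> cm(nvm, self), cm1(nvm1, self);

  for (int i = 0; i < nvm; ++i) {
    for (int j = i + 1; j < nvm; ++j) {
      double d = 0.0;
      bool match_m = true;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
        if (d > r) { match_m = false; break; }
      }
      if (!match_m) continue;
      ++cm[i]; ++cm[j];
      if (j < nvm1) {  // i < j implies i < nvm1 too
        double a = std::fabs(x[i + m] - x[j + m]);
        if (a <= r) { ++cm1[i]; ++cm1[j]; }
      }
    }
  }

  const double denom_m = static_cast<double>(nvm);
  const double denom_m1 =
      static_cast<double>(phi1_full_count ? (n - m + 1) : (n - m));
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nvm; ++i) {
    if (cm[i] == 0) return NA_REAL;  // possible only without self-matches
    phi_m += std::log(cm[i] / denom_m);
  }
  phi_m /= nvm;
  for (int i = 0; i < nvm1; ++i) {
    if (cm1[i] == 0) return NA_REAL;
    phi_m1 += std::log(cm1[i] / denom_m1);
  }
  phi_m1 /= nvm1;
  return phi_m - phi_m1;
}
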