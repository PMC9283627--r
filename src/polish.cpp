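#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static double median_of(std::vector<double> &v) {
  if (v.empty()) return 0.0;
  std::size_t n = v.size();
  std::size_t mid = n / 2;
  std::nth_element(v.begin(), v.begin() + mid, v.end());
  double hi = v[mid];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + mid);
  return 0.5 * (lo + hi);
}

// Iterative median polish of a matrix with missing entries, returning the
// accumulated row and column effects. The overall level stays with the
// residuals, so callers subtract only the returned effects.
// [[Rcpp::export]]
List polish_effects(NumericMatrix m, double eps, int maxiter) {
  int nr = m.nrow(), nc = m.ncol();
  NumericMatrix work(clone(m));
  NumericVector reff(nr), ceff(nc);
  std::vector<double> buf;
  buf.reserve(std::max(nr, nc));

  for (int it = 0; it < maxiter; ++it) {
    double worst = 0.0;
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int j = 0; j < nc; ++j)
        if (!NumericMatrix::is_na(work(i, j))) buf.push_back(work(i, j));
      double med = median_of(buf);
      if (!buf.empty()) {
        for (int j = 0; j < nc; ++j)
          if (!NumericMatrix::is_na(work(i, j))) work(i, j) -= med;
        reff[i] += med;
        worst = std::max(worst, std::fabs(med));
      }
    }
    for (int j = 0; j < nc; ++j) {
      buf.clear();
      for (int i = 0; i < nr; ++i)
        if (!NumericMatrix::is_na(work(i, j))) buf.push_back(work(i, j));
      double med = median_of(buf);
      if (!buf.empty()) {
        for (int i = 0; i < nr; ++i)
          if (!NumericMatrix::is_na(work(i, j))) work(i, j) -= med;
        ceff[j] += med;
        worst = std::max(worst, std::fabs(med));
      }
    }
    if (worst < eps) break;
  }
  return List::create(Named("row") = reff, Named("col") = ceff);
}
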