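#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Row-wise two-sided Wilcoxon rank-sum p-values for paired matrices a
// (group 1) and b (group 2) with equal row counts. Normal approximation
// with tie correction and continuity correction, matching
// wilcox.test(exact = FALSE, correct = TRUE). Rows with zero rank variance
// (all values tied) get p = 1.
// [[Rcpp::export]]
NumericVector wilcox_rows_pvalue(NumericMatrix a, NumericMatrix b) {
  const int nr = a.nrow(), n1 = a.ncol(), n2 = b.ncol(), m = n1 + n2;
  if (b.nrow() != nr) stop("matrices must have the same number of rows");
  if (n1 < 1 || n2 < 1) stop("both groups must have at least one column");
  NumericVector out(nr);
  std::vector<double> v(m), rk(m);
  std::vector<int> idx(m);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < n1; ++j) v[j] = a(i, j);
    for (int j = 0; j < n2; ++j) v[n1 + j] = b(i, j);
    std::iota(idx.begin(), idx.end(), 0);
    std::sort(idx.begin(), idx.end(),
              [&](int x, int y) { return v[x] < v[y]; });
    double tiesum = 0.0;
    int k = 0;
    while (k < m) {
      int k2 = k;
      while (k2 + 1 < m && v[idx[k2 + 1]] == v[idx[k]]) ++k2;
      const double avg = 0.5 * (k + k2) + 1.0;
      const double t = k2 - k + 1;
      for (int q = k; q <= k2; ++q) rk[idx[q]] = avg;
      tiesum += t * t * t - t;
      k = k2 + 1;
    }
    double r1 = 0.0;
    for (int j = 0; j < n1; ++j) r1 += rk[j];
    const double U = r1 - n1 * (n1 + 1.0) / 2.0;
    const double mu = 0.5 * n1 * (double)n2;
    const double sigma2 = (n1 * (double)n2 / 12.0) *
      ((m + 1.0) - tiesum / ((double)m * (m - 1.0)));
    if (sigma2 <= 0.0) { out[i] = 1.0; continue; }
    double z = U - mu;
    const double cc = (z > 0) ? 0.5 : ((z < 0) ? -0.5 : 0.0);
    z = (z - cc) / std::sqrt(sigma2);
    out[i] = std::min(1.0, 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0));
  }
  return out;
}
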