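#include <Rcpp.h>
using namespace Rcpp;

// Meuwissen-Luo style computation of inbreeding coefficients.
// For animal i with both parents known, F_i = a(s,d)/2 is obtained as
// A_ii - 1 of a virtual offspring by descending the ancestor weights
// (w_parent += w/2) and accumulating w_j^2 * D_j, where D_j is the
// Mendelian sampling variance ratio of ancestor j.
// Codes must be topologically ordered (parents before offspring).
// [[Rcpp::export]]
NumericVector inbreeding_ml(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n), w(n, 0.0);
  std::vector<int> touched;
  touched.reserve(64);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i) stop("pedigree not topologically ordered");
    D[i] = 1.0 - (s >= 0 ? 0.25 * (1.0 + F[s]) : 0.0)
               - (d >= 0 ? 0.25 * (1.0 + F[d]) : 0.0);
    if (s < 0 || d < 0) { F[i] = 0.0; continue; }
    double aii = 0.0;
    w[i] = 1.0;
    touched.clear();
    touched.push_back(i);
    for (int j = i; j >= 0; --j) {
      const double wj = w[j];
      if (wj == 0.0) continue;
      aii += wj * wj * D[j];
      const int sj = sire[j] - 1, dj = dam[j] - 1;
      if (sj >= 0) { if (w[sj] == 0.0) touched.push_back(sj); w[sj] += 0.5 * wj; }
      if (dj >= 0) { if (w[dj] == 0.0) touched.push_back(dj); w[dj] += 0.5 * wj; }
    }
    for (size_t k = 0; k < touched.size(); ++k) w[touched[k]] = 0.0;
    F[i] = aii - 1.0;
  }
  return F;
}
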