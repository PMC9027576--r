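#include <Rcpp.h>
using namespace Rcpp;

// Pedigree routines operate on 1-based parent indices into a pedigree already
// sorted parents-before-offspring; 0 marks an unknown parent.

// Meuwissen & Luo style inbreeding: F_i = sum_j L_ij^2 D_j - 1, accumulating
// the i-th row of the Cholesky factor L over ancestors only.
// [[Rcpp::export]]
NumericVector inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n), L(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    double fs = s > 0 ? F[s - 1] : -1.0;  // -1 encodes "unknown parent"
    double fd = d > 0 ? F[d - 1] : -1.0;
    // Mendelian sampling variance; unknown parent contributes as an
    // unrelated non-inbred founder drawn fresh.
    double di;
    if (s == 0 && d == 0)      di = 1.0;
    else if (s == 0 || d == 0) di = 0.75 - 0.25 * (s > 0 ? fs : fd);
    else                       di = 0.5 - 0.25 * (fs + fd);
    D[i] = di;
    if (s == 0 || d == 0) { F[i] = 0.0; continue; }
    std::fill(L.begin(), L.begin() + i + 1, 0.0);
    L[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      if (L[j] == 0.0) continue;
      const int sj = sire[j], dj = dam[j];
      if (sj > 0) L[sj - 1] += 0.5 * L[j];
      if (dj > 0) L[dj - 1] += 0.5 * L[j];
      aii += L[j] * L[j] * D[j];
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// Tabular (recursive) construction of the numerator relationship matrix A.
// [[Rcpp::export]]
NumericMatrix build_A_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    for (int j = 0; j < i; ++j) {
      double aij = 0.0;
      if (s > 0) aij += 0.5 * A(j, s - 1);
      if (d > 0) aij += 0.5 * A(j, d - 1);
      A(i, j) = A(j, i) = aij;
    }
    double aii = 1.0;
    if (s > 0 && d > 0) aii += 0.5 * A(s - 1, d - 1);
    A(i, i) = aii;
  }
  return A;
}
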