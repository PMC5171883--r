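#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo (1992) algorithm.
// `sire` and `dam` are 1-based indices into a pedigree sorted so that
// parents precede offspring; 0 codes an unknown parent. For animal i,
// F_i = A_ii - 1 with A_ii = sum_j L_ij^2 D_jj accumulated by tracing the
// ancestor set of i; unknown parents contribute nothing (founders are
// taken as unrelated and non-inbred).
// `F_init` optionally carries already-computed coefficients for a leading
// subset of the pedigree (it is append-only), so new generations can be
// scored incrementally.
// [[Rcpp::export]]
NumericVector inbreeding_ml(IntegerVector sire, IntegerVector dam,
                            NumericVector F_init = NumericVector()) {
  const int n = sire.size();
  if (dam.size() != n) stop("sire and dam must have equal length");
  const int m = F_init.size();
  if (m > n) stop("F_init longer than the pedigree");
  NumericVector F(n);
  for (int i = 0; i < m; ++i) F[i] = F_init[i];
  std::vector<double> v(n + 1, 0.0);

  for (int i = m + 1; i <= n; ++i) {
    int s = sire[i - 1], d = dam[i - 1];
    if (s < 0 || s > n || d < 0 || d > n || s >= i || d >= i)
      stop("pedigree is not sorted with parents before offspring");
    if (s == 0 && d == 0) { F[i - 1] = 0.0; continue; }

    v[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 1; --j) {
      double w = v[j];
      if (w == 0.0) continue;
      v[j] = 0.0;
      int sj = sire[j - 1], dj = dam[j - 1];
      if (sj > 0) v[sj] += 0.5 * w;
      if (dj > 0) v[dj] += 0.5 * w;
      double Dj;  // Mendelian sampling variance coefficient
      if (sj > 0 && dj > 0)      Dj = 0.5 - 0.25 * (F[sj - 1] + F[dj - 1]);
      else if (sj > 0)           Dj = 0.75 - 0.25 * F[sj - 1];
      else if (dj > 0)           Dj = 0.75 - 0.25 * F[dj - 1];
      else                       Dj = 1.0;
      aii += w * w * Dj;
    }
    F[i - 1] = aii - 1.0;
  }
  return F;
}
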