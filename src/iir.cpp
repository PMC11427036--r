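#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter: a[0]*y[n] = sum b[k] x[n-k] - sum a[k] y[n-k].
// Used by filtfilt_butter(); coefficients come from the R-side Butterworth design.
// [[Rcpp::export]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nord = std::max(nb, na);
  std::vector<double> bb(nord, 0.0), aa(nord, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  double a0 = aa[0];
  if (a0 == 0.0) stop("a[1] must be nonzero");
  for (int i = 0; i < nord; ++i) { bb[i] /= a0; aa[i] /= a0; }
  std::vector<double> z(nord - 1, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nord > 1 ? z[0] : 0.0);
    for (int j = 1; j < nord - 1; ++j)
      z[j - 1] = bb[j] * xi + z[j] - aa[j] * yi;
    if (nord > 1)
      z[nord - 2] = bb[nord - 1] * xi - aa[nord - 1] * yi;
    y[i] = yi;
  }
  return y;
}
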