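#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter: y = filter(b, a, x).
// Used for the noise-shaping filters of the signal synthesizer, where the
// recordings are long enough (tens of millions of samples) that an O(N)
// compiled pass matters. The order-4 case (our Butterworth band-passes and
// the pinking filter) is unrolled.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector x, NumericVector b, NumericVector a) {
  int nb = b.size(), na = a.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  int n = x.size();
  NumericVector y(n);
  const double *px = x.begin();
  double *py = y.begin();

  if (nz == 4) {
    const double b0 = bb[0], b1 = bb[1], b2 = bb[2], b3 = bb[3], b4 = bb[4];
    const double a1 = aa[1], a2 = aa[2], a3 = aa[3], a4 = aa[4];
    double z1 = 0, z2 = 0, z3 = 0, z4 = 0;
    for (int t = 0; t < n; ++t) {
      const double xt = px[t];
      const double yt = b0 * xt + z1;
      z1 = b1 * xt + z2 - a1 * yt;
      z2 = b2 * xt + z3 - a2 * yt;
      z3 = b3 * xt + z4 - a3 * yt;
      z4 = b4 * xt - a4 * yt;
      py[t] = yt;
    }
    return y;
  }
  if (nz == 3) {
    const double b0 = bb[0], b1 = bb[1], b2 = bb[2], b3 = bb[3];
    const double a1 = aa[1], a2 = aa[2], a3 = aa[3];
    double z1 = 0, z2 = 0, z3 = 0;
    for (int t = 0; t < n; ++t) {
      const double xt = px[t];
      const double yt = b0 * xt + z1;
      z1 = b1 * xt + z2 - a1 * yt;
      z2 = b2 * xt + z3 - a2 * yt;
      z3 = b3 * xt - a3 * yt;
      py[t] = yt;
    }
    return y;
  }
  std::vector<double> z(nz + 1, 0.0);
  for (int t = 0; t < n; ++t) {
    double xt = px[t];
    double yt = bb[0] * xt + z[0];
    for (int i = 0; i < nz; ++i) {
      z[i] = bb[i + 1] * xt + z[i + 1] - aa[i + 1] * yt;
    }
    py[t] = yt;
  }
  return y;
}
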