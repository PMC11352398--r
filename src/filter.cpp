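#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Causal IIR filter (direct form II transposed), applied independently to
// each row of a channels x samples matrix with zero initial conditions.
// Coefficients follow the usual b/a convention of a rational transfer
// function in z^-1. The time loop is outermost so memory access follows the
// column-major layout.
// [[Rcpp::export(".iirFilterMatrix")]]
NumericMatrix iirFilterMatrix(NumericMatrix x, NumericVector b,
                              NumericVector a) {
  const int nch = x.nrow(), n = x.ncol();
  const int nb = b.size(), na = a.size();
  const int nz = std::max(nb, na) - 1;
  NumericMatrix y(nch, n);
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  // per-channel delay lines, laid out channel-fastest
  std::vector<double> z((size_t)nch * nz, 0.0);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int t = 0; t < n; ++t) {
    const double *xc = xp + (size_t)t * nch;
    double *yc = yp + (size_t)t * nch;
    for (int ch = 0; ch < nch; ++ch) {
      double *zc = &z[(size_t)ch * nz];
      const double xt = xc[ch];
      const double yt = bb[0] * xt + zc[0];
      for (int k = 0; k < nz - 1; ++k) {
        zc[k] = bb[k + 1] * xt + zc[k + 1] - aa[k + 1] * yt;
      }
      zc[nz - 1] = bb[nz] * xt - aa[nz] * yt;
      yc[ch] = yt;
    }
  }
  return y;
}
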