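#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Direct-form II transposed IIR filter applied causally down each column.
// Coefficients follow the usual (b, a) convention with a[0] == 1 after
// normalisation; state is reset between columns so channels (and trials
// laid out as columns) never share transients.
// [[Rcpp::export]]
NumericMatrix iir_filter_cols(NumericVector b, NumericVector a, NumericMatrix x) {
  const int nb = b.size(), na = a.size();
  if (nb < 1 || na < 1) stop("empty filter coefficients");
  const double a0 = a[0];
  if (a0 == 0.0) stop("a[1] must be non-zero");
  std::vector<double> bn(nb), an(na);
  for (int i = 0; i < nb; ++i) bn[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) an[i] = a[i] / a0;

  const int T = x.nrow(), C = x.ncol();
  const int nw = std::max(nb, na) - 1;
  NumericMatrix y(T, C);
  std::vector<double> w(nw > 0 ? nw : 1);

  for (int c = 0; c < C; ++c) {
    std::fill(w.begin(), w.end(), 0.0);
    for (int t = 0; t < T; ++t) {
      const double xt = x(t, c);
      const double yt = bn[0] * xt + (nw > 0 ? w[0] : 0.0);
      for (int k = 0; k < nw; ++k) {
        double wn = (k + 1 < nw) ? w[k + 1] : 0.0;
        if (k + 1 < nb) wn += bn[k + 1] * xt;
        if (k + 1 < na) wn -= an[k + 1] * yt;
        w[k] = wn;
      }
      y(t, c) = yt;
    }
  }
  return y;
}
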