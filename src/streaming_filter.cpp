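#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit state, so that chunked
// (streaming) application is sample-exactly equal to filtering the
// concatenated signal. a must be normalized (a[0] == 1).
// x: samples x channels; zi: state (max(na,nb)-1) x channels.
// [[Rcpp::export(name = ".df2t_filter")]]
List df2t_filter(NumericVector b, NumericVector a, NumericMatrix x,
                 NumericMatrix zi) {
  const int n = x.nrow(), nc = x.ncol(), m = zi.nrow();
  NumericMatrix y(n, nc), zf(m, nc);
  std::vector<double> bb(m + 1, 0.0), aa(m + 1, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  for (int c = 0; c < nc; ++c) {
    std::vector<double> z(m);
    for (int i = 0; i < m; ++i) z[i] = zi(i, c);
    for (int t = 0; t < n; ++t) {
      const double xt = x(t, c);
      const double yt = bb[0] * xt + z[0];
      for (int i = 0; i < m - 1; ++i)
        z[i] = bb[i + 1] * xt + z[i + 1] - aa[i + 1] * yt;
      z[m - 1] = bb[m] * xt - aa[m] * yt;
      y(t, c) = yt;
    }
    for (int i = 0; i < m; ++i) zf(i, c) = z[i];
  }
  return List::create(_["y"] = y, _["zf"] = zf);
}
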