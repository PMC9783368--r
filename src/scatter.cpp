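#include <Rcpp.h>
using namespace Rcpp;

// Scatter-add for the convolution data gradient (col2im). `idx` holds, for
// every patch element of every output position of every image, the 1-based
// linear index into the padded input tensor; it is ordered (patch element,
// position, image) to match the im2col map. `dP` is (positions*images) x
// (patch elements). Overlapping patches accumulate.
// [[Rcpp::export]]
NumericVector scatter_add_cols(IntegerVector idx, NumericMatrix dP,
                               int out_len) {
  const int nB = dP.nrow();
  const int kkc = dP.ncol();
  NumericVector out(out_len);
  double* o = out.begin();
  const int* id = idx.begin();
  const double* p = dP.begin();
  for (int a = 0; a < kkc; ++a) {
    const double* col = p + (size_t)a * nB;
    for (int b = 0; b < nB; ++b) {
      o[id[(size_t)b * kkc + a] - 1] += col[b];
    }
  }
  return out;
}
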