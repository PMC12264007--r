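#include <Rcpp.h>
using namespace Rcpp;

// Centered FIR convolution along the second (time) dimension of a
// pixels x time matrix, with replicate (constant-edge) padding.  The
// filter length must be odd; taps are applied symmetrically so an
// (anti)symmetric design incurs zero phase.
// [[Rcpp::export]]
NumericMatrix fir_filter_mat(const NumericMatrix& m,
                             const NumericVector& h) {
  const int np = m.nrow(), nt = m.ncol(), L = h.size();
  const int half = (L - 1) / 2;
  NumericMatrix out(np, nt);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix::Column oc = out(_, t);
    for (int k = 0; k < L; ++k) {
      int src = t + half - k;
      if (src < 0) src = 0;
      if (src >= nt) src = nt - 1;
      const double w = h[k];
      NumericMatrix::ConstColumn ic = m(_, src);
      for (int p = 0; p < np; ++p) oc[p] += w * ic[p];
    }
  }
  return out;
}
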