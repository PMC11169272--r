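#include <Rcpp.h>
using namespace Rcpp;

// 1-D convolution kernels for the multi-task residual network.
// Layout: signals are column-major arrays [L, C, B] (length, channels,
// batch); weights are [k, Cin, Cout]. `stride` >= 1, `pad` is symmetric
// zero padding. All indices 0-based internally.

// [[Rcpp::export]]
NumericVector conv1d_fw(NumericVector x, IntegerVector xdim,
                        NumericVector w, IntegerVector wdim,
                        NumericVector bias, int stride, int pad) {
  const int L = xdim[0], Cin = xdim[1], B = xdim[2];
  const int k = wdim[0], Cout = wdim[2];
  const int Lout = (L + 2 * pad - k) / stride + 1;
  NumericVector y(Lout * Cout * B);
  for (int b = 0; b < B; ++b) {
    const double *xb = x.begin() + (size_t)b * L * Cin;
    double *yb = y.begin() + (size_t)b * Lout * Cout;
    for (int oc = 0; oc < Cout; ++oc) {
      const double *woc = w.begin() + (size_t)oc * k * Cin;
      double *yc = yb + (size_t)oc * Lout;
      for (int ol = 0; ol < Lout; ++ol) {
        double acc = bias[oc];
        const int base = ol * stride - pad;
        for (int ic = 0; ic < Cin; ++ic) {
          const double *xc = xb + (size_t)ic * L;
          const double *wk = woc + (size_t)ic * k;
          int k0 = base < 0 ? -base : 0;
          int k1 = base + k > L ? L - base : k;
          for (int kk = k0; kk < k1; ++kk) acc += xc[base + kk] * wk[kk];
        }
        yc[ol] = acc;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Lout, Cout, B);
  return y;
}

// [[Rcpp::export]]
List conv1d_bw(NumericVector x, IntegerVector xdim,
               NumericVector w, IntegerVector wdim,
               NumericVector dy, int stride, int pad) {
  const int L = xdim[0], Cin = xdim[1], B = xdim[2];
  const int k = wdim[0], Cout = wdim[2];
  const int Lout = (L + 2 * pad - k) / stride + 1;
  NumericVector dx(x.size()), dw(w.size()), db(Cout);
  for (int b = 0; b < B; ++b) {
    const double *xb = x.begin() + (size_t)b * L * Cin;
    double *dxb = dx.begin() + (size_t)b * L * Cin;
    const double *dyb = dy.begin() + (size_t)b * Lout * Cout;
    for (int oc = 0; oc < Cout; ++oc) {
      const double *wc = w.begin() + (size_t)oc * k * Cin;
      double *dwc = dw.begin() + (size_t)oc * k * Cin;
      const double *dyc = dyb + (size_t)oc * Lout;
      for (int ol = 0; ol < Lout; ++ol) {
        const double g = dyc[ol];
        if (g == 0.0) continue;
        db[oc] += g;
        const int base = ol * stride - pad;
        for (int ic = 0; ic < Cin; ++ic) {
          const double *xc = xb + (size_t)ic * L;
          double *dxc = dxb + (size_t)ic * L;
          const double *wk = wc + (size_t)ic * k;
          double *dwk = dwc + (size_t)ic * k;
          int k0 = base < 0 ? -base : 0;
          int k1 = base + k > L ? L - base : k;
          for (int kk = k0; kk < k1; ++kk) {
            dwk[kk] += xc[base + kk] * g;
            dxc[base + kk] += wk[kk] * g;
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = wdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
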