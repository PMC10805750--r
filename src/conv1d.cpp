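#include <Rcpp.h>
using namespace Rcpp;

// 1-D convolution primitives for the network code in R/nn.R.
// Layout conventions:
//   x : L x Cin matrix (time along rows, channels along columns)
//   w : numeric vector of length k*Cin*Cout, index u + k*(ci + Cin*co)
//   y : Lout x Cout with Lout = (L + 2*pad - k) / stride + 1
// Loops are ordered so the innermost runs over time with a constant weight
// (axpy form), which vectorizes well; everything is single-threaded so
// results are bit-reproducible.

// [[Rcpp::export]]
NumericMatrix conv1d_fwd(const NumericMatrix& x, const NumericVector& w,
                         const NumericVector& b, int k, int stride, int pad) {
  const int L = x.nrow(), Cin = x.ncol();
  const int Cout = b.size();
  const int Lout = (L + 2 * pad - k) / stride + 1;
  NumericMatrix y(Lout, Cout);
  const double* px = x.begin();
  const double* pw = w.begin();
  double* py = y.begin();
  for (int co = 0; co < Cout; ++co)
    std::fill(py + (size_t)co * Lout, py + (size_t)(co + 1) * Lout, b[co]);
  for (int co = 0; co < Cout; ++co) {
    double* yc = py + (size_t)co * Lout;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = px + (size_t)ci * L;
      const double* wc = pw + (size_t)k * (ci + (size_t)Cin * co);
      for (int u = 0; u < k; ++u) {
        const double wv = wc[u];
        if (wv == 0.0) continue;
        const int off = u - pad;
        // valid t: 0 <= t*stride + off <= L-1
        int t_lo = off < 0 ? (-off + stride - 1) / stride : 0;
        int t_hi = (L - 1 - off) / stride;
        if (t_hi > Lout - 1) t_hi = Lout - 1;
        const double* xs = xc + off;
        if (stride == 1) {
          for (int t = t_lo; t <= t_hi; ++t) yc[t] += wv * xs[t];
        } else {
          for (int t = t_lo; t <= t_hi; ++t) yc[t] += wv * xs[(size_t)t * stride];
        }
      }
    }
  }
  return y;
}

// Gradient of the loss w.r.t. the convolution input.
// [[Rcpp::export]]
NumericMatrix conv1d_bwd_input(const NumericMatrix& gy, const NumericVector& w,
                               int k, int stride, int pad, int L, int Cin) {
  const int Lout = gy.nrow(), Cout = gy.ncol();
  NumericMatrix gx(L, Cin);
  const double* pg = gy.begin();
  const double* pw = w.begin();
  double* px = gx.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* gc = pg + (size_t)co * Lout;
    for (int ci = 0; ci < Cin; ++ci) {
      double* xc = px + (size_t)ci * L;
      const double* wc = pw + (size_t)k * (ci + (size_t)Cin * co);
      for (int u = 0; u < k; ++u) {
        const double wv = wc[u];
        if (wv == 0.0) continue;
        const int off = u - pad;
        int t_lo = off < 0 ? (-off + stride - 1) / stride : 0;
        int t_hi = (L - 1 - off) / stride;
        if (t_hi > Lout - 1) t_hi = Lout - 1;
        double* xs = xc + off;
        if (stride == 1) {
          for (int t = t_lo; t <= t_hi; ++t) xs[t] += wv * gc[t];
        } else {
          for (int t = t_lo; t <= t_hi; ++t) xs[(size_t)t * stride] += wv * gc[t];
        }
      }
    }
  }
  return gx;
}

// Gradients of the loss w.r.t. kernel weights and biases.
// [[Rcpp::export]]
List conv1d_bwd_params(const NumericMatrix& x, const NumericMatrix& gy,
                       int k, int stride, int pad) {
  const int L = x.nrow(), Cin = x.ncol();
  const int Lout = gy.nrow(), Cout = gy.ncol();
  NumericVector gw(k * Cin * Cout);
  NumericVector gb(Cout);
  const double* px = x.begin();
  const double* pg = gy.begin();
  double* pgw = gw.begin();
  for (int co = 0; co < Cout; ++co) {
    const double* gc = pg + (size_t)co * Lout;
    double bacc = 0.0;
    for (int t = 0; t < Lout; ++t) bacc += gc[t];
    gb[co] = bacc;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = px + (size_t)ci * L;
      double* wc = pgw + (size_t)k * (ci + (size_t)Cin * co);
      for (int u = 0; u < k; ++u) {
        const int off = u - pad;
        int t_lo = off < 0 ? (-off + stride - 1) / stride : 0;
        int t_hi = (L - 1 - off) / stride;
        if (t_hi > Lout - 1) t_hi = Lout - 1;
        const double* xs = xc + off;
        double acc0 = 0.0, acc1 = 0.0;
        int t = t_lo;
        if (stride == 1) {
          for (; t + 1 <= t_hi; t += 2) {
            acc0 += xs[t] * gc[t];
            acc1 += xs[t + 1] * gc[t + 1];
          }
          for (; t <= t_hi; ++t) acc0 += xs[t] * gc[t];
        } else {
          for (; t + 1 <= t_hi; t += 2) {
            acc0 += xs[(size_t)t * stride] * gc[t];
            acc1 += xs[(size_t)(t + 1) * stride] * gc[t + 1];
          }
          for (; t <= t_hi; ++t) acc0 += xs[(size_t)t * stride] * gc[t];
        }
        wc[u] += acc0 + acc1;
      }
    }
  }
  return List::create(_["gw"] = gw, _["gb"] = gb);
}
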