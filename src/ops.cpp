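#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as (h*w) x c matrices, column-major, with the
// spatial index r = y + x*h (0-based) matching an R array of dim c(h, w, c).
// im2col column index: ky + kx*k + ch*k*k, so the weight matrix of a
// convolution has dim (k*k*c_in, c_out) with the same inner ordering.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericMatrix& X, int h, int w, int k,
                         int stride, int pad) {
  const int cin = X.ncol();
  const int ho = (h + 2 * pad - k) / stride + 1;
  const int wo = (w + 2 * pad - k) / stride + 1;
  NumericMatrix out(ho * wo, k * k * cin);
  for (int ch = 0; ch < cin; ++ch) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int col = ky + kx * k + ch * k * k;
        for (int xo = 0; xo < wo; ++xo) {
          const int xi = xo * stride - pad + kx;
          if (xi < 0 || xi >= w) continue;
          for (int yo = 0; yo < ho; ++yo) {
            const int yi = yo * stride - pad + ky;
            if (yi < 0 || yi >= h) continue;
            out(yo + xo * ho, col) = X(yi + xi * h, ch);
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix col2im_cpp(const NumericMatrix& dcol, int h, int w, int cin,
                         int k, int stride, int pad) {
  const int ho = (h + 2 * pad - k) / stride + 1;
  const int wo = (w + 2 * pad - k) / stride + 1;
  NumericMatrix dx(h * w, cin);
  for (int ch = 0; ch < cin; ++ch) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int col = ky + kx * k + ch * k * k;
        for (int xo = 0; xo < wo; ++xo) {
          const int xi = xo * stride - pad + kx;
          if (xi < 0 || xi >= w) continue;
          for (int yo = 0; yo < ho; ++yo) {
            const int yi = yo * stride - pad + ky;
            if (yi < 0 || yi >= h) continue;
            dx(yi + xi * h, ch) += dcol(yo + xo * ho, col);
          }
        }
      }
    }
  }
  return dx;
}

// Max pooling with stride 1 and same padding (k odd); returns the pooled
// map and the 1-based flat row index of each argmax for the backward pass.
// Ties resolve to the first element in (ky, kx) scan order.
// [[Rcpp::export]]
List maxpool_same_cpp(const NumericMatrix& X, int h, int w, int k) {
  const int c = X.ncol();
  const int pad = k / 2;
  NumericMatrix Y(h * w, c);
  IntegerMatrix idx(h * w, c);
  for (int ch = 0; ch < c; ++ch) {
    for (int xo = 0; xo < w; ++xo) {
      for (int yo = 0; yo < h; ++yo) {
        double best = R_NegInf;
        int besti = -1;
        for (int kx = 0; kx < k; ++kx) {
          const int xi = xo - pad + kx;
          if (xi < 0 || xi >= w) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int yi = yo - pad + ky;
            if (yi < 0 || yi >= h) continue;
            const double v = X(yi + xi * h, ch);
            if (v > best) { best = v; besti = yi + xi * h; }
          }
        }
        Y(yo + xo * h, ch) = best;
        idx(yo + xo * h, ch) = besti + 1;
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxpool_bwd_cpp(const NumericMatrix& dY, const IntegerMatrix& idx,
                              int n) {
  const int c = dY.ncol();
  NumericMatrix dX(n, c);
  for (int ch = 0; ch < c; ++ch)
    for (int i = 0; i < dY.nrow(); ++i)
      dX(idx(i, ch) - 1, ch) += dY(i, ch);
  return dX;
}
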