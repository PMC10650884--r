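#include <Rcpp.h>
using namespace Rcpp;

// Arrays are laid out (C, T, B) column-major: index = c + C*(t + T*b).
// Depthwise 1-D convolution with odd kernel k and 'same' zero padding.

// [[Rcpp::export]]
NumericVector dwconv_fwd(NumericVector x, NumericVector w,
                         int C, int T, int B, int k) {
  NumericVector y(x.size());
  int h = (k - 1) / 2;
  for (int b = 0; b < B; ++b) {
    R_xlen_t base = (R_xlen_t)C * T * b;
    for (int j = 0; j < k; ++j) {
      int off = j - h;
      int t0 = off < 0 ? -off : 0;
      int t1 = off > 0 ? T - off : T;
      for (int t = t0; t < t1; ++t) {
        R_xlen_t yi = base + (R_xlen_t)C * t;
        R_xlen_t xi = base + (R_xlen_t)C * (t + off);
        for (int c = 0; c < C; ++c)
          y[yi + c] += w[c + C * j] * x[xi + c];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int C, int T, int B, int k) {
  NumericVector dx(x.size());
  NumericVector dw((R_xlen_t)C * k);
  int h = (k - 1) / 2;
  for (int b = 0; b < B; ++b) {
    R_xlen_t base = (R_xlen_t)C * T * b;
    for (int j = 0; j < k; ++j) {
      int off = j - h;
      int t0 = off < 0 ? -off : 0;
      int t1 = off > 0 ? T - off : T;
      for (int t = t0; t < t1; ++t) {
        R_xlen_t yi = base + (R_xlen_t)C * t;
        R_xlen_t xi = base + (R_xlen_t)C * (t + off);
        for (int c = 0; c < C; ++c) {
          dw[c + C * j] += dy[yi + c] * x[xi + c];
          dx[xi + c] += w[c + C * j] * dy[yi + c];
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// Max pooling, window 3, stride 1, 'same' padding (edges use the valid part).

// [[Rcpp::export]]
List maxpool3_fwd(NumericVector x, int C, int T, int B) {
  NumericVector y(x.size());
  IntegerVector idx(x.size());  // time index of the chosen element
  for (int b = 0; b < B; ++b) {
    R_xlen_t base = (R_xlen_t)C * T * b;
    for (int t = 0; t < T; ++t) {
      int s0 = t > 0 ? t - 1 : 0;
      int s1 = t < T - 1 ? t + 1 : T - 1;
      for (int c = 0; c < C; ++c) {
        double best = x[base + (R_xlen_t)C * s0 + c];
        int bs = s0;
        for (int s = s0 + 1; s <= s1; ++s) {
          double v = x[base + (R_xlen_t)C * s + c];
          if (v > best) { best = v; bs = s; }
        }
        y[base + (R_xlen_t)C * t + c] = best;
        idx[base + (R_xlen_t)C * t + c] = bs;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3_bwd(NumericVector dy, IntegerVector idx,
                           int C, int T, int B) {
  NumericVector dx(dy.size());
  for (int b = 0; b < B; ++b) {
    R_xlen_t base = (R_xlen_t)C * T * b;
    for (int t = 0; t < T; ++t)
      for (int c = 0; c < C; ++c) {
        R_xlen_t i = base + (R_xlen_t)C * t + c;
        dx[base + (R_xlen_t)C * idx[i] + c] += dy[i];
      }
  }
  return dx;
}
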