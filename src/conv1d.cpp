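#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Signal batches are (B, L, C) column-major arrays; the batch index is
// fastest, so one (time, channel) slot is a contiguous run of B doubles.

// im2col with implicit zero padding: output is (B * Lo) x (k * C), column
// (dt * C + c) holding the input at kernel offset dt for channel c.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int B, int L, int Cin,
                         int pad, int k) {
  const int Lo = L + 2 * pad - k + 1;
  NumericMatrix out((R_xlen_t)B * Lo, (R_xlen_t)k * Cin);
  const double* xs = x.begin();
  double* os = out.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dt = 0; dt < k; ++dt) {
      double* dst = os + (R_xlen_t)(dt * Cin + ci) * B * Lo;
      for (int t = 0; t < Lo; ++t) {
        const int tp = t + dt - pad;
        double* d = dst + (R_xlen_t)t * B;
        if (tp < 0 || tp >= L) {
          std::memset(d, 0, sizeof(double) * B);
        } else {
          const double* s = xs + (R_xlen_t)B * (tp + (R_xlen_t)L * ci);
          std::memcpy(d, s, sizeof(double) * B);
        }
      }
    }
  }
  return out;
}

// adjoint of cpp_im2col: scatter-add the column gradient back onto the
// (B, L, Cin) input gradient
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dXc, int B, int L, int Cin,
                         int pad, int k) {
  const int Lo = L + 2 * pad - k + 1;
  NumericVector dx((R_xlen_t)B * L * Cin);
  const double* gs = dXc.begin();
  double* ds = dx.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dt = 0; dt < k; ++dt) {
      const double* src = gs + (R_xlen_t)(dt * Cin + ci) * B * Lo;
      for (int t = 0; t < Lo; ++t) {
        const int tp = t + dt - pad;
        if (tp < 0 || tp >= L) continue;
        double* d = ds + (R_xlen_t)B * (tp + (R_xlen_t)L * ci);
        const double* s = src + (R_xlen_t)t * B;
        for (int b = 0; b < B; ++b) d[b] += s[b];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(B, L, Cin);
  return dx;
}

// width-w stride-w average pooling over time, (B, L, C) -> (B, L/w, C);
// trailing samples that do not fill a window are dropped
// [[Rcpp::export]]
NumericVector cpp_poolk(NumericVector x, int B, int L, int C, int w) {
  const int Lo = L / w;
  NumericVector out((R_xlen_t)B * Lo * C);
  const double* xs = x.begin();
  double* os = out.begin();
  const double inv = 1.0 / w;
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < Lo; ++t) {
      double* d = os + (R_xlen_t)B * (t + (R_xlen_t)Lo * c);
      for (int j = 0; j < w; ++j) {
        const double* s = xs + (R_xlen_t)B * (w * t + j + (R_xlen_t)L * c);
        if (j == 0) for (int b = 0; b < B; ++b) d[b] = s[b] * inv;
        else for (int b = 0; b < B; ++b) d[b] += s[b] * inv;
      }
    }
  out.attr("dim") = IntegerVector::create(B, Lo, C);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_poolk_bwd(NumericVector dout, int B, int L_in, int C, int w) {
  const int Lo = L_in / w;
  NumericVector dx((R_xlen_t)B * L_in * C);
  const double* gs = dout.begin();
  double* ds = dx.begin();
  const double inv = 1.0 / w;
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < Lo; ++t) {
      const double* s = gs + (R_xlen_t)B * (t + (R_xlen_t)Lo * c);
      for (int j = 0; j < w; ++j) {
        double* d = ds + (R_xlen_t)B * (w * t + j + (R_xlen_t)L_in * c);
        for (int b = 0; b < B; ++b) d[b] = s[b] * inv;
      }
    }
  dx.attr("dim") = IntegerVector::create(B, L_in, C);
  return dx;
}
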