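// Hot numerical kernels for the network layers: im2col/col2im patch
// extraction for 1-D and 2-D convolution (the matrix products themselves go
// through R's BLAS), depthwise convolution, max pooling, and the Adam
// update. Array layouts match the R side: channel-first, column-major,
// batch last.

#include <Rcpp.h>
using namespace Rcpp;

// ---- 1-D convolution patches ----------------------------------------------
// x: (cin, L, B); returns (cin*k, Lout*B), rows ordered (c, kk).
// [[Rcpp::export]]
NumericMatrix im2col1d_cpp(NumericVector x, int cin, int L, int B,
                           int k, int stride, int pad) {
  int Lout = (L + 2 * pad - k) / stride + 1;
  NumericMatrix M(cin * k, Lout * B);
  for (int b = 0; b < B; ++b) {
    for (int o = 0; o < Lout; ++o) {
      double* mcol = &M(0, b * Lout + o);
      for (int kk = 0; kk < k; ++kk) {
        int pos = o * stride + kk - pad;
        double* dst = mcol + kk * cin;
        if (pos < 0 || pos >= L) {
          for (int c = 0; c < cin; ++c) dst[c] = 0.0;
        } else {
          const double* src = &x[(size_t)cin * (pos + (size_t)L * b)];
          for (int c = 0; c < cin; ++c) dst[c] = src[c];
        }
      }
    }
  }
  return M;
}

// dM: (cin*k, Lout*B) -> dx: (cin, L, B), accumulating over overlaps.
// [[Rcpp::export]]
NumericVector col2im1d_cpp(NumericMatrix dM, int cin, int L, int B,
                           int k, int stride, int pad) {
  int Lout = (L + 2 * pad - k) / stride + 1;
  NumericVector dx((size_t)cin * L * B);
  for (int b = 0; b < B; ++b) {
    for (int o = 0; o < Lout; ++o) {
      const double* mcol = &dM(0, b * Lout + o);
      for (int kk = 0; kk < k; ++kk) {
        int pos = o * stride + kk - pad;
        if (pos < 0 || pos >= L) continue;
        double* dst = &dx[(size_t)cin * (pos + (size_t)L * b)];
        const double* src = mcol + kk * cin;
        for (int c = 0; c < cin; ++c) dst[c] += src[c];
      }
    }
  }
  return dx;
}

// ---- 2-D convolution patches ----------------------------------------------
// x: (cin, H, W, B); returns (cin*k*k, Ho*Wo*B), rows ordered (c, ki, kj),
// columns ordered (oi, oj, b).
// [[Rcpp::export]]
NumericMatrix im2col2d_cpp(NumericVector x, int cin, int H, int W, int B,
                           int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int P = Ho * Wo;
  NumericMatrix M(cin * k * k, (size_t)P * B);
  for (int b = 0; b < B; ++b) {
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        double* mcol = &M(0, (size_t)b * P + oj * Ho + oi);
        for (int kj = 0; kj < k; ++kj) {
          int jj = oj * stride + kj - pad;
          for (int ki = 0; ki < k; ++ki) {
            int ii = oi * stride + ki - pad;
            double* dst = mcol + (size_t)cin * (ki + k * kj);
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) {
              for (int c = 0; c < cin; ++c) dst[c] = 0.0;
            } else {
              const double* src =
                &x[(size_t)cin * (ii + (size_t)H * (jj + (size_t)W * b))];
              for (int c = 0; c < cin; ++c) dst[c] = src[c];
            }
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector col2im2d_cpp(NumericMatrix dM, int cin, int H, int W, int B,
                           int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int P = Ho * Wo;
  NumericVector dx((size_t)cin * H * W * B);
  for (int b = 0; b < B; ++b) {
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        const double* mcol = &dM(0, (size_t)b * P + oj * Ho + oi);
        for (int kj = 0; kj < k; ++kj) {
          int jj = oj * stride + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            double* dst =
              &dx[(size_t)cin * (ii + (size_t)H * (jj + (size_t)W * b))];
            const double* src = mcol + (size_t)cin * (ki + k * kj);
            for (int c = 0; c < cin; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return dx;
}

// ---- depthwise convolution -------------------------------------------------
// x: (C, H, W, B), w: (C, k, k) -> y: (C, Ho, Wo, B)
// [[Rcpp::export]]
NumericVector dwconv_fw_cpp(NumericVector x, NumericVector w, int C, int H,
                            int W, int B, int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)C * Ho * Wo * B);
  for (int b = 0; b < B; ++b) {
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        double* dst =
          &y[(size_t)C * (oi + (size_t)Ho * (oj + (size_t)Wo * b))];
        for (int kj = 0; kj < k; ++kj) {
          int jj = oj * stride + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            const double* src =
              &x[(size_t)C * (ii + (size_t)H * (jj + (size_t)W * b))];
            const double* wv = &w[(size_t)C * (ki + k * kj)];
            for (int c = 0; c < C; ++c) dst[c] += src[c] * wv[c];
          }
        }
      }
    }
  }
  return y;
}

// returns list(dx, dw); gy: (C, Ho, Wo, B)
// [[Rcpp::export]]
List dwconv_bw_cpp(NumericVector x, NumericVector w, NumericVector gy,
                   int C, int H, int W, int B, int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector dx((size_t)C * H * W * B);
  NumericVector dw((size_t)C * k * k);
  for (int b = 0; b < B; ++b) {
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        const double* g =
          &gy[(size_t)C * (oi + (size_t)Ho * (oj + (size_t)Wo * b))];
        for (int kj = 0; kj < k; ++kj) {
          int jj = oj * stride + kj - pad;
          if (jj < 0 || jj >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            int ii = oi * stride + ki - pad;
            if (ii < 0 || ii >= H) continue;
            const double* src =
              &x[(size_t)C * (ii + (size_t)H * (jj + (size_t)W * b))];
            double* dsrc =
              &dx[(size_t)C * (ii + (size_t)H * (jj + (size_t)W * b))];
            const double* wv = &w[(size_t)C * (ki + k * kj)];
            double* dwv = &dw[(size_t)C * (ki + k * kj)];
            for (int c = 0; c < C; ++c) {
              dsrc[c] += g[c] * wv[c];
              dwv[c] += g[c] * src[c];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw);
}

// ---- max pooling ------------------------------------------------------------
// x: (C, H, W, B) -> list(y: (C, Ho, Wo, B), amax: flat 0-based input index)
// [[Rcpp::export]]
List maxpool_fw_cpp(NumericVector x, int C, int H, int W, int B,
                    int k, int stride, int pad) {
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  size_t n = (size_t)C * Ho * Wo * B;
  NumericVector y(n);
  IntegerVector amax(n);
  for (int b = 0; b < B; ++b) {
    for (int oj = 0; oj < Wo; ++oj) {
      for (int oi = 0; oi < Ho; ++oi) {
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          size_t bestIdx = 0;
          for (int kj = 0; kj < k; ++kj) {
            int jj = oj * stride + kj - pad;
            if (jj < 0 || jj >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int ii = oi * stride + ki - pad;
              if (ii < 0 || ii >= H) continue;
              size_t idx =
                c + (size_t)C * (ii + (size_t)H * (jj + (size_t)W * b));
              if (x[idx] > best) { best = x[idx]; bestIdx = idx; }
            }
          }
          size_t o =
            c + (size_t)C * (oi + (size_t)Ho * (oj + (size_t)Wo * b));
          y[o] = best;
          amax[o] = (int)bestIdx;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool_bw_cpp(NumericVector gy, IntegerVector amax,
                             size_t nIn) {
  NumericVector dx(nIn);
  for (R_xlen_t i = 0; i < gy.size(); ++i) dx[amax[i]] += gy[i];
  return dx;
}

// ---- Adam -------------------------------------------------------------------
// Updates m and v in place (optimizer-private buffers) and returns the new
// parameter vector.
// [[Rcpp::export]]
NumericVector adam_step_cpp(NumericVector p, NumericVector g,
                            NumericVector m, NumericVector v,
                            double lr, double beta1, double beta2,
                            double eps, double bc1, double bc2) {
  R_xlen_t n = p.size();
  NumericVector out(n);
  const double* pp = REAL(p);
  const double* pg = REAL(g);
  double* pm = REAL(m);
  double* pv = REAL(v);
  double* po = REAL(out);
  const double im1 = 1 - beta1, im2 = 1 - beta2;
  const double s2 = 1.0 / std::sqrt(bc2);
  const double a = lr / bc1;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = pg[i];
    const double mi = beta1 * pm[i] + im1 * gi;
    const double vi = beta2 * pv[i] + im2 * gi * gi;
    pm[i] = mi;
    pv[i] = vi;
    po[i] = pp[i] - a * mi / (std::sqrt(vi) * s2 + eps);
  }
  out.attr("dim") = p.attr("dim");
  return out;
}
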