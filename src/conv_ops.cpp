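// Compute kernels for the auto-encoder: strided 2-D convolution via
// im2col + GEMM (images processed in chunks so the GEMMs are well
// shaped), plus fused batch-norm, ReLU and nearest-neighbour
// up-sampling. Array layout follows R column-major conventions:
//   activations: (H, W, C, B), weights: (kh, kw, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int CHUNK = 8;  // images per im2col/GEMM block

// Patch matrix in transposed layout: colsT is (Ho*Wo) x (kh*kw*C),
// column-major, so for a fixed patch offset (ki,kj,c) the inner loop
// over output rows is a contiguous copy from the image column.
static inline void im2col_one(const double* x, int H, int W, int C,
                              int kh, int kw, int stride, int pad,
                              int Ho, int Wo, double* colsT,
                              size_t ld /* rows of colsT */) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        double* dst = colsT + ld * r;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kj;
          double* d = dst + (size_t)Ho * wo;
          if (w < 0 || w >= W) {
            std::fill(d, d + Ho, 0.0);
            continue;
          }
          const double* src = xc + (size_t)H * w + (ki - pad);
          // valid output rows: 0 <= ho*stride + ki - pad < H
          const int lo = (ki - pad < 0)
            ? (pad - ki + stride - 1) / stride : 0;
          const int hi = std::min(Ho, (H - 1 - (ki - pad)) / stride + 1);
          for (int ho = 0; ho < lo; ++ho) d[ho] = 0.0;
          if (stride == 1) {
            for (int ho = lo; ho < hi; ++ho) d[ho] = src[ho];
          } else {
            for (int ho = lo; ho < hi; ++ho) d[ho] = src[(size_t)ho * stride];
          }
          for (int ho = hi; ho < Ho; ++ho) d[ho] = 0.0;
        }
      }
    }
  }
}

static inline void col2im_one(const double* colsT, int H, int W, int C,
                              int kh, int kw, int stride, int pad,
                              int Ho, int Wo, double* dx, size_t ld) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        const double* src = colsT + ld * r;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kj;
          if (w < 0 || w >= W) continue;
          const double* s = src + (size_t)Ho * wo;
          double* d = xc + (size_t)H * w + (ki - pad);
          const int lo = (ki - pad < 0)
            ? (pad - ki + stride - 1) / stride : 0;
          const int hi = std::min(Ho, (H - 1 - (ki - pad)) / stride + 1);
          if (stride == 1) {
            for (int ho = lo; ho < hi; ++ho) d[ho] += s[ho];
          } else {
            for (int ho = lo; ho < hi; ++ho) d[(size_t)ho * stride] += s[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward(NumericVector x, NumericVector w,
                             NumericVector bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], K = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int R = kh * kw * C;
  const size_t HWo = (size_t)Ho * Wo;

  const arma::mat W2(const_cast<double*>(w.begin()), R, K, false, true);
  NumericVector out(HWo * K * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, K, B);
  const int chunk = std::min(B, CHUNK);
  const size_t ld = HWo * chunk;  // rows of the chunk patch matrix
  arma::mat colsT(ld, R);
  arma::mat obuf(ld, K);

  for (int b0 = 0; b0 < B; b0 += CHUNK) {
    const int nb = std::min(CHUNK, B - b0);
    for (int i = 0; i < nb; ++i) {
      im2col_one(x.begin() + (size_t)H * W * C * (b0 + i), H, W, C,
                 kh, kw, stride, pad, Ho, Wo, colsT.memptr() + HWo * i, ld);
    }
    arma::mat o(obuf.memptr(), ld, K, false, true);
    o = colsT * W2;  // (ld x R)(R x K); trailing ld-HWo*nb rows are scratch
    // scatter (pos, k) of each chunk image into the (Ho,Wo,K,B) output
    for (int i = 0; i < nb; ++i) {
      double* dst = out.begin() + HWo * K * (b0 + i);
      for (int k = 0; k < K; ++k) {
        const double* src = o.colptr(k) + HWo * i;
        const double bk = bias[k];
        double* d = dst + HWo * k;
        for (size_t p = 0; p < HWo; ++p) d[p] = src[p] + bk;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dout,
                     int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), od = dout.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], K = wd[3];
  const int Ho = od[0], Wo = od[1];
  const int R = kh * kw * C;
  const size_t HWo = (size_t)Ho * Wo;

  const arma::mat W2(const_cast<double*>(w.begin()), R, K, false, true);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(K);
  arma::mat dW2(dw.begin(), R, K, false, true);
  arma::vec dB(db.begin(), K, false, true);

  const int chunk = std::min(B, CHUNK);
  const size_t ld = HWo * chunk;
  arma::mat colsT(ld, R);
  arma::mat D(ld, K);
  arma::mat dcolsT(ld, R);

  for (int b0 = 0; b0 < B; b0 += CHUNK) {
    const int nb = std::min(CHUNK, B - b0);
    if (nb < chunk) { colsT.zeros(); D.zeros(); }  // mask scratch rows
    for (int i = 0; i < nb; ++i) {
      im2col_one(x.begin() + (size_t)H * W * C * (b0 + i), H, W, C,
                 kh, kw, stride, pad, Ho, Wo, colsT.memptr() + HWo * i, ld);
      // gather dout image into the chunk gradient buffer
      const double* src = dout.begin() + HWo * K * (b0 + i);
      for (int k = 0; k < K; ++k) {
        std::copy(src + HWo * k, src + HWo * (k + 1), D.colptr(k) + HWo * i);
      }
    }
    dW2 += colsT.t() * D;
    dB += arma::sum(D, 0).t();
    dcolsT = D * W2.t();
    for (int i = 0; i < nb; ++i) {
      col2im_one(dcolsT.memptr() + HWo * i, H, W, C, kh, kw, stride, pad,
                 Ho, Wo, dx.begin() + (size_t)H * W * C * (b0 + i), ld);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---- batch normalisation over (H, W, B) per channel ----

// [[Rcpp::export]]
List bn_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], B = xd[3];
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int b = 0; b < B; ++b) {
      const double* p = x.begin() + HW * (c + (size_t)C * b);
      for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double n = (double)HW * B;
    mean[c] = s / n;
    var[c] = s2 / n - mean[c] * mean[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = gamma * (x - mean)/sqrt(var + eps) + beta; also returns xhat
// [[Rcpp::export]]
List bn_apply(NumericVector x, NumericVector gamma, NumericVector beta,
              NumericVector mean, NumericVector var, double eps,
              bool keep_xhat) {
  IntegerVector xd = x.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], B = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericVector xhat;
  if (keep_xhat) { xhat = NumericVector(x.size()); xhat.attr("dim") = xd; }
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], bt = beta[c], mu = mean[c];
    for (int b = 0; b < B; ++b) {
      const size_t off = HW * (c + (size_t)C * b);
      const double* p = x.begin() + off;
      double* q = y.begin() + off;
      if (keep_xhat) {
        double* h = xhat.begin() + off;
        for (size_t i = 0; i < HW; ++i) {
          h[i] = (p[i] - mu) * inv;
          q[i] = g * h[i] + bt;
        }
      } else {
        for (size_t i = 0; i < HW; ++i) q[i] = g * (p[i] - mu) * inv + bt;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// [[Rcpp::export]]
List bn_backward_cpp(NumericVector xhat, NumericVector dy,
                     NumericVector gamma, NumericVector var, double eps,
                     bool training) {
  IntegerVector xd = xhat.attr("dim");
  const size_t HW = (size_t)xd[0] * xd[1];
  const int C = xd[2], B = xd[3];
  NumericVector dx(xhat.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sb = 0.0;
    for (int b = 0; b < B; ++b) {
      const size_t off = HW * (c + (size_t)C * b);
      const double* h = xhat.begin() + off;
      const double* d = dy.begin() + off;
      for (size_t i = 0; i < HW; ++i) { sg += d[i] * h[i]; sb += d[i]; }
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double inv = gamma[c] / std::sqrt(var[c] + eps);
    const double n = (double)HW * B;
    for (int b = 0; b < B; ++b) {
      const size_t off = HW * (c + (size_t)C * b);
      const double* h = xhat.begin() + off;
      const double* d = dy.begin() + off;
      double* o = dx.begin() + off;
      if (training) {
        for (size_t i = 0; i < HW; ++i) {
          o[i] = inv * (d[i] - sb / n - h[i] * sg / n);
        }
      } else {
        for (size_t i = 0; i < HW; ++i) o[i] = inv * d[i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---- ReLU ----

// [[Rcpp::export]]
NumericVector relu_forward(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin();
  double* q = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) q[i] = p[i] > 0 ? p[i] : 0.0;
  return y;
}

// dx = dout where the forward output was positive
// [[Rcpp::export]]
NumericVector relu_backward(NumericVector dout, NumericVector out) {
  NumericVector dx(dout.size());
  dx.attr("dim") = dout.attr("dim");
  const double* d = dout.begin();
  const double* o = out.begin();
  double* q = dx.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i) q[i] = o[i] > 0 ? d[i] : 0.0;
  return dx;
}

// ---- factor-2 nearest-neighbour up-sampling ----

// [[Rcpp::export]]
NumericVector upsample2_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  NumericVector y((size_t)4 * H * W * C * B);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, B);
  const int H2 = 2 * H;
  for (int cb = 0; cb < C * B; ++cb) {
    const double* p = x.begin() + (size_t)H * W * cb;
    double* q = y.begin() + (size_t)4 * H * W * cb;
    for (int w = 0; w < W; ++w) {
      double* q0 = q + (size_t)H2 * 2 * w;
      double* q1 = q0 + H2;
      const double* pc = p + (size_t)H * w;
      for (int h = 0; h < H; ++h) {
        const double v = pc[h];
        q0[2 * h] = v; q0[2 * h + 1] = v;
        q1[2 * h] = v; q1[2 * h + 1] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_backward(NumericVector dout) {
  IntegerVector od = dout.attr("dim");
  const int H2 = od[0], W2 = od[1], C = od[2], B = od[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  for (int cb = 0; cb < C * B; ++cb) {
    const double* q = dout.begin() + (size_t)H2 * W2 * cb;
    double* p = dx.begin() + (size_t)H * W * cb;
    for (int w = 0; w < W; ++w) {
      const double* q0 = q + (size_t)H2 * 2 * w;
      const double* q1 = q0 + H2;
      double* pc = p + (size_t)H * w;
      for (int h = 0; h < H; ++h) {
        pc[h] = q0[2 * h] + q0[2 * h + 1] + q1[2 * h] + q1[2 * h + 1];
      }
    }
  }
  return dx;
}
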