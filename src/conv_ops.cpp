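// 2-D convolution (cross-correlation) via im2col + GEMM.
// Tensor layout follows R's column-major arrays with dim (H, W, C, N) so a
// single channel slice is a contiguous H x W matrix; weights are (KH, KW, C, O).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void tensor_dims(const NumericVector& x, int d[4]) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a 4-D tensor");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

static void im2col(const double* x, int H, int W, int C,
                   int KH, int KW, int stride, int pad,
                   int OH, int OW, arma::mat& col) {
  // col is P x K with P = OH*OW, K = KH*KW*C, k = kh + KH*(kw + KW*c)
  const int P = OH * OW;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        double* dst = col.colptr(kh + KH * (kw + KW * c));
        for (int ow = 0; ow < OW; ++ow) {
          int wi = ow * stride - pad + kw;
          if (wi < 0 || wi >= W) {
            for (int oh = 0; oh < OH; ++oh) dst[oh + OH * ow] = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)wi * H;
          for (int oh = 0; oh < OH; ++oh) {
            int hi = oh * stride - pad + kh;
            dst[oh + OH * ow] = (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
          }
        }
      }
    }
  }
  (void)P;
}

static void col2im(const arma::mat& col, int H, int W, int C,
                   int KH, int KW, int stride, int pad,
                   int OH, int OW, double* gx) {
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)c * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const double* src = col.colptr(kh + KH * (kw + KW * c));
        for (int ow = 0; ow < OW; ++ow) {
          int wi = ow * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)wi * H;
          for (int oh = 0; oh < OH; ++oh) {
            int hi = oh * stride - pad + kh;
            if (hi >= 0 && hi < H) xcol[hi] += src[oh + OH * ow];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  int xd[4], wd[4];
  tensor_dims(x, xd);
  tensor_dims(w, wd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], O = wd[3];
  if (wd[2] != C) stop("conv2d: weight expects %d channels, got %d", wd[2], C);
  const int OH = (H + 2 * pad - KH) / stride + 1;
  const int OW = (W + 2 * pad - KW) / stride + 1;
  if (OH <= 0 || OW <= 0) stop("conv2d: output size would be non-positive");
  const int P = OH * OW, K = KH * KW * C;

  arma::mat Wmat(const_cast<double*>(w.begin()), K, O, false, true);
  NumericVector out(Rf_allocVector(REALSXP, (R_xlen_t)P * O * N));
  out.attr("dim") = IntegerVector::create(OH, OW, O, N);
  arma::mat col(P, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad,
           OH, OW, col);
    arma::mat y(out.begin() + (size_t)n * P * O, P, O, false, true);
    y = col * Wmat;
    if (b.size() > 0) {
      for (int o = 0; o < O; ++o) y.col(o) += b[o];
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad) {
  int xd[4], wd[4], gd[4];
  tensor_dims(x, xd);
  tensor_dims(w, wd);
  tensor_dims(gy, gd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], O = wd[3];
  const int OH = gd[0], OW = gd[1];
  const int P = OH * OW, K = KH * KW * C;

  arma::mat Wmat(const_cast<double*>(w.begin()), K, O, false, true);
  NumericVector gx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * C * N));
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::fill(gx.begin(), gx.end(), 0.0);
  NumericVector gw(Rf_allocVector(REALSXP, (R_xlen_t)K * O));
  gw.attr("dim") = IntegerVector::create(KH, KW, C, O);
  std::fill(gw.begin(), gw.end(), 0.0);
  NumericVector gb(O);

  arma::mat gWmat(gw.begin(), K, O, false, true);
  arma::mat col(P, K), gcol(P, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad,
           OH, OW, col);
    arma::mat gyM(const_cast<double*>(gy.begin()) + (size_t)n * P * O,
                  P, O, false, true);
    gWmat += col.t() * gyM;
    gcol = gyM * Wmat.t();
    col2im(gcol, H, W, C, KH, KW, stride, pad, OH, OW,
           gx.begin() + (size_t)n * H * W * C);
    for (int o = 0; o < O; ++o) gb[o] += arma::accu(gyM.col(o));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
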