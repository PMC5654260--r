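// im2col-based valid convolution and 2x2-style max pooling, forward and
// backward, on (H, W, C, N) column-major arrays. The heavy lifting is a
// BLAS matrix product per sample via Armadillo.
#include <RcppArmadillo.h>
using namespace Rcpp;
// [[Rcpp::depends(RcppArmadillo)]]

static inline R_xlen_t idx4(int i, int j, int c, int n, int H, int W, int C) {
  return i + (R_xlen_t)H * (j + (R_xlen_t)W * (c + (R_xlen_t)C * n));
}

static void im2col(const double* xp, int n, int H, int W, int C, int kh,
                   int kw, arma::mat& col) {
  int Ho = H - kh + 1, Wo = W - kw + 1;
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      double* dst = col.colptr(io + (R_xlen_t)Ho * jo);
      int r = 0;
      for (int c = 0; c < C; ++c)
        for (int kj = 0; kj < kw; ++kj)
          for (int ki = 0; ki < kh; ++ki)
            dst[r++] = xp[idx4(io + ki, jo + kj, c, n, H, W, C)];
    }
  }
}

// x: (H,W,C,N); w: (kh,kw,C,F); b: length F  ->  y: (Ho,Wo,F,N)
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  if (wd[2] != C) stop("filter channel count does not match input");
  int Ho = H - kh + 1, Wo = W - kw + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than input");
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, F, false, true);
  arma::mat col(kh * kw * C, (R_xlen_t)Ho * Wo);
  NumericVector y((R_xlen_t)Ho * Wo * F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  double* yp = y.begin();
  const double* xp = x.begin();
  R_xlen_t plane = (R_xlen_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    im2col(xp, n, H, W, C, kh, kw, col);
    arma::mat ym = Wm.t() * col;  // F x (Ho*Wo)
    for (int f = 0; f < F; ++f) {
      double bf = b[f];
      double* dst = yp + plane * (f + (R_xlen_t)F * n);
      for (R_xlen_t q = 0; q < plane; ++q) dst[q] = ym(f, q) + bf;
    }
  }
  return y;
}

// Gradients of the valid convolution. dy: (Ho,Wo,F,N).
// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  int Ho = H - kh + 1, Wo = W - kw + 1;
  R_xlen_t plane = (R_xlen_t)Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, F, false, true);
  arma::mat col(kh * kw * C, plane);
  arma::mat dW(kh * kw * C, F, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  double* dxp = dx.begin();
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  arma::mat dym(F, plane);
  for (int n = 0; n < N; ++n) {
    for (int f = 0; f < F; ++f) {
      const double* src = dyp + plane * (f + (R_xlen_t)F * n);
      for (R_xlen_t q = 0; q < plane; ++q) dym(f, q) = src[q];
    }
    im2col(xp, n, H, W, C, kh, kw, col);
    dW += col * dym.t();
    db += arma::sum(dym, 1);
    arma::mat dcol = Wm * dym;  // (kh*kw*C) x plane
    // col2im accumulate
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const double* src = dcol.colptr(io + (R_xlen_t)Ho * jo);
        int r = 0;
        for (int c = 0; c < C; ++c)
          for (int kj = 0; kj < kw; ++kj)
            for (int ki = 0; ki < kh; ++ki)
              dxp[idx4(io + ki, jo + kj, c, n, H, W, C)] += src[r++];
      }
    }
  }
  NumericVector dwOut(w.size());
  dwOut.attr("dim") = wd;
  std::copy(dW.begin(), dW.end(), dwOut.begin());
  NumericVector dbOut(F);
  std::copy(db.begin(), db.end(), dbOut.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwOut, _["db"] = dbOut);
}

// Non-overlapping p x p max pooling; trailing rows/cols that do not fill a
// window are dropped. idx stores the argmax as (i + H*j) within the slice.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int p) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / p, Wo = W / p;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  R_xlen_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          double best = -1e300;
          int barg = 0;
          for (int kj = 0; kj < p; ++kj) {
            for (int ki = 0; ki < p; ++ki) {
              int i = io * p + ki, j = jo * p + kj;
              double v = xp[base + i + (R_xlen_t)H * j];
              if (v > best) {
                best = v;
                barg = i + H * j;
              }
            }
          }
          // column-major write order matches loop order (io fastest after
          // jo within (c,n)) -- recompute target explicitly for clarity
          q = io + (R_xlen_t)Ho * (jo + (R_xlen_t)Wo * (c + (R_xlen_t)C * n));
          yp[q] = best;
          ip[q] = barg;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx,
                              IntegerVector xdim) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  int H = xdim[0], W = xdim[1];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xdim;
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          R_xlen_t q =
              io + (R_xlen_t)Ho * (jo + (R_xlen_t)Wo * (c + (R_xlen_t)C * n));
          dxp[base + ip[q]] += dyp[q];
        }
      }
    }
  }
  return dx;
}
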