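// Low-level tensor kernels for the segmentation network engine.
// Layout convention: activations are column-major R arrays (H, W, C, N);
// convolution weights are (k, k, C_in, C_out). Stride is always 1 with
// "same" padding (asymmetric for even kernels: floor((k-1)/2) before,
// the remainder after, matching the common framework convention).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const double* x, int H, int W, int C, int k,
                        int pad_before) {
  // rows: output pixels (h + H*w), cols: kh + k*kw + k*k*c
  arma::mat P(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int col = kh + k * kw + k * k * c;
        for (int w = 0; w < W; ++w) {
          int iw = w - pad_before + kw;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H; ++h) {
            int ih = h - pad_before + kh;
            if (ih < 0 || ih >= H) continue;
            P(h + H * w, col) = xc[ih + (size_t)H * iw];
          }
        }
      }
    }
  }
  return P;
}

static void col2im_add(double* gx, const arma::mat& gP, int H, int W, int C,
                       int k, int pad_before) {
  for (int c = 0; c < C; ++c) {
    double* gxc = gx + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        int col = kh + k * kw + k * k * c;
        for (int w = 0; w < W; ++w) {
          int iw = w - pad_before + kw;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H; ++h) {
            int ih = h - pad_before + kh;
            if (ih < 0 || ih >= H) continue;
            gxc[ih + (size_t)H * iw] += gP(h + H * w, col);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         Nullable<NumericVector> bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  int pad_before = (k - 1) / 2;
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false, true);
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::rowvec b(Cout, arma::fill::zeros);
  if (bias.isNotNull()) {
    NumericVector bb(bias);
    b = arma::rowvec(bb.begin(), Cout);
  }
  for (int n = 0; n < N; ++n) {
    arma::mat P = im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, pad_before);
    arma::mat Y = P * Wm;
    Y.each_row() += b;
    std::copy(Y.begin(), Y.end(), y.begin() + (size_t)H * W * Cout * n);
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int pad_before = (k - 1) / 2;
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * C, Cout, false, true);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  arma::mat gW(k * k * C, Cout, arma::fill::zeros);
  arma::rowvec gb(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat P = im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, pad_before);
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)H * W * Cout * n,
                 H * W, Cout, false, true);
    gW += P.t() * Gy;
    if (has_bias) gb += arma::sum(Gy, 0);
    arma::mat gP = Gy * Wm.t();
    col2im_add(gx.begin() + (size_t)H * W * C * n, gP, H, W, C, k, pad_before);
  }
  NumericVector gwv(gW.begin(), gW.end());
  gwv.attr("dim") = wd;
  List out = List::create(_["gx"] = gx, _["gw"] = gwv);
  if (has_bias) out["gb"] = NumericVector(gb.begin(), gb.end());
  return out;
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // 0-based linear index into x
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h, ++o) {
          int h0 = 2 * h, w0 = 2 * w;
          size_t best = h0 + (size_t)H * w0;
          double bv = xp[best];
          size_t cand[3] = {h0 + 1 + (size_t)H * w0, h0 + (size_t)H * (w0 + 1),
                            h0 + 1 + (size_t)H * (w0 + 1)};
          for (int q = 0; q < 3; ++q)
            if (xp[cand[q]] > bv) { bv = xp[cand[q]]; best = cand[q]; }
          y[o] = bv;
          idx[o] = (int)(base + best);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector gy, IntegerVector idx,
                           IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}
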