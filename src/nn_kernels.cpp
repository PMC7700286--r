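// Low-level tensor kernels for the conv-net engine.
// Tensor layout everywhere: R array with dim = c(H, W, C, N), column-major,
// i.e. element (h, w, c, n) sits at h + w*H + c*H*W + n*H*W*C.
// Weight layout: dim = c(kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uvec tensor_dims(const NumericVector& x, int need) {
  IntegerVector d = x.attr("dim");
  if (d.size() != need) stop("expected a %d-d array", need);
  return arma::conv_to<arma::uvec>::from(as<arma::ivec>(d));
}

// Fill `col` (kh*kw*Cin x Ho*Wo) from one sample (pointer to H*W*Cin block).
static void im2col_one(const double* x, int H, int W, int Cin,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, arma::mat& col) {
  col.zeros();
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (size_t)wi * H;
          double* cdst = col.colptr(0) + row; // col(row, p), p = ho + Ho*wo
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            cdst[(size_t)(ho + Ho * wo) * col.n_rows] = xcol[hi];
          }
        }
      }
    }
  }
}

// Scatter-add `col` back into one sample of dx.
static void col2im_one(const arma::mat& col, double* dx, int H, int W, int Cin,
                       int kh, int kw, int stride, int pad, int Ho, int Wo) {
  for (int c = 0; c < Cin; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int row = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            xcol[hi] += col(row, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  arma::uvec xd = tensor_dims(x, 4), wd = tensor_dims(w, 4);
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  if ((int)wd[2] != Cin) stop("conv2d: channel mismatch");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: kernel larger than padded input");
  int K = kh * kw * Cin, P = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::vec bv(const_cast<double*>(b.begin()), Cout, false, true);

  NumericVector out((size_t)P * Cout * N);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
               kh, kw, stride, pad, Ho, Wo, col);
    arma::mat on(out.begin() + (size_t)n * P * Cout, P, Cout, false, true);
    on = col.t() * Wm;
    on.each_row() += bv.t();
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dout,
                int stride, int pad, bool need_dx) {
  arma::uvec xd = tensor_dims(x, 4), wd = tensor_dims(w, 4),
             od = tensor_dims(dout, 4);
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = od[0], Wo = od[1];
  int K = kh * kw * Cin, P = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);

  NumericVector dw((size_t)K * Cout), db(Cout);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  NumericVector dx(need_dx ? x.size() : 0);
  arma::mat col(K, P), dcol(K, P);
  for (int n = 0; n < N; ++n) {
    arma::mat Dn(const_cast<double*>(dout.begin()) + (size_t)n * P * Cout,
                 P, Cout, false, true);
    im2col_one(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
               kh, kw, stride, pad, Ho, Wo, col);
    dWm += col * Dn;
    dbv += arma::sum(Dn, 0).t();
    if (need_dx) {
      dcol = Wm * Dn.t();
      col2im_one(dcol, dx.begin() + (size_t)n * H * W * Cin,
                 H, W, Cin, kh, kw, stride, pad, Ho, Wo);
    }
  }
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  if (need_dx) dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  return List::create(_["dw"] = dw, _["db"] = db,
                      _["dx"] = need_dx ? dx : NumericVector(0));
}

// [[Rcpp::export(name = ".maxpool_fwd")]]
List maxpool_fwd(NumericVector x, int k, int stride) {
  arma::uvec xd = tensor_dims(x, 4);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = (H - k) / stride + 1, Wo = (W - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("maxpool: window larger than input");
  size_t M = (size_t)Ho * Wo * C * N;
  NumericVector out(M);
  IntegerVector idx(M); // 0-based linear index into x of each max
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; size_t bidx = 0;
          for (int kj = 0; kj < k; ++kj)
            for (int ki = 0; ki < k; ++ki) {
              size_t ii = (size_t)(wo * stride + kj) * H + ho * stride + ki;
              if (xc[ii] > best) { best = xc[ii]; bidx = ii; }
            }
          // out layout (Ho,Wo,C,N): position within (c,n) block is ho+Ho*wo
          o = base / ((size_t)H * W) * Ho * Wo + (size_t)wo * Ho + ho;
          out[o] = best; idx[o] = (int)(base + bidx);
        }
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bwd")]]
NumericVector maxpool_bwd(NumericVector dout, IntegerVector idx,
                          IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[idx[i]] += dout[i];
  dx.attr("dim") = xdim;
  return dx;
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x) {
  arma::uvec xd = tensor_dims(x, 4);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int H2 = 2 * H, W2 = 2 * W;
  NumericVector out((size_t)H2 * W2 * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = x.begin() + ((size_t)n * C + c) * H * W;
      double* dst = out.begin() + ((size_t)n * C + c) * H2 * W2;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double v = src[(size_t)w * H + h];
          size_t b = (size_t)(2 * w) * H2 + 2 * h;
          dst[b] = v; dst[b + 1] = v;
          dst[b + H2] = v; dst[b + H2 + 1] = v;
        }
    }
  out.attr("dim") = IntegerVector::create(H2, W2, C, N);
  return out;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector dout) {
  arma::uvec od = tensor_dims(dout, 4);
  int H2 = od[0], W2 = od[1], C = od[2], N = od[3];
  int H = H2 / 2, W = W2 / 2;
  NumericVector dx((size_t)H * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dst = dx.begin() + ((size_t)n * C + c) * H * W;
      const double* src = dout.begin() + ((size_t)n * C + c) * H2 * W2;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          size_t b = (size_t)(2 * w) * H2 + 2 * h;
          dst[(size_t)w * H + h] = src[b] + src[b + 1] + src[b + H2] + src[b + H2 + 1];
        }
    }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
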