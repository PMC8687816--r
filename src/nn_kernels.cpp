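// Low-level dense 2-D convolution and max-pooling kernels (forward + backward)
// used by the network layers in R/nn.R.  Arrays are column-major with
// dimensions (H, W, C, B): H = temporal axis, W = spatial/source axis,
// C = feature maps, B = batch.  Convolution is implemented as im2col + GEMM
// per sample; the im2col row index dh + kh*(dw + kw*ci) matches the
// column-major layout of a (kh, kw, Cin, Cout) weight array, so the weight
// array can be reinterpreted as a (kh*kw*Cin) x Cout matrix without copying.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int conv_out(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

static void im2col(const double* x, int H, int W, int Ci,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int OH, int OW, arma::mat& M) {
  // M: (kh*kw*Ci) x (OH*OW), column q = oh + OH*ow, row r = dh + kh*(dw + kw*ci).
  // Columns are filled contiguously (r fastest) so writes stream through M.
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      double* col = M.colptr(oh + OH * ow);
      int h0 = oh * sh - ph, w0 = ow * sw - pw;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xc = x + (size_t)ci * H * W;
        for (int dw = 0; dw < kw; ++dw) {
          int iw = w0 + dw;
          if (iw < 0 || iw >= W) {
            for (int dh = 0; dh < kh; ++dh) *col++ = 0.0;
          } else {
            const double* xw = xc + (size_t)iw * H;
            for (int dh = 0; dh < kh; ++dh) {
              int ih = h0 + dh;
              *col++ = (ih < 0 || ih >= H) ? 0.0 : xw[ih];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector bias,
                                 int sh, int sw, int ph, int pw,
                                 bool apply_elu) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Ci = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], Co = wd[3];
  if (wd[2] != Ci) stop("conv2d: weight in_channels %d != input channels %d", (int)wd[2], Ci);
  int OH = conv_out(H, kh, sh, ph), OW = conv_out(W, kw, sw, pw);
  int K = kh * kw * Ci;

  NumericVector y((R_xlen_t)OH * OW * Co * B);
  y.attr("dim") = IntegerVector::create(OH, OW, Co, B);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Co, false, true);
  arma::mat M(K, OH * OW);
  arma::rowvec bv(const_cast<double*>(bias.begin()), Co, false, true);

  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)b * H * W * Ci, H, W, Ci,
           kh, kw, sh, sw, ph, pw, OH, OW, M);
    arma::mat Yb(y.begin() + (size_t)b * OH * OW * Co, OH * OW, Co, false, true);
    Yb = M.t() * Wm;
    Yb.each_row() += bv;
  }
  if (apply_elu) {
    double* p = y.begin();
    for (R_xlen_t i = 0; i < y.size(); ++i)
      if (p[i] < 0) p[i] = std::expm1(p[i]);
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         int sh, int sw, int ph, int pw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Ci = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], Co = wd[3];
  int OH = conv_out(H, kh, sh, ph), OW = conv_out(W, kw, sw, pw);
  int K = kh * kw * Ci;

  NumericVector dx((R_xlen_t)H * W * Ci * B);
  dx.attr("dim") = IntegerVector::create(H, W, Ci, B);
  NumericVector dw((R_xlen_t)kh * kw * Ci * Co);
  dw.attr("dim") = IntegerVector::create(kh, kw, Ci, Co);
  NumericVector db(Co);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Co, false, true);
  arma::mat dWm(dw.begin(), K, Co, false, true);
  arma::vec dbv(db.begin(), Co, false, true);
  arma::mat M(K, OH * OW);

  for (int b = 0; b < B; ++b) {
    arma::mat dYb(const_cast<double*>(dy.begin()) + (size_t)b * OH * OW * Co,
                  OH * OW, Co, false, true);
    im2col(x.begin() + (size_t)b * H * W * Ci, H, W, Ci,
           kh, kw, sh, sw, ph, pw, OH, OW, M);
    dWm += M * dYb;
    dbv += arma::sum(dYb, 0).t();
    arma::mat dM = Wm * dYb.t();  // K x (OH*OW)
    // col2im: scatter-add the patch gradients back onto the input plane,
    // reading dM contiguously column by column
    double* dxb = dx.begin() + (size_t)b * H * W * Ci;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const double* col = dM.colptr(oh + OH * ow);
        int h0 = oh * sh - ph, w0 = ow * sw - pw;
        for (int ci = 0; ci < Ci; ++ci) {
          double* dxc = dxb + (size_t)ci * H * W;
          for (int dw2 = 0; dw2 < kw; ++dw2) {
            int iw = w0 + dw2;
            if (iw < 0 || iw >= W) { col += kh; continue; }
            double* dxw = dxc + (size_t)iw * H;
            for (int dh = 0; dh < kh; ++dh) {
              int ih = h0 + dh;
              if (ih >= 0 && ih < H) dxw[ih] += col[dh];
            }
            col += kh;
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".elu")]]
NumericVector elu_cpp(NumericVector x) {
  NumericVector y = clone(x);
  double* p = y.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i)
    if (p[i] < 0) p[i] = std::expm1(p[i]);
  return y;
}

// gradient through ELU expressed via its output y: dz = dy * (y > 0 ? 1 : y + 1)
// [[Rcpp::export(name = ".elu_grad")]]
NumericVector elu_grad_cpp(NumericVector y, NumericVector dy) {
  NumericVector dz = clone(dy);
  const double* yp = y.begin();
  double* p = dz.begin();
  for (R_xlen_t i = 0; i < dz.size(); ++i)
    if (yp[i] < 0) p[i] *= yp[i] + 1.0;
  return dz;
}

// [[Rcpp::export(name = ".maxpool_forward")]]
List maxpool_forward_cpp(NumericVector x, int kh, int kw, int sh, int sw) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int OH = (H - kh) / sh + 1, OW = (W - kw) / sw + 1;

  NumericVector y((R_xlen_t)OH * OW * C * B);
  y.attr("dim") = IntegerVector::create(OH, OW, C, B);
  IntegerVector idx(y.size());  // 0-based linear index into x of each max
  size_t o = 0;
  for (int b = 0; b < B; ++b) {
    const double* xp = x.begin() + (size_t)b * H * W * C;
    size_t base = (size_t)b * H * W * C;
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)c * H * W;
      size_t cbase = base + (size_t)c * H * W;
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          int h0 = oh * sh, w0 = ow * sw;
          double best = xc[h0 + (size_t)w0 * H];
          size_t bidx = cbase + h0 + (size_t)w0 * H;
          for (int dw = 0; dw < kw; ++dw)
            for (int dh = 0; dh < kh; ++dh) {
              double v = xc[(h0 + dh) + (size_t)(w0 + dw) * H];
              if (v > best) { best = v; bidx = cbase + (h0 + dh) + (size_t)(w0 + dw) * H; }
            }
          // output is written in (OH, OW) transposed order of the loops:
          y[o + (size_t)oh + (size_t)OH * ow] = best;
          idx[o + (size_t)oh + (size_t)OH * ow] = (int)bidx;
        }
      }
      o += (size_t)OH * OW;
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
NumericVector maxpool_backward_cpp(IntegerVector idx, NumericVector dy, int xlen) {
  NumericVector dx(xlen);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// Large intermediate activations churn through malloc once per layer per
// batch; with glibc's default mmap threshold every such block is mapped and
// unmapped, so each training batch pays the page-fault cost of its full
// working set again. Raising the threshold keeps freed blocks on the heap
// free lists for reuse.
// [[Rcpp::export(name = ".tune_allocator")]]
void tune_allocator_cpp() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}

// fused max-pool + ELU backward: routes each pooled gradient to the argmax
// input position and applies the ELU derivative (via the activation value e
// at that position) in the same pass
// [[Rcpp::export(name = ".maxpool_elu_backward")]]
NumericVector maxpool_elu_backward_cpp(IntegerVector idx, NumericVector dy,
                                       NumericVector e, int xlen) {
  NumericVector dx(xlen);
  const double* ep = e.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) {
    int j = idx[i];
    double v = ep[j];
    dx[j] += v < 0 ? dy[i] * (v + 1.0) : dy[i];
  }
  return dx;
}
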