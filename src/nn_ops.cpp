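// Low-level single-precision tensor primitives for the encoder-decoder
// network. Feature maps are stored as arma::fmat with one row per channel
// and one column per pixel, columns ordered image-major then column-major
// in space (index = b*H*W + y + x*H). Keeping tensors behind external
// pointers avoids double<->float copies between R calls.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

typedef XPtr<fmat> FT;

static inline fmat& deref(SEXP p) { return *FT(p); }

// [[Rcpp::export]]
SEXP ft_new(const NumericMatrix& x) {
  fmat* m = new fmat(x.nrow(), x.ncol());
  const double* src = x.begin();
  float* dst = m->memptr();
  const size_t n = (size_t)x.nrow() * x.ncol();
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return FT(m, true);
}

// [[Rcpp::export]]
NumericMatrix ft_mat(SEXP p) {
  fmat& m = deref(p);
  NumericMatrix out(m.n_rows, m.n_cols);
  const float* src = m.memptr();
  double* dst = out.begin();
  const size_t n = m.n_elem;
  for (size_t i = 0; i < n; ++i) dst[i] = (double)src[i];
  return out;
}

// [[Rcpp::export]]
IntegerVector ft_shape(SEXP p) {
  fmat& m = deref(p);
  return IntegerVector::create((int)m.n_rows, (int)m.n_cols);
}

// [[Rcpp::export]]
SEXP ft_clone(SEXP p) { return FT(new fmat(deref(p)), true); }

// overwrite an existing tensor in place (shape must match)
// [[Rcpp::export]]
void ft_set(SEXP p, const NumericMatrix& x) {
  fmat& m = deref(p);
  if ((int)m.n_rows != x.nrow() || (int)m.n_cols != x.ncol())
    stop("ft_set: shape mismatch");
  const double* src = x.begin();
  float* dst = m.memptr();
  for (size_t i = 0; i < m.n_elem; ++i) dst[i] = (float)src[i];
}

// [[Rcpp::export]]
SEXP ft_zeros(int nr, int nc) {
  return FT(new fmat(nr, nc, arma::fill::zeros), true);
}

// ---- im2col / col2im for 3x3 kernels with dilation (zero 'same' padding) ----

static void im2col3(const fmat& x, fmat& col, int C, int H, int W, int B, int dil) {
  const int HW = H * W;
  col.zeros();
  for (int b = 0; b < B; ++b) {
    for (int xc = 0; xc < W; ++xc) {
      for (int ky = 0; ky < 3; ++ky) {
        const int dy = (ky - 1) * dil;
        for (int kx = 0; kx < 3; ++kx) {
          const int dx = (kx - 1) * dil;
          const int xs = xc + dx;
          if (xs < 0 || xs >= W) continue;
          const int k = ky * 3 + kx;
          const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
          for (int y = y0; y < y1; ++y) {
            const float* src = x.colptr((size_t)b * HW + (y + dy) + (size_t)xs * H);
            float* dst = col.colptr((size_t)b * HW + y + (size_t)xc * H) + (size_t)k * C;
            std::memcpy(dst, src, sizeof(float) * C);
          }
        }
      }
    }
  }
}

static void col2im3(const fmat& dcol, fmat& dx, int C, int H, int W, int B, int dil) {
  const int HW = H * W;
  dx.zeros();
  for (int b = 0; b < B; ++b) {
    for (int xc = 0; xc < W; ++xc) {
      for (int ky = 0; ky < 3; ++ky) {
        const int dy = (ky - 1) * dil;
        for (int kx = 0; kx < 3; ++kx) {
          const int dx_ = (kx - 1) * dil;
          const int xs = xc + dx_;
          if (xs < 0 || xs >= W) continue;
          const int k = ky * 3 + kx;
          const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
          for (int y = y0; y < y1; ++y) {
            float* dst = dx.colptr((size_t)b * HW + (y + dy) + (size_t)xs * H);
            const float* src = dcol.colptr((size_t)b * HW + y + (size_t)xc * H) + (size_t)k * C;
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List conv3x3_fwd(SEXP xp, SEXP Wp, SEXP bp, int C, int H, int W, int B, int dil) {
  fmat& x = deref(xp); fmat& Wm = deref(Wp); fmat& bm = deref(bp);
  fmat* col = new fmat((size_t)C * 9, x.n_cols);
  im2col3(x, *col, C, H, W, B, dil);
  fmat* y = new fmat(Wm * (*col));
  y->each_col() += bm.col(0);
  return List::create(_["y"] = FT(y, true), _["col"] = FT(col, true));
}

// [[Rcpp::export]]
List conv3x3_bwd(SEXP dyp, SEXP colp, SEXP Wp, int C, int H, int W, int B, int dil) {
  fmat& dy = deref(dyp); fmat& col = deref(colp); fmat& Wm = deref(Wp);
  fmat* dW = new fmat(dy * col.t());
  fmat* db = new fmat(arma::sum(dy, 1));
  fmat dcol = Wm.t() * dy;
  fmat* dx = new fmat(C, dy.n_cols);
  col2im3(dcol, *dx, C, H, W, B, dil);
  return List::create(_["dx"] = FT(dx, true), _["dW"] = FT(dW, true), _["db"] = FT(db, true));
}

// as conv3x3_bwd, optionally skipping the (expensive) input gradient
// [[Rcpp::export]]
List conv3x3_bwd2(SEXP dyp, SEXP colp, SEXP Wp, int C, int H, int W, int B,
                  int dil, bool need_dx) {
  fmat& dy = deref(dyp); fmat& col = deref(colp); fmat& Wm = deref(Wp);
  fmat* dW = new fmat(dy * col.t());
  fmat* db = new fmat(arma::sum(dy, 1));
  if (!need_dx)
    return List::create(_["dx"] = R_NilValue, _["dW"] = FT(dW, true),
                        _["db"] = FT(db, true));
  fmat dcol = Wm.t() * dy;
  fmat* dx = new fmat(C, dy.n_cols);
  col2im3(dcol, *dx, C, H, W, B, dil);
  return List::create(_["dx"] = FT(dx, true), _["dW"] = FT(dW, true), _["db"] = FT(db, true));
}

// [[Rcpp::export]]
SEXP conv1x1_fwd(SEXP xp, SEXP Wp, SEXP bp) {
  fmat& x = deref(xp); fmat& Wm = deref(Wp); fmat& bm = deref(bp);
  fmat* y = new fmat(Wm * x);
  y->each_col() += bm.col(0);
  return FT(y, true);
}

// [[Rcpp::export]]
List conv1x1_bwd(SEXP dyp, SEXP xp, SEXP Wp) {
  fmat& dy = deref(dyp); fmat& x = deref(xp); fmat& Wm = deref(Wp);
  fmat* dW = new fmat(dy * x.t());
  fmat* db = new fmat(arma::sum(dy, 1));
  fmat* dx = new fmat(Wm.t() * dy);
  return List::create(_["dx"] = FT(dx, true), _["dW"] = FT(dW, true), _["db"] = FT(db, true));
}

// ---- depth-wise 3x3 convolution (one 3x3x1 kernel per channel) ----

// [[Rcpp::export]]
SEXP dwconv3x3_fwd(SEXP xp, SEXP Wp, SEXP bp, int C, int H, int W, int B) {
  fmat& x = deref(xp); fmat& K = deref(Wp); fmat& bm = deref(bp); // K: C x 9
  const int HW = H * W;
  fmat* yp = new fmat(C, x.n_cols, arma::fill::zeros);
  fmat& y = *yp;
  for (int b = 0; b < B; ++b) {
    for (int xc = 0; xc < W; ++xc) {
      for (int ky = 0; ky < 3; ++ky) {
        const int dy = ky - 1;
        for (int kx = 0; kx < 3; ++kx) {
          const int dxo = kx - 1;
          const int xs = xc + dxo;
          if (xs < 0 || xs >= W) continue;
          const int k = ky * 3 + kx;
          const float* kcol = K.colptr(k);
          const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
          for (int yy = y0; yy < y1; ++yy) {
            const float* src = x.colptr((size_t)b * HW + (yy + dy) + (size_t)xs * H);
            float* dst = y.colptr((size_t)b * HW + yy + (size_t)xc * H);
            for (int c = 0; c < C; ++c) dst[c] += kcol[c] * src[c];
          }
        }
      }
    }
  }
  y.each_col() += bm.col(0);
  return FT(yp, true);
}

// [[Rcpp::export]]
List dwconv3x3_bwd(SEXP dyp, SEXP xp, SEXP Wp, int C, int H, int W, int B) {
  fmat& dy = deref(dyp); fmat& x = deref(xp); fmat& K = deref(Wp);
  const int HW = H * W;
  fmat* dKp = new fmat(C, 9, arma::fill::zeros);
  fmat* dxp = new fmat(C, x.n_cols, arma::fill::zeros);
  fmat& dK = *dKp; fmat& dx = *dxp;
  for (int b = 0; b < B; ++b) {
    for (int xc = 0; xc < W; ++xc) {
      for (int ky = 0; ky < 3; ++ky) {
        const int dyo = ky - 1;
        for (int kx = 0; kx < 3; ++kx) {
          const int dxo = kx - 1;
          const int xs = xc + dxo;
          if (xs < 0 || xs >= W) continue;
          const int k = ky * 3 + kx;
          const float* kcol = K.colptr(k);
          float* dkcol = dK.colptr(k);
          const int y0 = std::max(0, -dyo), y1 = std::min(H, H - dyo);
          for (int yy = y0; yy < y1; ++yy) {
            const size_t pin = (size_t)b * HW + (yy + dyo) + (size_t)xs * H;
            const size_t pout = (size_t)b * HW + yy + (size_t)xc * H;
            const float* xs_ = x.colptr(pin);
            const float* dys = dy.colptr(pout);
            float* dxs = dx.colptr(pin);
            for (int c = 0; c < C; ++c) {
              dkcol[c] += dys[c] * xs_[c];
              dxs[c] += dys[c] * kcol[c];
            }
          }
        }
      }
    }
  }
  fmat* db = new fmat(arma::sum(dy, 1));
  return List::create(_["dx"] = FT(dxp, true), _["dW"] = FT(dKp, true), _["db"] = FT(db, true));
}

// ---- grouped (depth-wise) 2x2 stride-2 transposed convolution ----

// [[Rcpp::export]]
SEXP deconv2x2_fwd(SEXP xp, SEXP Wp, SEXP bp, int C, int H, int W, int B) {
  fmat& x = deref(xp); fmat& K = deref(Wp); fmat& bm = deref(bp); // K: C x 4
  const int HW = H * W, Ho = 2 * H, Wo = 2 * W, HWo = Ho * Wo;
  fmat* yp = new fmat(C, (size_t)B * HWo, arma::fill::zeros);
  fmat& y = *yp;
  for (int b = 0; b < B; ++b) {
    for (int xc = 0; xc < W; ++xc) {
      for (int yy = 0; yy < H; ++yy) {
        const float* src = x.colptr((size_t)b * HW + yy + (size_t)xc * H);
        for (int t = 0; t < 4; ++t) {
          const int dy = t % 2, dxo = t / 2;  // kernel entry (dy, dx)
          const float* kcol = K.colptr(t);
          float* dst = y.colptr((size_t)b * HWo + (2 * yy + dy) + (size_t)(2 * xc + dxo) * Ho);
          for (int c = 0; c < C; ++c) dst[c] += kcol[c] * src[c];
        }
      }
    }
  }
  y.each_col() += bm.col(0);
  return FT(yp, true);
}

// [[Rcpp::export]]
List deconv2x2_bwd(SEXP dyp, SEXP xp, SEXP Wp, int C, int H, int W, int B) {
  fmat& dy = deref(dyp); fmat& x = deref(xp); fmat& K = deref(Wp);
  const int HW = H * W, Ho = 2 * H, HWo = 4 * HW;
  fmat* dKp = new fmat(C, 4, arma::fill::zeros);
  fmat* dxp = new fmat(C, x.n_cols, arma::fill::zeros);
  fmat& dK = *dKp; fmat& dx = *dxp;
  for (int b = 0; b < B; ++b) {
    for (int xc = 0; xc < W; ++xc) {
      for (int yy = 0; yy < H; ++yy) {
        const size_t pin = (size_t)b * HW + yy + (size_t)xc * H;
        const float* xs = x.colptr(pin);
        float* dxs = dx.colptr(pin);
        for (int t = 0; t < 4; ++t) {
          const int dyo = t % 2, dxo = t / 2;
          const float* kcol = K.colptr(t);
          float* dkcol = dK.colptr(t);
          const float* dys = dy.colptr((size_t)b * HWo + (2 * yy + dyo) + (size_t)(2 * xc + dxo) * Ho);
          for (int c = 0; c < C; ++c) {
            dkcol[c] += dys[c] * xs[c];
            dxs[c] += dys[c] * kcol[c];
          }
        }
      }
    }
  }
  fmat* db = new fmat(arma::sum(dy, 1));
  return List::create(_["dx"] = FT(dxp, true), _["dW"] = FT(dKp, true), _["db"] = FT(db, true));
}

// ---- 2x2 stride-2 max pooling ----

// [[Rcpp::export]]
List maxpool2_fwd(SEXP xp, int C, int H, int W, int B) {
  fmat& x = deref(xp);
  const int HW = H * W, Ho = H / 2, Wo = W / 2, HWo = Ho * Wo;
  fmat* yp = new fmat(C, (size_t)B * HWo);
  arma::Mat<arma::u32>* idx = new arma::Mat<arma::u32>(C, (size_t)B * HWo);
  for (int b = 0; b < B; ++b) {
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        const size_t po = (size_t)b * HWo + yo + (size_t)xo * Ho;
        size_t cand[4] = {
          (size_t)b * HW + 2 * yo     + (size_t)(2 * xo) * H,
          (size_t)b * HW + 2 * yo + 1 + (size_t)(2 * xo) * H,
          (size_t)b * HW + 2 * yo     + (size_t)(2 * xo + 1) * H,
          (size_t)b * HW + 2 * yo + 1 + (size_t)(2 * xo + 1) * H };
        const float* s0 = x.colptr(cand[0]);
        const float* s1 = x.colptr(cand[1]);
        const float* s2 = x.colptr(cand[2]);
        const float* s3 = x.colptr(cand[3]);
        float* dst = yp->colptr(po);
        arma::u32* ix = idx->colptr(po);
        for (int c = 0; c < C; ++c) {
          float best = s0[c]; arma::u32 bi = (arma::u32)cand[0];
          if (s1[c] > best) { best = s1[c]; bi = (arma::u32)cand[1]; }
          if (s2[c] > best) { best = s2[c]; bi = (arma::u32)cand[2]; }
          if (s3[c] > best) { best = s3[c]; bi = (arma::u32)cand[3]; }
          dst[c] = best; ix[c] = bi;
        }
      }
    }
  }
  return List::create(_["y"] = FT(yp, true),
                      _["idx"] = XPtr<arma::Mat<arma::u32>>(idx, true));
}

// [[Rcpp::export]]
SEXP maxpool2_bwd(SEXP dyp, SEXP idxp, int C, int H, int W, int B) {
  fmat& dy = deref(dyp);
  arma::Mat<arma::u32>& idx = *XPtr<arma::Mat<arma::u32>>(idxp);
  fmat* dxp = new fmat(C, (size_t)B * H * W, arma::fill::zeros);
  for (size_t p = 0; p < dy.n_cols; ++p) {
    const float* dys = dy.colptr(p);
    const arma::u32* ix = idx.colptr(p);
    for (int c = 0; c < C; ++c) (*dxp)(c, ix[c]) += dys[c];
  }
  return FT(dxp, true);
}

// ---- batch normalization over (batch x space) per channel ----

// [[Rcpp::export]]
List bn_fwd(SEXP xp, SEXP gp, SEXP bp, SEXP rmp, SEXP rvp,
            bool training, double momentum, double eps) {
  fmat& x = deref(xp); fmat& g = deref(gp); fmat& be = deref(bp);
  fmat& rm = deref(rmp); fmat& rv = deref(rvp);
  const int C = x.n_rows; const size_t n = x.n_cols;
  fvec mu(C), var(C);
  if (training) {
    mu = arma::mean(x, 1);
    fvec s2(C, arma::fill::zeros);
    for (size_t p = 0; p < n; ++p) {
      const float* xs = x.colptr(p);
      for (int c = 0; c < C; ++c) { const float d = xs[c] - mu(c); s2(c) += d * d; }
    }
    var = s2 / (float)n;
    rm.col(0) = (1.0f - (float)momentum) * rm.col(0) + (float)momentum * mu;
    rv.col(0) = (1.0f - (float)momentum) * rv.col(0) + (float)momentum * var;
  } else {
    mu = rm.col(0); var = rv.col(0);
  }
  fvec invstd = 1.0f / arma::sqrt(var + (float)eps);
  fmat* xhat = new fmat(C, n);
  fmat* y = new fmat(C, n);
  for (size_t p = 0; p < n; ++p) {
    const float* xs = x.colptr(p);
    float* xh = xhat->colptr(p);
    float* ys = y->colptr(p);
    for (int c = 0; c < C; ++c) {
      xh[c] = (xs[c] - mu(c)) * invstd(c);
      ys[c] = g(c, 0) * xh[c] + be(c, 0);
    }
  }
  fmat* is = new fmat(invstd);
  return List::create(_["y"] = FT(y, true), _["xhat"] = FT(xhat, true),
                      _["invstd"] = FT(is, true));
}

// [[Rcpp::export]]
List bn_bwd(SEXP dyp, SEXP xhatp, SEXP invstdp, SEXP gp, bool training) {
  fmat& dy = deref(dyp); fmat& xhat = deref(xhatp);
  fmat& invstd = deref(invstdp); fmat& g = deref(gp);
  const int C = dy.n_rows; const size_t n = dy.n_cols;
  fvec dg(C, arma::fill::zeros), db(C, arma::fill::zeros), m1(C, arma::fill::zeros);
  for (size_t p = 0; p < n; ++p) {
    const float* dys = dy.colptr(p);
    const float* xh = xhat.colptr(p);
    for (int c = 0; c < C; ++c) { dg(c) += dys[c] * xh[c]; db(c) += dys[c]; }
  }
  fmat* dx = new fmat(C, n);
  if (training) {
    // dx = invstd * gamma * (dy - mean(dy) - xhat * mean(dy*xhat))
    const fvec mdy = db / (float)n;
    const fvec mdyx = dg / (float)n;
    for (size_t p = 0; p < n; ++p) {
      const float* dys = dy.colptr(p);
      const float* xh = xhat.colptr(p);
      float* dxs = dx->colptr(p);
      for (int c = 0; c < C; ++c)
        dxs[c] = invstd(c, 0) * g(c, 0) * (dys[c] - mdy(c) - xh[c] * mdyx(c));
    }
  } else {
    for (size_t p = 0; p < n; ++p) {
      const float* dys = dy.colptr(p);
      float* dxs = dx->colptr(p);
      for (int c = 0; c < C; ++c) dxs[c] = invstd(c, 0) * g(c, 0) * dys[c];
    }
  }
  fmat* dgm = new fmat(dg); fmat* dbm = new fmat(db);
  return List::create(_["dx"] = FT(dx, true), _["dgamma"] = FT(dgm, true),
                      _["dbeta"] = FT(dbm, true));
}

// ---- simple elementwise / structural ops ----

// [[Rcpp::export]]
SEXP relu_fwd(SEXP xp) {
  fmat* y = new fmat(deref(xp));
  y->transform([](float v) { return v > 0.0f ? v : 0.0f; });
  return FT(y, true);
}

// [[Rcpp::export]]
SEXP relu_bwd(SEXP dyp, SEXP yp) {
  fmat& dy = deref(dyp); fmat& y = deref(yp);
  fmat* dx = new fmat(dy);
  const float* ys = y.memptr(); float* d = dx->memptr();
  for (size_t i = 0; i < dx->n_elem; ++i) if (ys[i] <= 0.0f) d[i] = 0.0f;
  return FT(dx, true);
}

// [[Rcpp::export]]
SEXP add_fwd(SEXP ap, SEXP bp) {
  fmat* y = new fmat(deref(ap) + deref(bp));
  return FT(y, true);
}

// [[Rcpp::export]]
SEXP ft_accum(SEXP ap, SEXP bp) { deref(ap) += deref(bp); return ap; }

// [[Rcpp::export]]
SEXP concat_fwd(SEXP ap, SEXP bp) {
  fmat* y = new fmat(arma::join_cols(deref(ap), deref(bp)));
  return FT(y, true);
}

// [[Rcpp::export]]
List concat_bwd(SEXP dyp, int Ca) {
  fmat& dy = deref(dyp);
  fmat* da = new fmat(dy.rows(0, Ca - 1));
  fmat* db = new fmat(dy.rows(Ca, dy.n_rows - 1));
  return List::create(_["da"] = FT(da, true), _["db"] = FT(db, true));
}

// [[Rcpp::export]]
SEXP concat_many_fwd(List ps) {
  fmat* y = new fmat(deref(ps[0]));
  for (int i = 1; i < ps.size(); ++i) *y = arma::join_cols(*y, deref(ps[i]));
  return FT(y, true);
}

// [[Rcpp::export]]
List split_rows(SEXP dyp, IntegerVector sizes) {
  fmat& dy = deref(dyp);
  List out(sizes.size());
  int r = 0;
  for (int i = 0; i < sizes.size(); ++i) {
    out[i] = FT(new fmat(dy.rows(r, r + sizes[i] - 1)), true);
    r += sizes[i];
  }
  return out;
}

// global average pool: (C, B*HW) -> (C, B)
// [[Rcpp::export]]
SEXP gap_fwd(SEXP xp, int HW, int B) {
  fmat& x = deref(xp);
  const int C = x.n_rows;
  fmat* y = new fmat(C, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int p = 0; p < HW; ++p) y->col(b) += x.col((size_t)b * HW + p);
    y->col(b) /= (float)HW;
  }
  return FT(y, true);
}

// [[Rcpp::export]]
SEXP gap_bwd(SEXP dyp, int HW, int B) {
  fmat& dy = deref(dyp);
  const int C = dy.n_rows;
  fmat* dx = new fmat(C, (size_t)B * HW);
  for (int b = 0; b < B; ++b) {
    const fvec g = dy.col(b) / (float)HW;
    for (int p = 0; p < HW; ++p) dx->col((size_t)b * HW + p) = g;
  }
  return FT(dx, true);
}

// broadcast a (C, B) image-level feature to (C, B*HW)
// [[Rcpp::export]]
SEXP broadcast_fwd(SEXP xp, int HW, int B) {
  fmat& x = deref(xp);
  fmat* y = new fmat(x.n_rows, (size_t)B * HW);
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < HW; ++p) y->col((size_t)b * HW + p) = x.col(b);
  return FT(y, true);
}

// [[Rcpp::export]]
SEXP broadcast_bwd(SEXP dyp, int HW, int B) {
  fmat& dy = deref(dyp);
  fmat* dx = new fmat(dy.n_rows, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < HW; ++p) dx->col(b) += dy.col((size_t)b * HW + p);
  return FT(dx, true);
}

// two-class softmax over the channel axis; returns the foreground row
// [[Rcpp::export]]
List softmax2_fwd(SEXP logitp) {
  fmat& z = deref(logitp);
  fmat* p = new fmat(1, z.n_cols);
  for (size_t i = 0; i < z.n_cols; ++i) {
    const float a = z(0, i), b = z(1, i);
    const float m = std::max(a, b);
    const float ea = std::exp(a - m), eb = std::exp(b - m);
    (*p)(0, i) = eb / (ea + eb);   // channel 2 = foreground
  }
  return List::create(_["p"] = FT(p, true));
}

// [[Rcpp::export]]
SEXP softmax2_bwd(SEXP dpp, SEXP pp) {
  fmat& dp = deref(dpp); fmat& p = deref(pp);
  fmat* dz = new fmat(2, p.n_cols);
  for (size_t i = 0; i < p.n_cols; ++i) {
    const float g = dp(0, i) * p(0, i) * (1.0f - p(0, i));
    (*dz)(0, i) = -g;
    (*dz)(1, i) = g;
  }
  return FT(dz, true);
}

// ---- RMSProp update (in place) ----

// [[Rcpp::export]]
void rmsprop_step(SEXP pp, SEXP gp, SEXP cp, double lr, double rho, double eps) {
  fmat& p = deref(pp); fmat& g = deref(gp); fmat& c = deref(cp);
  const float frho = (float)rho, flr = (float)lr, feps = (float)eps;
  float* pm = p.memptr(); const float* gm = g.memptr(); float* cm = c.memptr();
  for (size_t i = 0; i < p.n_elem; ++i) {
    cm[i] = frho * cm[i] + (1.0f - frho) * gm[i] * gm[i];
    pm[i] -= flr * gm[i] / (std::sqrt(cm[i]) + feps);
  }
}

// mean over channels / max over channels for activation maps: (C, n) -> (1, n)
// [[Rcpp::export]]
NumericVector channel_reduce(SEXP xp, std::string mode) {
  fmat& x = deref(xp);
  NumericVector out(x.n_cols);
  for (size_t p = 0; p < x.n_cols; ++p) {
    const float* xs = x.colptr(p);
    float v = xs[0];
    if (mode == "mean") {
      for (arma::uword c = 1; c < x.n_rows; ++c) v += xs[c];
      v /= (float)x.n_rows;
    } else {
      for (arma::uword c = 1; c < x.n_rows; ++c) v = std::max(v, xs[c]);
    }
    out[p] = (double)v;
  }
  return out;
}
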