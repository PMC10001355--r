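#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Rasters are H x W x C cubes (row, col, channel), matching R's array layout.
// Convolution weights are (k*k*Cin) x Cout matrices; the patch column index is
// ci*k*k + kj*k + ki (channel-major, then kernel column, then kernel row).
// This ordering is a fixed internal contract shared with the R layer code.

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static mat im2col(const cube& x, int k, int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat P(Ho * Wo, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = c * k * k + kj * k + ki;
        for (int j = 0; j < Wo; ++j) {
          const int wj = j * stride + kj - pad;
          if (wj < 0 || wj >= W) continue;
          if (stride == 1) {
            // contiguous strip: output rows i in [i0, i1] read x rows i + ki - pad
            const int i0 = std::max(0, pad - ki);
            const int i1 = std::min(Ho - 1, H - 1 - ki + pad);
            if (i0 > i1) continue;
            std::memcpy(P.colptr(col) + j * Ho + i0,
                        x.slice_colptr(c, wj) + i0 + ki - pad,
                        (i1 - i0 + 1) * sizeof(double));
          } else {
            for (int i = 0; i < Ho; ++i) {
              const int wi = i * stride + ki - pad;
              if (wi < 0 || wi >= H) continue;
              P(j * Ho + i, col) = x(wi, wj, c);
            }
          }
        }
      }
    }
  }
  return P;
}

// scatter-add of im2col-layout gradients back onto the input raster
static void col2im_add(cube& dx, const mat& dP, int k, int stride, int pad,
                       int Ho, int Wo) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = c * k * k + kj * k + ki;
        for (int j = 0; j < Wo; ++j) {
          const int wj = j * stride + kj - pad;
          if (wj < 0 || wj >= W) continue;
          if (stride == 1) {
            const int i0 = std::max(0, pad - ki);
            const int i1 = std::min(Ho - 1, H - 1 - ki + pad);
            if (i0 > i1) continue;
            double* dst = dx.slice_colptr(c, wj) + i0 + ki - pad;
            const double* src = dP.colptr(col) + j * Ho + i0;
            for (int t = 0; t <= i1 - i0; ++t) dst[t] += src[t];
          } else {
            for (int i = 0; i < Ho; ++i) {
              const int wi = i * stride + ki - pad;
              if (wi < 0 || wi >= H) continue;
              dx(wi, wj, c) += dP(j * Ho + i, col);
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w, const arma::vec& b,
                      int k, int stride, int pad) {
  const int Ho = out_dim(x.n_rows, k, stride, pad);
  const int Wo = out_dim(x.n_cols, k, stride, pad);
  mat P = im2col(x, k, stride, pad, Ho, Wo);
  mat Y = P * w;
  Y.each_row() += b.t();
  cube out(Ho, Wo, w.n_cols);
  for (uword co = 0; co < w.n_cols; ++co)
    out.slice(co) = reshape(Y.col(co), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& dy,
                      int k, int stride, int pad) {
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat P = im2col(x, k, stride, pad, Ho, Wo);
  mat dY(Ho * Wo, dy.n_slices);
  for (uword co = 0; co < dy.n_slices; ++co)
    dY.col(co) = vectorise(dy.slice(co));
  mat dw = P.t() * dY;
  vec db = sum(dY, 0).t();
  mat dP = dY * w.t();
  cube dx(H, W, C, fill::zeros);
  col2im_add(dx, dP, k, stride, pad, Ho, Wo);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2 average pooling, stride 2; requires even spatial dims.
// [[Rcpp::export]]
arma::cube avgpool2_fwd(const arma::cube& x) {
  const int Ho = x.n_rows / 2, Wo = x.n_cols / 2, C = x.n_slices;
  cube out(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        out(i, j, c) = 0.25 * (x(2 * i, 2 * j, c) + x(2 * i + 1, 2 * j, c) +
                               x(2 * i, 2 * j + 1, c) + x(2 * i + 1, 2 * j + 1, c));
  return out;
}

// [[Rcpp::export]]
arma::cube avgpool2_bwd(const arma::cube& dy) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  cube dx(2 * Ho, 2 * Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double g = 0.25 * dy(i, j, c);
        dx(2 * i, 2 * j, c) = g;
        dx(2 * i + 1, 2 * j, c) = g;
        dx(2 * i, 2 * j + 1, c) = g;
        dx(2 * i + 1, 2 * j + 1, c) = g;
      }
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
arma::cube upsample2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
  return out;
}

// [[Rcpp::export]]
arma::cube upsample2_bwd(const arma::cube& dy) {
  const int Ho = dy.n_rows / 2, Wo = dy.n_cols / 2, C = dy.n_slices;
  cube dx(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

// ---------------------------------------------------------------------------
// Fused training steps. These compose the primitives above inside a single
// call so that per-image training does not cross the R/C++ boundary once per
// layer. The R-level seg_fwd/seg_bwd/cls_fwd/cls_bwd compose the exported
// primitives into the same computation and serve as the reference path in
// tests.

static const double NORM_EPS = 1e-5;

struct ConvFB {
  mat P;      // im2col patches of the input
  int k, stride, pad, H, W, C;
};

static cube conv_fwd_keep(const cube& x, const mat& w, const vec& b,
                          int k, int stride, int pad, ConvFB& fb) {
  const int Ho = out_dim(x.n_rows, k, stride, pad);
  const int Wo = out_dim(x.n_cols, k, stride, pad);
  fb.P = im2col(x, k, stride, pad, Ho, Wo);
  fb.k = k; fb.stride = stride; fb.pad = pad;
  fb.H = x.n_rows; fb.W = x.n_cols; fb.C = x.n_slices;
  mat Y = fb.P * w;
  Y.each_row() += b.t();
  cube out(Ho, Wo, w.n_cols);
  for (uword co = 0; co < w.n_cols; ++co)
    out.slice(co) = reshape(Y.col(co), Ho, Wo);
  return out;
}

static cube conv_bwd_keep(const ConvFB& fb, const mat& w, const cube& dy,
                          mat& dw, vec& db, bool need_dx) {
  const int Ho = dy.n_rows, Wo = dy.n_cols;
  mat dY(Ho * Wo, dy.n_slices);
  for (uword co = 0; co < dy.n_slices; ++co)
    dY.col(co) = vectorise(dy.slice(co));
  dw = fb.P.t() * dY;
  db = sum(dY, 0).t();
  cube dx;
  if (!need_dx) return dx;
  mat dP = dY * w.t();
  dx.zeros(fb.H, fb.W, fb.C);
  col2im_add(dx, dP, fb.k, fb.stride, fb.pad, Ho, Wo);
  return dx;
}

static inline cube relu_c(cube x) {
  x.transform([](double v) { return v > 0 ? v : 0.0; });
  return x;
}

static inline cube relu_mask_mul(cube g, const cube& act) {
  for (uword i = 0; i < g.n_elem; ++i) if (act(i) <= 0) g(i) = 0;
  return g;
}

static cube concat_c(const cube& a, const cube& b) {
  cube out(a.n_rows, a.n_cols, a.n_slices + b.n_slices);
  out.slices(0, a.n_slices - 1) = a;
  out.slices(a.n_slices, out.n_slices - 1) = b;
  return out;
}

// rank loss on hard pixel pairs; fills ds (gradient wrt scores)
static double rank_loss_c(const mat& s, const mat& y, int top_k, double margin,
                          mat& ds) {
  ds.zeros(s.n_rows, s.n_cols);
  std::vector<uword> fg, bg;
  for (uword i = 0; i < s.n_elem; ++i) (y(i) == 1 ? fg : bg).push_back(i);
  if (fg.empty() || bg.empty()) return 0.0;
  const int kk = std::min<size_t>(top_k, std::min(fg.size(), bg.size()));
  std::partial_sort(fg.begin(), fg.begin() + kk, fg.end(),
                    [&](uword a, uword b) { return s(a) < s(b); });
  std::partial_sort(bg.begin(), bg.begin() + kk, bg.end(),
                    [&](uword a, uword b) { return s(a) > s(b); });
  double loss = 0;
  for (int i = 0; i < kk; ++i) {
    const double gap = margin - (s(fg[i]) - s(bg[i]));
    if (gap > 0) {
      loss += gap;
      ds(fg[i]) -= 1.0 / kk;
      ds(bg[i]) += 1.0 / kk;
    }
  }
  return loss / kk;
}

struct SegParams {
  mat c1w, c2w, c3w, c4w, c5w, hw, fw;
  vec c1b, c2b, c3b, c4b, c5b, hb, fb_, fgamma, fbeta;
  bool fusion;
};

static SegParams seg_unpack(const Rcpp::List& p, bool fusion) {
  SegParams sp;
  sp.fusion = fusion;
  sp.c1w = Rcpp::as<mat>(p["conv1_w"]); sp.c1b = Rcpp::as<vec>(p["conv1_b"]);
  sp.c2w = Rcpp::as<mat>(p["conv2_w"]); sp.c2b = Rcpp::as<vec>(p["conv2_b"]);
  sp.c3w = Rcpp::as<mat>(p["conv3_w"]); sp.c3b = Rcpp::as<vec>(p["conv3_b"]);
  sp.c4w = Rcpp::as<mat>(p["conv4_w"]); sp.c4b = Rcpp::as<vec>(p["conv4_b"]);
  sp.c5w = Rcpp::as<mat>(p["conv5_w"]); sp.c5b = Rcpp::as<vec>(p["conv5_b"]);
  sp.hw = Rcpp::as<mat>(p["head_w"]);   sp.hb = Rcpp::as<vec>(p["head_b"]);
  if (fusion) {
    sp.fw = Rcpp::as<mat>(p["fus_w"]); sp.fb_ = Rcpp::as<vec>(p["fus_b"]);
    sp.fgamma = Rcpp::as<vec>(p["fus_gamma"]);
    sp.fbeta = Rcpp::as<vec>(p["fus_beta"]);
  }
  return sp;
}

struct SegTrace {
  ConvFB f1, f2, f3, f4, f5, fh, ff;
  cube e1, e2, b, f, d2, d1, zcat, fpre_hat;
  vec sdv;
  mat s;
};

static mat seg_forward_c(const cube& x, const SegParams& sp, const mat& cam_grid,
                         SegTrace& tr) {
  tr.e1 = relu_c(conv_fwd_keep(x, sp.c1w, sp.c1b, 3, 1, 1, tr.f1));
  cube p1 = avgpool2_fwd(tr.e1);
  tr.e2 = relu_c(conv_fwd_keep(p1, sp.c2w, sp.c2b, 3, 1, 1, tr.f2));
  cube p2 = avgpool2_fwd(tr.e2);
  tr.b = relu_c(conv_fwd_keep(p2, sp.c3w, sp.c3b, 3, 1, 1, tr.f3));
  if (sp.fusion) {
    cube camc(cam_grid.n_rows, cam_grid.n_cols, 1);
    camc.slice(0) = cam_grid;
    tr.zcat = concat_c(tr.b, camc);
    cube fpre = conv_fwd_keep(tr.zcat, sp.fw, sp.fb_, 3, 1, 1, tr.ff);
    const int C = fpre.n_slices;
    tr.fpre_hat.set_size(fpre.n_rows, fpre.n_cols, C);
    tr.sdv.set_size(C);
    cube fn(fpre.n_rows, fpre.n_cols, C);
    for (int c = 0; c < C; ++c) {
      const double mu = accu(fpre.slice(c)) / fpre.slice(c).n_elem;
      mat d = fpre.slice(c) - mu;
      tr.sdv(c) = std::sqrt(accu(d % d) / d.n_elem + NORM_EPS);
      tr.fpre_hat.slice(c) = d / tr.sdv(c);
      fn.slice(c) = sp.fgamma(c) * tr.fpre_hat.slice(c) + sp.fbeta(c);
    }
    tr.f = relu_c(fn);
  } else {
    tr.f = tr.b;
  }
  cube u2 = upsample2_fwd(tr.f);
  cube c2cat = concat_c(u2, tr.e2);
  tr.d2 = relu_c(conv_fwd_keep(c2cat, sp.c4w, sp.c4b, 3, 1, 1, tr.f4));
  cube u1 = upsample2_fwd(tr.d2);
  cube c1cat = concat_c(u1, tr.e1);
  tr.d1 = relu_c(conv_fwd_keep(c1cat, sp.c5w, sp.c5b, 3, 1, 1, tr.f5));
  cube z = conv_fwd_keep(tr.d1, sp.hw, sp.hb, 3, 1, 1, tr.fh);
  tr.s = 1.0 / (1.0 + exp(-z.slice(0)));
  return tr.s;
}

// [[Rcpp::export]]
Rcpp::List seg_step_c(const arma::cube& x, const arma::mat& y, Rcpp::List params,
                      bool fusion, const arma::mat& cam_grid,
                      double lambda, int top_k, double margin) {
  SegParams sp = seg_unpack(params, fusion);
  SegTrace tr;
  mat s = seg_forward_c(x, sp, cam_grid, tr);
  const double n = s.n_elem;
  // loss
  mat sc = clamp(s, 1e-7, 1.0 - 1e-7);
  double loss = -accu(y % log(sc) + (1.0 - y) % log(1.0 - sc)) / n;
  mat dz = (s - y) / n;
  if (lambda > 0) {
    mat dsr;
    loss += lambda * rank_loss_c(s, y, top_k, margin, dsr);
    dz += lambda * dsr % s % (1.0 - s);
  }
  // backward
  const uword c1 = tr.e1.n_slices, c2 = tr.e2.n_slices, c3 = tr.b.n_slices;
  Rcpp::List g;
  cube dzc(dz.n_rows, dz.n_cols, 1); dzc.slice(0) = dz;
  mat dw; vec db;
  cube dd1 = conv_bwd_keep(tr.fh, sp.hw, dzc, dw, db, true);
  g["head_w"] = dw; g["head_b"] = db;
  dd1 = relu_mask_mul(dd1, tr.d1);
  cube dc1cat = conv_bwd_keep(tr.f5, sp.c5w, dd1, dw, db, true);
  g["conv5_w"] = dw; g["conv5_b"] = db;
  cube du1 = dc1cat.slices(0, c2 - 1);
  cube de1 = dc1cat.slices(c2, c2 + c1 - 1);
  cube dd2 = relu_mask_mul(upsample2_bwd(du1), tr.d2);
  cube dc2cat = conv_bwd_keep(tr.f4, sp.c4w, dd2, dw, db, true);
  g["conv4_w"] = dw; g["conv4_b"] = db;
  cube du2 = dc2cat.slices(0, c3 - 1);
  cube de2 = dc2cat.slices(c3, c3 + c2 - 1);
  cube df = upsample2_bwd(du2);
  cube db_;
  if (fusion) {
    cube dfn = relu_mask_mul(df, tr.f);
    const int C = dfn.n_slices;
    vec dgamma(C), dbeta(C);
    cube dfpre(dfn.n_rows, dfn.n_cols, C);
    for (int c = 0; c < C; ++c) {
      mat gsl = dfn.slice(c);
      mat xh = tr.fpre_hat.slice(c);
      dgamma(c) = accu(gsl % xh);
      dbeta(c) = accu(gsl);
      mat dxhat = gsl * sp.fgamma(c);
      const double m1 = accu(dxhat) / dxhat.n_elem;
      const double m2 = accu(dxhat % xh) / dxhat.n_elem;
      dfpre.slice(c) = (dxhat - m1 - xh * m2) / tr.sdv(c);
    }
    g["fus_gamma"] = dgamma; g["fus_beta"] = dbeta;
    cube dzcat = conv_bwd_keep(tr.ff, sp.fw, dfpre, dw, db, true);
    g["fus_w"] = dw; g["fus_b"] = db;
    db_ = dzcat.slices(0, c3 - 1);
  } else {
    db_ = df;
  }
  db_ = relu_mask_mul(db_, tr.b);
  cube dp2 = conv_bwd_keep(tr.f3, sp.c3w, db_, dw, db, true);
  g["conv3_w"] = dw; g["conv3_b"] = db;
  de2 = relu_mask_mul(de2 + avgpool2_bwd(dp2), tr.e2);
  cube dp1 = conv_bwd_keep(tr.f2, sp.c2w, de2, dw, db, true);
  g["conv2_w"] = dw; g["conv2_b"] = db;
  de1 = relu_mask_mul(de1 + avgpool2_bwd(dp1), tr.e1);
  conv_bwd_keep(tr.f1, sp.c1w, de1, dw, db, false);
  g["conv1_w"] = dw; g["conv1_b"] = db;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("s") = s,
                            Rcpp::Named("grads") = g);
}

// [[Rcpp::export]]
arma::mat seg_infer_c(const arma::cube& x, Rcpp::List params, bool fusion,
                      const arma::mat& cam_grid) {
  SegParams sp = seg_unpack(params, fusion);
  SegTrace tr;
  return seg_forward_c(x, sp, cam_grid, tr);
}

struct ClsParams {
  mat c1w, c2w, c3w, c4w, fcw;
  vec c1b, c2b, c3b, c4b, fcb;
};

static ClsParams cls_unpack(const Rcpp::List& p) {
  ClsParams cp;
  cp.c1w = Rcpp::as<mat>(p["conv1_w"]); cp.c1b = Rcpp::as<vec>(p["conv1_b"]);
  cp.c2w = Rcpp::as<mat>(p["conv2_w"]); cp.c2b = Rcpp::as<vec>(p["conv2_b"]);
  cp.c3w = Rcpp::as<mat>(p["conv3_w"]); cp.c3b = Rcpp::as<vec>(p["conv3_b"]);
  cp.c4w = Rcpp::as<mat>(p["conv4_w"]); cp.c4b = Rcpp::as<vec>(p["conv4_b"]);
  cp.fcw = Rcpp::as<mat>(p["fc_w"]);    cp.fcb = Rcpp::as<vec>(p["fc_b"]);
  return cp;
}

struct ClsTrace {
  ConvFB f1, f2, f3, f4;
  cube h1, h2, h3, h4;
  vec gvec, probs;
};

static vec cls_forward_c(const cube& x, const ClsParams& cp, ClsTrace& tr) {
  tr.h1 = relu_c(conv_fwd_keep(x, cp.c1w, cp.c1b, 3, 2, 1, tr.f1));
  tr.h2 = relu_c(conv_fwd_keep(tr.h1, cp.c2w, cp.c2b, 3, 2, 1, tr.f2));
  tr.h3 = relu_c(conv_fwd_keep(tr.h2, cp.c3w, cp.c3b, 3, 2, 1, tr.f3));
  tr.h4 = relu_c(conv_fwd_keep(tr.h3, cp.c4w, cp.c4b, 3, 1, 1, tr.f4));
  tr.gvec.set_size(tr.h4.n_slices);
  for (uword c = 0; c < tr.h4.n_slices; ++c)
    tr.gvec(c) = accu(tr.h4.slice(c)) / tr.h4.slice(c).n_elem;
  vec logits = cp.fcw * tr.gvec + cp.fcb;
  vec e = exp(logits - logits.max());
  tr.probs = e / accu(e);
  return tr.probs;
}

// [[Rcpp::export]]
Rcpp::List cls_step_c(const arma::cube& x, int label, double weight,
                      Rcpp::List params) {
  ClsParams cp = cls_unpack(params);
  ClsTrace tr;
  vec probs = cls_forward_c(x, cp, tr);
  const double loss = -weight * std::log(std::max(probs(label - 1), 1e-12));
  vec dlogits = probs;
  dlogits(label - 1) -= 1.0;
  dlogits *= weight;
  Rcpp::List g;
  g["fc_w"] = mat(dlogits * tr.gvec.t());
  g["fc_b"] = dlogits;
  vec dg = cp.fcw.t() * dlogits;
  const double hw = tr.h4.n_rows * tr.h4.n_cols;
  cube dh4(tr.h4.n_rows, tr.h4.n_cols, tr.h4.n_slices);
  for (uword c = 0; c < tr.h4.n_slices; ++c)
    dh4.slice(c).fill(dg(c) / hw);
  dh4 = relu_mask_mul(dh4, tr.h4);
  mat dw; vec db;
  cube dh3 = conv_bwd_keep(tr.f4, cp.c4w, dh4, dw, db, true);
  g["conv4_w"] = dw; g["conv4_b"] = db;
  dh3 = relu_mask_mul(dh3, tr.h3);
  cube dh2 = conv_bwd_keep(tr.f3, cp.c3w, dh3, dw, db, true);
  g["conv3_w"] = dw; g["conv3_b"] = db;
  dh2 = relu_mask_mul(dh2, tr.h2);
  cube dh1 = conv_bwd_keep(tr.f2, cp.c2w, dh2, dw, db, true);
  g["conv2_w"] = dw; g["conv2_b"] = db;
  dh1 = relu_mask_mul(dh1, tr.h1);
  conv_bwd_keep(tr.f1, cp.c1w, dh1, dw, db, false);
  g["conv1_w"] = dw; g["conv1_b"] = db;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("probs") = probs,
                            Rcpp::Named("grads") = g);
}

// [[Rcpp::export]]
Rcpp::List cls_infer_c(const arma::cube& x, Rcpp::List params) {
  ClsParams cp = cls_unpack(params);
  ClsTrace tr;
  vec probs = cls_forward_c(x, cp, tr);
  return Rcpp::List::create(Rcpp::Named("probs") = probs,
                            Rcpp::Named("fmap") = tr.h4);
}

// ---------------------------------------------------------------------------
// Flat-parameter training steps with in-place Adam.
//
// The per-image R-side loop allocates ~35 small R objects per step (gradient
// lists, Adam temporaries); with a large dataset resident on the R heap the
// garbage collector then dominates the step time. These entry points keep
// parameters, Adam state and gradients in flat double vectors owned by the
// training loop and mutate them in place, so a training step performs no R
// allocation at all. Parameter layout matches the construction order of
// seg_model()/cls_model(); equivalence with the list-based step is covered
// by tests.

static SegParams seg_unpack_flat(double* p, int cin, int c1, bool fusion) {
  const int c2 = 2 * c1, c3 = 4 * c1;
  SegParams sp; sp.fusion = fusion;
  double* q = p;
  auto M = [&q](int r, int c) { mat m(q, r, c, false, true); q += r * c; return m; };
  auto V = [&q](int n) { vec v(q, n, false, true); q += n; return v; };
  sp.c1w = M(9 * cin, c1);      sp.c1b = V(c1);
  sp.c2w = M(9 * c1, c2);       sp.c2b = V(c2);
  sp.c3w = M(9 * c2, c3);       sp.c3b = V(c3);
  sp.c4w = M(9 * (c3 + c2), c2); sp.c4b = V(c2);
  sp.c5w = M(9 * (c2 + c1), c1); sp.c5b = V(c1);
  sp.hw = M(9 * c1, 1);         sp.hb = V(1);
  if (fusion) {
    sp.fw = M(9 * (c3 + 1), c3); sp.fb_ = V(c3);
    sp.fgamma = V(c3);           sp.fbeta = V(c3);
  }
  return sp;
}

static void adam_inplace(double* p, double* m, double* v, const double* g,
                         int n, int t, double lr) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  const double b1t = 1.0 - std::pow(b1, t), b2t = 1.0 - std::pow(b2, t);
  for (int i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1 - b1) * g[i];
    v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
    p[i] -= lr * (m[i] / b1t) / (std::sqrt(v[i] / b2t) + eps);
  }
}

// [[Rcpp::export]]
double seg_train_step_flat(const arma::cube& x, const arma::mat& y,
                           Rcpp::NumericVector flat, Rcpp::NumericVector mstate,
                           Rcpp::NumericVector vstate, int step_t,
                           int cin, int c1, bool fusion,
                           const arma::mat& cam_grid,
                           double lr, double lambda, int top_k, double margin) {
  SegParams sp = seg_unpack_flat(flat.begin(), cin, c1, fusion);
  SegTrace tr;
  mat s = seg_forward_c(x, sp, cam_grid, tr);
  const double n = s.n_elem;
  mat sc = clamp(s, 1e-7, 1.0 - 1e-7);
  double loss = -accu(y % log(sc) + (1.0 - y) % log(1.0 - sc)) / n;
  mat dz = (s - y) / n;
  if (lambda > 0) {
    mat dsr;
    loss += lambda * rank_loss_c(s, y, top_k, margin, dsr);
    dz += lambda * dsr % s % (1.0 - s);
  }
  std::vector<double> gbuf(flat.size());
  SegParams gp = seg_unpack_flat(gbuf.data(), cin, c1, fusion);
  const uword cc1 = tr.e1.n_slices, cc2 = tr.e2.n_slices, cc3 = tr.b.n_slices;
  cube dzc(dz.n_rows, dz.n_cols, 1); dzc.slice(0) = dz;
  cube dd1 = conv_bwd_keep(tr.fh, sp.hw, dzc, gp.hw, gp.hb, true);
  dd1 = relu_mask_mul(dd1, tr.d1);
  cube dc1cat = conv_bwd_keep(tr.f5, sp.c5w, dd1, gp.c5w, gp.c5b, true);
  cube du1 = dc1cat.slices(0, cc2 - 1);
  cube de1 = dc1cat.slices(cc2, cc2 + cc1 - 1);
  cube dd2 = relu_mask_mul(upsample2_bwd(du1), tr.d2);
  cube dc2cat = conv_bwd_keep(tr.f4, sp.c4w, dd2, gp.c4w, gp.c4b, true);
  cube du2 = dc2cat.slices(0, cc3 - 1);
  cube de2 = dc2cat.slices(cc3, cc3 + cc2 - 1);
  cube df = upsample2_bwd(du2);
  cube db_;
  if (fusion) {
    cube dfn = relu_mask_mul(df, tr.f);
    const int C = dfn.n_slices;
    cube dfpre(dfn.n_rows, dfn.n_cols, C);
    for (int c = 0; c < C; ++c) {
      mat gsl = dfn.slice(c);
      mat xh = tr.fpre_hat.slice(c);
      gp.fgamma(c) = accu(gsl % xh);
      gp.fbeta(c) = accu(gsl);
      mat dxhat = gsl * sp.fgamma(c);
      const double m1 = accu(dxhat) / dxhat.n_elem;
      const double m2 = accu(dxhat % xh) / dxhat.n_elem;
      dfpre.slice(c) = (dxhat - m1 - xh * m2) / tr.sdv(c);
    }
    cube dzcat = conv_bwd_keep(tr.ff, sp.fw, dfpre, gp.fw, gp.fb_, true);
    db_ = dzcat.slices(0, cc3 - 1);
  } else {
    db_ = df;
  }
  db_ = relu_mask_mul(db_, tr.b);
  cube dp2 = conv_bwd_keep(tr.f3, sp.c3w, db_, gp.c3w, gp.c3b, true);
  de2 = relu_mask_mul(de2 + avgpool2_bwd(dp2), tr.e2);
  cube dp1 = conv_bwd_keep(tr.f2, sp.c2w, de2, gp.c2w, gp.c2b, true);
  de1 = relu_mask_mul(de1 + avgpool2_bwd(dp1), tr.e1);
  conv_bwd_keep(tr.f1, sp.c1w, de1, gp.c1w, gp.c1b, false);
  adam_inplace(flat.begin(), mstate.begin(), vstate.begin(), gbuf.data(),
               flat.size(), step_t, lr);
  return loss;
}

static ClsParams cls_unpack_flat(double* p, int cin, int c1, int C) {
  const int c2 = 2 * c1, c3 = 4 * c1;
  ClsParams cp;
  double* q = p;
  auto M = [&q](int r, int c) { mat m(q, r, c, false, true); q += r * c; return m; };
  auto V = [&q](int n) { vec v(q, n, false, true); q += n; return v; };
  cp.c1w = M(9 * cin, c1); cp.c1b = V(c1);
  cp.c2w = M(9 * c1, c2);  cp.c2b = V(c2);
  cp.c3w = M(9 * c2, c3);  cp.c3b = V(c3);
  cp.c4w = M(9 * c3, c3);  cp.c4b = V(c3);
  cp.fcw = M(C, c3);       cp.fcb = V(C);
  return cp;
}

// [[Rcpp::export]]
double cls_train_step_flat(const arma::cube& x, int label, double weight,
                           Rcpp::NumericVector flat, Rcpp::NumericVector mstate,
                           Rcpp::NumericVector vstate, int step_t,
                           int cin, int c1, int nclass, double lr) {
  ClsParams cp = cls_unpack_flat(flat.begin(), cin, c1, nclass);
  ClsTrace tr;
  vec probs = cls_forward_c(x, cp, tr);
  const double loss = -weight * std::log(std::max(probs(label - 1), 1e-12));
  vec dlogits = probs;
  dlogits(label - 1) -= 1.0;
  dlogits *= weight;
  std::vector<double> gbuf(flat.size());
  ClsParams gp = cls_unpack_flat(gbuf.data(), cin, c1, nclass);
  gp.fcw = dlogits * tr.gvec.t();
  gp.fcb = dlogits;
  vec dg = cp.fcw.t() * dlogits;
  const double hw = tr.h4.n_rows * tr.h4.n_cols;
  cube dh4(tr.h4.n_rows, tr.h4.n_cols, tr.h4.n_slices);
  for (uword c = 0; c < tr.h4.n_slices; ++c)
    dh4.slice(c).fill(dg(c) / hw);
  dh4 = relu_mask_mul(dh4, tr.h4);
  cube dh3 = conv_bwd_keep(tr.f4, cp.c4w, dh4, gp.c4w, gp.c4b, true);
  dh3 = relu_mask_mul(dh3, tr.h3);
  cube dh2 = conv_bwd_keep(tr.f3, cp.c3w, dh3, gp.c3w, gp.c3b, true);
  dh2 = relu_mask_mul(dh2, tr.h2);
  cube dh1 = conv_bwd_keep(tr.f2, cp.c2w, dh2, gp.c2w, gp.c2b, true);
  dh1 = relu_mask_mul(dh1, tr.h1);
  conv_bwd_keep(tr.f1, cp.c1w, dh1, gp.c1w, gp.c1b, false);
  adam_inplace(flat.begin(), mstate.begin(), vstate.begin(), gbuf.data(),
               flat.size(), step_t, lr);
  return loss;
}
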