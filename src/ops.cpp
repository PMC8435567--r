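#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Tensor layout conventions (column-major R arrays):
//   feature maps x: dim (N, C, H, W)  -> x[n + N*(c + C*(h + H*w))]
//   conv weights w: dim (KH, KW, Cg, Cout) with Cg = Cin/groups
//                 -> w[kh + KH*(kw + KW*(ci + Cg*co))]
// All kernels are single-threaded and deterministic.

static inline void get4(const IntegerVector &d, int &a, int &b, int &c, int &e) {
  a = d[0]; b = d[1]; c = d[2]; e = d[3];
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector bias, int stride, int pad,
                             int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int N, C, H, W, KH, KW, Cg, Cout;
  get4(xd, N, C, H, W);
  get4(wd, KH, KW, Cg, Cout);
  if (C != Cg * groups) stop("input channels (%d) != kernel channels (%d) * groups (%d)", C, Cg, groups);
  if (Cout % groups != 0) stop("output channels not divisible by groups");
  int Ho = (H + 2 * pad - KH) / stride + 1;
  int Wo = (W + 2 * pad - KW) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("input spatially too small for this kernel");
  NumericVector y(static_cast<R_xlen_t>(N) * Cout * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, Cout, Ho, Wo);
  int copg = Cout / groups;
  bool has_bias = bias.size() > 0;
  double *yp = y.begin(), *xp = x.begin(), *wp = w.begin();
  for (int co = 0; co < Cout; ++co) {
    int cbase = (co / copg) * Cg;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t yoff = (R_xlen_t)N * (co + (R_xlen_t)Cout * (ho + (R_xlen_t)Ho * wo));
        if (has_bias) {
          double bv = bias[co];
          for (int n = 0; n < N; ++n) yp[yoff + n] = bv;
        }
        for (int ci = 0; ci < Cg; ++ci) {
          int c = cbase + ci;
          for (int kw = 0; kw < KW; ++kw) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < KH; ++kh) {
              int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              double wv = wp[kh + (R_xlen_t)KH * (kw + (R_xlen_t)KW * (ci + (R_xlen_t)Cg * co))];
              if (wv == 0.0) continue;
              R_xlen_t xoff = (R_xlen_t)N * (c + (R_xlen_t)C * (hi + (R_xlen_t)H * wi));
              for (int n = 0; n < N; ++n) yp[yoff + n] += wv * xp[xoff + n];
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector conv2d_bwd_input_cpp(NumericVector gy, NumericVector w,
                                   IntegerVector xdim, int stride, int pad,
                                   int groups) {
  IntegerVector yd = gy.attr("dim"), wd = w.attr("dim");
  int N, Cout, Ho, Wo, KH, KW, Cg, Cout2, C, H, W, Nx;
  get4(yd, N, Cout, Ho, Wo);
  get4(wd, KH, KW, Cg, Cout2);
  get4(xdim, Nx, C, H, W);
  NumericVector gx(static_cast<R_xlen_t>(N) * C * H * W);
  gx.attr("dim") = IntegerVector::create(N, C, H, W);
  int copg = Cout / groups;
  double *gxp = gx.begin(), *gyp = gy.begin(), *wp = w.begin();
  for (int co = 0; co < Cout; ++co) {
    int cbase = (co / copg) * Cg;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t yoff = (R_xlen_t)N * (co + (R_xlen_t)Cout * (ho + (R_xlen_t)Ho * wo));
        for (int ci = 0; ci < Cg; ++ci) {
          int c = cbase + ci;
          for (int kw = 0; kw < KW; ++kw) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < KH; ++kh) {
              int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              double wv = wp[kh + (R_xlen_t)KH * (kw + (R_xlen_t)KW * (ci + (R_xlen_t)Cg * co))];
              if (wv == 0.0) continue;
              R_xlen_t xoff = (R_xlen_t)N * (c + (R_xlen_t)C * (hi + (R_xlen_t)H * wi));
              for (int n = 0; n < N; ++n) gxp[xoff + n] += wv * gyp[yoff + n];
            }
          }
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector conv2d_bwd_weight_cpp(NumericVector x, NumericVector gy,
                                    IntegerVector wdim, int stride, int pad,
                                    int groups) {
  IntegerVector xd = x.attr("dim"), yd = gy.attr("dim");
  int N, C, H, W, Ny, Cout, Ho, Wo, KH, KW, Cg, Cout2;
  get4(xd, N, C, H, W);
  get4(yd, Ny, Cout, Ho, Wo);
  get4(wdim, KH, KW, Cg, Cout2);
  NumericVector gw(static_cast<R_xlen_t>(KH) * KW * Cg * Cout);
  gw.attr("dim") = IntegerVector::create(KH, KW, Cg, Cout);
  int copg = Cout / groups;
  double *gwp = gw.begin(), *xp = x.begin(), *gyp = gy.begin();
  for (int co = 0; co < Cout; ++co) {
    int cbase = (co / copg) * Cg;
    for (int ci = 0; ci < Cg; ++ci) {
      int c = cbase + ci;
      for (int kw = 0; kw < KW; ++kw) {
        for (int kh = 0; kh < KH; ++kh) {
          double acc = 0.0;
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              R_xlen_t yoff = (R_xlen_t)N * (co + (R_xlen_t)Cout * (ho + (R_xlen_t)Ho * wo));
              R_xlen_t xoff = (R_xlen_t)N * (c + (R_xlen_t)C * (hi + (R_xlen_t)H * wi));
              for (int n = 0; n < N; ++n) acc += xp[xoff + n] * gyp[yoff + n];
            }
          }
          gwp[kh + (R_xlen_t)KH * (kw + (R_xlen_t)KW * (ci + (R_xlen_t)Cg * co))] = acc;
        }
      }
    }
  }
  return gw;
}

// Max pooling; returns the pooled map plus the 1-based linear argmax index
// into the input (first maximum wins), which the backward pass scatters into.
// [[Rcpp::export]]
List maxpool2d_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int N, C, H, W;
  get4(xd, N, C, H, W);
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("input spatially too small for max pooling");
  NumericVector y(static_cast<R_xlen_t>(N) * C * Ho * Wo);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  double *xp = x.begin(), *yp = y.begin();
  R_xlen_t p = 0;
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = R_NegInf;
          R_xlen_t bidx = -1;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              R_xlen_t xi = n + (R_xlen_t)N * (c + (R_xlen_t)C * (hi + (R_xlen_t)H * wi));
              if (xp[xi] > best) { best = xp[xi]; bidx = xi; }
            }
          }
          R_xlen_t yi = n + (R_xlen_t)N * (c + (R_xlen_t)C * (ho + (R_xlen_t)Ho * wo));
          yp[yi] = best;
          idx[yi] = (int)(bidx + 1);
          ++p;
        }
  (void)p;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2d_bwd_cpp(NumericVector gy, IntegerVector idx,
                                IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  return gx;
}

// Bilinear resampling of an (H, W, C) image to (oh, ow); half-pixel centers,
// clamped at the borders. Used for preprocessing and activation-map upsampling.
// [[Rcpp::export]]
NumericVector bilinear_resize_cpp(NumericVector img, int oh, int ow) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d.size() > 2 ? d[2] : 1;
  NumericVector out(static_cast<R_xlen_t>(oh) * ow * C);
  if (d.size() > 2) out.attr("dim") = IntegerVector::create(oh, ow, C);
  else out.attr("dim") = IntegerVector::create(oh, ow);
  double sh = (double)H / oh, sw = (double)W / ow;
  for (int c = 0; c < C; ++c) {
    R_xlen_t ob = (R_xlen_t)oh * ow * c, ib = (R_xlen_t)H * W * c;
    for (int j = 0; j < ow; ++j) {
      double sx = (j + 0.5) * sw - 0.5;
      int x0 = (int)std::floor(sx);
      double fx = sx - x0;
      int x0c = std::min(std::max(x0, 0), W - 1);
      int x1c = std::min(std::max(x0 + 1, 0), W - 1);
      for (int i = 0; i < oh; ++i) {
        double sy = (i + 0.5) * sh - 0.5;
        int y0 = (int)std::floor(sy);
        double fy = sy - y0;
        int y0c = std::min(std::max(y0, 0), H - 1);
        int y1c = std::min(std::max(y0 + 1, 0), H - 1);
        double v00 = img[ib + y0c + (R_xlen_t)H * x0c];
        double v01 = img[ib + y0c + (R_xlen_t)H * x1c];
        double v10 = img[ib + y1c + (R_xlen_t)H * x0c];
        double v11 = img[ib + y1c + (R_xlen_t)H * x1c];
        out[ob + i + (R_xlen_t)oh * j] =
          (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
      }
    }
  }
  return out;
}

// Signed distance field to a union of capsules (thick line segments with
// linearly interpolated half-width). segs is n x 6: x0, y0, x1, y1, w0, w1 in
// pixel units. Negative inside. Drives the instrument silhouette renderer.
// [[Rcpp::export]]
NumericMatrix capsule_field_cpp(NumericMatrix segs, int H, int W) {
  NumericMatrix out(H, W);
  int ns = segs.nrow();
  std::fill(out.begin(), out.end(), 1e9);
  for (int s = 0; s < ns; ++s) {
    double x0 = segs(s, 0), y0 = segs(s, 1), x1 = segs(s, 2), y1 = segs(s, 3);
    double w0 = segs(s, 4), w1 = segs(s, 5);
    double dx = x1 - x0, dy = y1 - y0;
    double len2 = dx * dx + dy * dy;
    double wmax = std::max(w0, w1);
    // bounding box with margin; skip pixels that cannot be inside
    int jlo = std::max(0, (int)std::floor(std::min(x0, x1) - wmax - 2.0));
    int jhi = std::min(W - 1, (int)std::ceil(std::max(x0, x1) + wmax + 2.0));
    int ilo = std::max(0, (int)std::floor(std::min(y0, y1) - wmax - 2.0));
    int ihi = std::min(H - 1, (int)std::ceil(std::max(y0, y1) + wmax + 2.0));
    for (int j = jlo; j <= jhi; ++j) {
      double px = j + 0.5;
      for (int i = ilo; i <= ihi; ++i) {
        double py = i + 0.5;
        double t = 0.0;
        if (len2 > 0) {
          t = ((px - x0) * dx + (py - y0) * dy) / len2;
          t = std::min(1.0, std::max(0.0, t));
        }
        double qx = x0 + t * dx - px, qy = y0 + t * dy - py;
        double d = std::sqrt(qx * qx + qy * qy) - (w0 + t * (w1 - w0));
        if (d < out(i, j)) out(i, j) = d;
      }
    }
  }
  return out;
}
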