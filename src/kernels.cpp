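// Low-level numeric kernels for the shear-deformable segmentation network.
//
// Array convention throughout: feature maps are H x W x C cubes (rows = y,
// cols = x, slices = channels), matching R's array(dim = c(H, W, C)).
// Spatial positions are linearised column-major over the H x W grid,
// p = x * H + y, so reshaping a (C x H*W) matrix back into a cube is a
// plain column-major copy.
//
// 3x3 kernel taps are ordered row-major over (dy, dx):
//   t = (dy + 1) * 3 + (dx + 1),  dy, dx in {-1, 0, 1}.
// Flattened weight matrices have 9*Cin rows indexed r = ci * 9 + t.
// Offset fields carry 18 channels: channel 2t is the x-displacement of tap t,
// channel 2t + 1 its y-displacement.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double at0(const arma::cube& x, int y, int xx, int c) {
  if (y < 0 || xx < 0 || y >= (int)x.n_rows || xx >= (int)x.n_cols) return 0.0;
  return x(y, xx, c);
}

// round half away from zero; odd-symmetric so shear and inverse-shear row
// shifts cancel exactly even when the offset lands on a half-integer
static inline int rhafz(double v) {
  return (v >= 0.0) ? (int)std::floor(v + 0.5) : -(int)std::floor(-v + 0.5);
}

// ---------------------------------------------------------------------------
// plain 3x3 convolution, stride 1, zero padding 1 (same-size output)
// ---------------------------------------------------------------------------

static void build_cols(const arma::cube& x, arma::mat& cols) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int HW = H * W;
  const double* xp = x.memptr();
  double* cp = cols.memptr();           // (9C) x HW, column-major
  const int K = 9 * C;
  for (int xo = 0; xo < W; ++xo) {
    for (int yo = 0; yo < H; ++yo) {
      double* col = cp + (size_t)(xo * H + yo) * K;
      for (int ci = 0; ci < C; ++ci) {
        const double* xs0 = xp + (size_t)ci * HW;
        double* dst = col + ci * 9;
        for (int t = 0; t < 9; ++t) {
          const int ys = yo + t / 3 - 1, xsx = xo + t % 3 - 1;
          dst[t] = (ys >= 0 && ys < H && xsx >= 0 && xsx < W)
                       ? xs0[(size_t)xsx * H + ys] : 0.0;
        }
      }
    }
  }
}

static arma::cube mat_to_cube(const arma::mat& m, int H, int W) {
  // m is (C x H*W) with p = x*H + y
  const int C = m.n_rows;
  arma::cube out(H, W, C);
  for (int c = 0; c < C; ++c) {
    arma::rowvec r = m.row(c);
    out.slice(c) = arma::reshape(r, H, W);
  }
  return out;
}

static arma::mat cube_to_mat(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat m(C, H * W);
  for (int c = 0; c < C; ++c)
    m.row(c) = arma::vectorise(x.slice(c)).t();
  return m;
}

// [[Rcpp::export(rng = false)]]
arma::cube conv3x3_fwd(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if ((int)w.n_rows != 9 * C)
    stop("conv3x3_fwd: weight rows (%d) do not match 9*channels (%d)",
         (int)w.n_rows, 9 * C);
  arma::mat cols(9 * C, H * W);
  build_cols(x, cols);
  arma::mat y = w.t() * cols;   // Cout x HW
  y.each_col() += b;
  return mat_to_cube(y, H, W);
}

// [[Rcpp::export(rng = false)]]
List conv3x3_bwd(const arma::cube& x, const arma::mat& w,
                 const arma::cube& gy) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(9 * C, H * W);
  build_cols(x, cols);
  arma::mat gym = cube_to_mat(gy);              // Cout x HW
  arma::mat gw = cols * gym.t();                // 9C x Cout
  arma::vec gb = arma::sum(gym, 1);
  arma::mat gcols = w * gym;                    // 9C x HW
  arma::cube gx(H, W, C, arma::fill::zeros);
  const int HW = H * W, K = 9 * C;
  double* gp = gx.memptr();
  const double* gc = gcols.memptr();
  for (int xo = 0; xo < W; ++xo) {
    for (int yo = 0; yo < H; ++yo) {
      const double* col = gc + (size_t)(xo * H + yo) * K;
      for (int ci = 0; ci < C; ++ci) {
        double* g0 = gp + (size_t)ci * HW;
        const double* src = col + ci * 9;
        for (int t = 0; t < 9; ++t) {
          const int ys = yo + t / 3 - 1, xs = xo + t % 3 - 1;
          if (ys >= 0 && ys < H && xs >= 0 && xs < W)
            g0[(size_t)xs * H + ys] += src[t];
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// deformable 3x3 convolution (per-position, per-tap fractional offsets)
// ---------------------------------------------------------------------------

static void build_cols_deform(const arma::cube& x, const arma::cube& off,
                              arma::mat& cols) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int HW = H * W, K = 9 * C;
  const double* xp = x.memptr();
  double* cp = cols.memptr();
  for (int xo = 0; xo < W; ++xo) {
    for (int yo = 0; yo < H; ++yo) {
      const int p = xo * H + yo;
      double* col = cp + (size_t)p * K;
      for (int t = 0; t < 9; ++t) {
        const int dy = t / 3 - 1, dx = t % 3 - 1;
        const double px = xo + dx + off(yo, xo, 2 * t);
        const double py = yo + dy + off(yo, xo, 2 * t + 1);
        const int x0 = (int)std::floor(px), y0 = (int)std::floor(py);
        const double wx = px - x0, wy = py - y0;
        const double w00 = (1 - wx) * (1 - wy), w01 = wx * (1 - wy),
                     w10 = (1 - wx) * wy,       w11 = wx * wy;
        const bool i00 = y0 >= 0 && y0 < H && x0 >= 0 && x0 < W;
        const bool i01 = y0 >= 0 && y0 < H && x0 + 1 < W && x0 + 1 >= 0;
        const bool i10 = y0 + 1 < H && y0 + 1 >= 0 && x0 >= 0 && x0 < W;
        const bool i11 = y0 + 1 < H && y0 + 1 >= 0 && x0 + 1 < W && x0 + 1 >= 0;
        const ptrdiff_t b00 = (ptrdiff_t)x0 * H + y0;
        for (int ci = 0; ci < C; ++ci) {
          const double* x0p = xp + (size_t)ci * HW;
          double v = 0.0;
          if (i00) v += w00 * x0p[b00];
          if (i01) v += w01 * x0p[b00 + H];
          if (i10) v += w10 * x0p[b00 + 1];
          if (i11) v += w11 * x0p[b00 + H + 1];
          col[ci * 9 + t] = v;
        }
      }
    }
  }
}

// [[Rcpp::export(rng = false)]]
arma::cube deform3x3_fwd(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b, const arma::cube& off) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if ((int)w.n_rows != 9 * C)
    stop("deform3x3_fwd: weight rows (%d) do not match 9*channels (%d)",
         (int)w.n_rows, 9 * C);
  if ((int)off.n_rows != H || (int)off.n_cols != W || off.n_slices != 18)
    stop("deform3x3_fwd: offset field shape mismatch");
  arma::mat cols(9 * C, H * W);
  build_cols_deform(x, off, cols);
  arma::mat y = w.t() * cols;
  y.each_col() += b;
  return mat_to_cube(y, H, W);
}

// [[Rcpp::export(rng = false)]]
List deform3x3_bwd(const arma::cube& x, const arma::mat& w,
                   const arma::cube& off, const arma::cube& gy) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(9 * C, H * W);
  build_cols_deform(x, off, cols);
  arma::mat gym = cube_to_mat(gy);
  arma::mat gw = cols * gym.t();
  arma::vec gb = arma::sum(gym, 1);
  arma::mat gcols = w * gym;                    // 9C x HW
  arma::cube gx(H, W, C, arma::fill::zeros);
  arma::cube goff(H, W, 18, arma::fill::zeros);
  for (int xo = 0; xo < W; ++xo) {
    for (int yo = 0; yo < H; ++yo) {
      const int p = xo * H + yo;
      for (int t = 0; t < 9; ++t) {
        const int dy = t / 3 - 1, dx = t % 3 - 1;
        const double px = xo + dx + off(yo, xo, 2 * t);
        const double py = yo + dy + off(yo, xo, 2 * t + 1);
        const int x0 = (int)std::floor(px), y0 = (int)std::floor(py);
        const double wx = px - x0, wy = py - y0;
        const double w00 = (1 - wx) * (1 - wy), w01 = wx * (1 - wy),
                     w10 = (1 - wx) * wy,       w11 = wx * wy;
        const bool i00 = y0 >= 0 && y0 < H && x0 >= 0 && x0 < W;
        const bool i01 = y0 >= 0 && y0 < H && x0 + 1 >= 0 && x0 + 1 < W;
        const bool i10 = y0 + 1 >= 0 && y0 + 1 < H && x0 >= 0 && x0 < W;
        const bool i11 = y0 + 1 >= 0 && y0 + 1 < H && x0 + 1 >= 0 && x0 + 1 < W;
        const ptrdiff_t b00 = (ptrdiff_t)x0 * H + y0;
        const int HW = H * W;
        const double* xp = x.memptr();
        double* gxp = gx.memptr();
        const double* gc = gcols.memptr() + (size_t)p * 9 * C;
        double gpx = 0.0, gpy = 0.0;
        for (int ci = 0; ci < C; ++ci) {
          const double g = gc[ci * 9 + t];
          if (g == 0.0) continue;
          const double* x0p = xp + (size_t)ci * HW;
          double* g0p = gxp + (size_t)ci * HW;
          const double v00 = i00 ? x0p[b00] : 0.0;
          const double v01 = i01 ? x0p[b00 + H] : 0.0;
          const double v10 = i10 ? x0p[b00 + 1] : 0.0;
          const double v11 = i11 ? x0p[b00 + H + 1] : 0.0;
          if (i00) g0p[b00] += g * w00;
          if (i01) g0p[b00 + H] += g * w01;
          if (i10) g0p[b00 + 1] += g * w10;
          if (i11) g0p[b00 + H + 1] += g * w11;
          gpx += g * ((1 - wy) * (v01 - v00) + wy * (v11 - v10));
          gpy += g * ((1 - wx) * (v10 - v00) + wx * (v11 - v01));
        }
        goff(yo, xo, 2 * t) += gpx;
        goff(yo, xo, 2 * t + 1) += gpy;
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb,
                      _["goff"] = goff);
}

// [[Rcpp::export(rng = false)]]
NumericVector bilinear_sample_cpp(const arma::cube& x, const arma::vec& px,
                                  const arma::vec& py, int c) {
  const int n = px.n_elem;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const int x0 = (int)std::floor(px[i]), y0 = (int)std::floor(py[i]);
    const double wx = px[i] - x0, wy = py[i] - y0;
    out[i] = (1 - wx) * (1 - wy) * at0(x, y0, x0, c) +
             wx * (1 - wy) * at0(x, y0, x0 + 1, c) +
             (1 - wx) * wy * at0(x, y0 + 1, x0, c) +
             wx * wy * at0(x, y0 + 1, x0 + 1, c);
  }
  return out;
}

// ---------------------------------------------------------------------------
// shear warp (backward resampling) and its adjoint
//
// Horizontal: output row y reads source column  u - (shift + factor*y).
// Vertical:   output column x reads source row  v - (shift + factor*x).
// interp: 0 = nearest (integer per-row/col shift, round half away from zero),
//         1 = bilinear. Out-of-source samples are zero.
// ---------------------------------------------------------------------------

// [[Rcpp::export(rng = false)]]
arma::cube shear_warp(const arma::cube& x, double factor, bool horizontal,
                      double shift, int out_len, int interp) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int outH = horizontal ? H : out_len;
  const int outW = horizontal ? out_len : W;
  arma::cube out(outH, outW, C, arma::fill::zeros);
  if (horizontal) {
    for (int y = 0; y < H; ++y) {
      const double t = shift + factor * y;
      if (interp == 0) {
        const int s = rhafz(t);
        for (int c = 0; c < C; ++c)
          for (int u = 0; u < outW; ++u) {
            const int xs = u - s;
            if (xs >= 0 && xs < W) out(y, u, c) = x(y, xs, c);
          }
      } else {
        for (int c = 0; c < C; ++c)
          for (int u = 0; u < outW; ++u) {
            const double src = u - t;
            const int i0 = (int)std::floor(src);
            const double wf = src - i0;
            double v = 0.0;
            if (i0 >= 0 && i0 < W) v += (1 - wf) * x(y, i0, c);
            if (i0 + 1 >= 0 && i0 + 1 < W) v += wf * x(y, i0 + 1, c);
            out(y, u, c) = v;
          }
      }
    }
  } else {
    for (int xx = 0; xx < W; ++xx) {
      const double t = shift + factor * xx;
      if (interp == 0) {
        const int s = rhafz(t);
        for (int c = 0; c < C; ++c)
          for (int v = 0; v < outH; ++v) {
            const int ys = v - s;
            if (ys >= 0 && ys < H) out(v, xx, c) = x(ys, xx, c);
          }
      } else {
        for (int c = 0; c < C; ++c)
          for (int v = 0; v < outH; ++v) {
            const double src = v - t;
            const int i0 = (int)std::floor(src);
            const double wf = src - i0;
            double val = 0.0;
            if (i0 >= 0 && i0 < H) val += (1 - wf) * x(i0, xx, c);
            if (i0 + 1 >= 0 && i0 + 1 < H) val += wf * x(i0 + 1, xx, c);
            out(v, xx, c) = val;
          }
      }
    }
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
arma::cube shear_warp_adjoint(const arma::cube& g, double factor,
                              bool horizontal, double shift, int in_H,
                              int in_W, int interp) {
  const int C = g.n_slices;
  arma::cube gx(in_H, in_W, C, arma::fill::zeros);
  if (horizontal) {
    const int outW = g.n_cols;
    for (int y = 0; y < (int)g.n_rows; ++y) {
      const double t = shift + factor * y;
      if (interp == 0) {
        const int s = rhafz(t);
        for (int c = 0; c < C; ++c)
          for (int u = 0; u < outW; ++u) {
            const int xs = u - s;
            if (xs >= 0 && xs < in_W) gx(y, xs, c) += g(y, u, c);
          }
      } else {
        for (int c = 0; c < C; ++c)
          for (int u = 0; u < outW; ++u) {
            const double src = u - t;
            const int i0 = (int)std::floor(src);
            const double wf = src - i0;
            if (i0 >= 0 && i0 < in_W) gx(y, i0, c) += (1 - wf) * g(y, u, c);
            if (i0 + 1 >= 0 && i0 + 1 < in_W) gx(y, i0 + 1, c) += wf * g(y, u, c);
          }
      }
    }
  } else {
    const int outH = g.n_rows;
    for (int xx = 0; xx < (int)g.n_cols; ++xx) {
      const double t = shift + factor * xx;
      if (interp == 0) {
        const int s = rhafz(t);
        for (int c = 0; c < C; ++c)
          for (int v = 0; v < outH; ++v) {
            const int ys = v - s;
            if (ys >= 0 && ys < in_H) gx(ys, xx, c) += g(v, xx, c);
          }
      } else {
        for (int c = 0; c < C; ++c)
          for (int v = 0; v < outH; ++v) {
            const double src = v - t;
            const int i0 = (int)std::floor(src);
            const double wf = src - i0;
            if (i0 >= 0 && i0 < in_H) gx(i0, xx, c) += (1 - wf) * g(v, xx, c);
            if (i0 + 1 >= 0 && i0 + 1 < in_H) gx(i0 + 1, xx, c) += wf * g(v, xx, c);
          }
      }
    }
  }
  return gx;
}

// ---------------------------------------------------------------------------
// 2x2 max pooling (stride 2) with argmax bookkeeping
// ---------------------------------------------------------------------------

// [[Rcpp::export(rng = false)]]
List maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("maxpool2_fwd: spatial dims must be even");
  const int H2 = H / 2, W2 = W / 2;
  arma::cube y(H2, W2, C);
  arma::cube arg(H2, W2, C);   // 0..3 = ry*2 + rx of the winning corner
  for (int c = 0; c < C; ++c)
    for (int xo = 0; xo < W2; ++xo)
      for (int yo = 0; yo < H2; ++yo) {
        double best = x(2 * yo, 2 * xo, c);
        int bi = 0;
        for (int k = 1; k < 4; ++k) {
          const double v = x(2 * yo + (k / 2), 2 * xo + (k % 2), c);
          if (v > best) { best = v; bi = k; }
        }
        y(yo, xo, c) = best;
        arg(yo, xo, c) = bi;
      }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(rng = false)]]
arma::cube maxpool2_bwd(const arma::cube& gy, const arma::cube& arg) {
  const int H2 = gy.n_rows, W2 = gy.n_cols, C = gy.n_slices;
  arma::cube gx(2 * H2, 2 * W2, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int xo = 0; xo < W2; ++xo)
      for (int yo = 0; yo < H2; ++yo) {
        const int k = (int)arg(yo, xo, c);
        gx(2 * yo + (k / 2), 2 * xo + (k % 2), c) = gy(yo, xo, c);
      }
  return gx;
}

// ---------------------------------------------------------------------------
// 2x2 stride-2 transposed convolution (learned upsampling)
// weight matrix: Cin x (4*Cout), column co*4 + (a*2 + b) maps input pixel
// (i, j) to output pixel (2i + a, 2j + b) of channel co
// ---------------------------------------------------------------------------

// [[Rcpp::export(rng = false)]]
arma::cube tconv2_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if ((int)w.n_rows != C) stop("tconv2_fwd: weight/channel mismatch");
  const int Cout = w.n_cols / 4;
  arma::mat X = cube_to_mat(x);          // C x HW
  arma::mat Y4 = w.t() * X;              // 4Cout x HW
  arma::cube out(2 * H, 2 * W, Cout);
  for (int co = 0; co < Cout; ++co) {
    for (int xo = 0; xo < W; ++xo)
      for (int yo = 0; yo < H; ++yo) {
        const int p = xo * H + yo;
        out(2 * yo,     2 * xo,     co) = Y4(co * 4 + 0, p) + b(co);
        out(2 * yo,     2 * xo + 1, co) = Y4(co * 4 + 1, p) + b(co);
        out(2 * yo + 1, 2 * xo,     co) = Y4(co * 4 + 2, p) + b(co);
        out(2 * yo + 1, 2 * xo + 1, co) = Y4(co * 4 + 3, p) + b(co);
      }
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List tconv2_bwd(const arma::cube& x, const arma::mat& w,
                const arma::cube& gy) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Cout = gy.n_slices;
  arma::mat gY4(4 * Cout, H * W);
  arma::vec gb(Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    gb(co) = arma::accu(gy.slice(co));
    for (int xo = 0; xo < W; ++xo)
      for (int yo = 0; yo < H; ++yo) {
        const int p = xo * H + yo;
        gY4(co * 4 + 0, p) = gy(2 * yo,     2 * xo,     co);
        gY4(co * 4 + 1, p) = gy(2 * yo,     2 * xo + 1, co);
        gY4(co * 4 + 2, p) = gy(2 * yo + 1, 2 * xo,     co);
        gY4(co * 4 + 3, p) = gy(2 * yo + 1, 2 * xo + 1, co);
      }
  }
  arma::mat X = cube_to_mat(x);
  arma::mat gw = X * gY4.t();            // C x 4Cout
  arma::mat gX = w * gY4;                // C x HW
  return List::create(_["gx"] = mat_to_cube(gX, H, W), _["gw"] = gw,
                      _["gb"] = gb);
}
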