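// Low-level 3D tensor ops for the residual U-Net: direct stride-1
// zero-padded convolution, stride-2 transposed convolution, and 2x2x2 max
// pooling, each with an explicit backward pass.  Layout convention
// throughout: R arrays [C, X, Y, Z], channel fastest (column-major).
// Channel counts are small (<= ~64), so direct register-accumulating
// loops beat im2col+gemm: the volumes stay cache-resident instead of being
// expanded k^3-fold.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static IntegerVector spatial_dims(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a [C, X, Y, Z] array");
  return d;
}

// valid kernel-offset range [o0, o1) for position p on an axis of size n
static inline void valid_range(int p, int n, int k, int pad, int& o0,
                               int& o1) {
  o0 = std::max(0, pad - p);
  o1 = std::min(k, n + pad - p);
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int k, int pad) {
  IntegerVector d = spatial_dims(x);
  const int C = d[0], X = d[1], Y = d[2], Z = d[3];
  IntegerVector dw = w.attr("dim");
  const int Cout = dw[0];
  if (dw[1] != C) stop("conv3d: input has %d channels, kernel expects %d",
                       C, (int)dw[1]);
  NumericVector out((size_t)Cout * X * Y * Z);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = out.begin();
  std::vector<double> acc(Cout);
  for (int z = 0; z < Z; ++z) {
    int l0, l1; valid_range(z, Z, k, pad, l0, l1);
    for (int y = 0; y < Y; ++y) {
      int j0, j1; valid_range(y, Y, k, pad, j0, j1);
      for (int xx = 0; xx < X; ++xx) {
        int i0, i1; valid_range(xx, X, k, pad, i0, i1);
        for (int co = 0; co < Cout; ++co) acc[co] = b[co];
        for (int l = l0; l < l1; ++l) {
          const int sz = z + l - pad;
          for (int j = j0; j < j1; ++j) {
            const int sy = y + j - pad;
            const size_t base = (size_t)C * ((xx + i0 - pad) +
                                 (size_t)X * (sy + (size_t)Y * sz));
            const double* xv = xp + base;
            for (int i = i0; i < i1; ++i, xv += C) {
              const double* wv = wp +
                (size_t)Cout * C * (i + k * (j + k * l));
              for (int ci = 0; ci < C; ++ci) {
                const double v = xv[ci];
                const double* wc = wv + (size_t)Cout * ci;
                for (int co = 0; co < Cout; ++co) acc[co] += wc[co] * v;
              }
            }
          }
        }
        double* yv = yp + (size_t)Cout * (xx + (size_t)X * (y + (size_t)Y * z));
        for (int co = 0; co < Cout; ++co) yv[co] = acc[co];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Cout, X, Y, Z);
  return out;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int k, int pad) {
  IntegerVector d = spatial_dims(x);
  const int C = d[0], X = d[1], Y = d[2], Z = d[3];
  IntegerVector dw = w.attr("dim");
  const int Cout = dw[0];
  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();
  double* gbp = gb.begin();
  std::vector<double> gacc(C);
  for (int z = 0; z < Z; ++z) {
    int l0, l1; valid_range(z, Z, k, pad, l0, l1);
    for (int y = 0; y < Y; ++y) {
      int j0, j1; valid_range(y, Y, k, pad, j0, j1);
      for (int xx = 0; xx < X; ++xx) {
        int i0, i1; valid_range(xx, X, k, pad, i0, i1);
        const double* gyv = gyp +
          (size_t)Cout * (xx + (size_t)X * (y + (size_t)Y * z));
        for (int co = 0; co < Cout; ++co) gbp[co] += gyv[co];
        for (int l = l0; l < l1; ++l) {
          const int sz = z + l - pad;
          for (int j = j0; j < j1; ++j) {
            const int sy = y + j - pad;
            const size_t base = (size_t)C * ((xx + i0 - pad) +
                                 (size_t)X * (sy + (size_t)Y * sz));
            const double* xv = xp + base;
            double* gxv = gxp + base;
            for (int i = i0; i < i1; ++i, xv += C, gxv += C) {
              const size_t wo = (size_t)Cout * C * (i + k * (j + k * l));
              const double* wv = wp + wo;
              double* gwv = gwp + wo;
              for (int ci = 0; ci < C; ++ci) {
                const double v = xv[ci];
                const double* wc = wv + (size_t)Cout * ci;
                double* gwc = gwv + (size_t)Cout * ci;
                double a = 0.0;
                for (int co = 0; co < Cout; ++co) {
                  const double g = gyv[co];
                  gwc[co] += g * v;
                  a += wc[co] * g;
                }
                gxv[ci] += a;
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = x.attr("dim");
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution, kernel 2, stride 2 (doubles each spatial dim).
// w layout: [Cin, Cout, 2, 2, 2].
// [[Rcpp::export(name = ".convtrans3d_fwd")]]
NumericVector convtrans3d_fwd(NumericVector x, NumericVector w,
                              NumericVector b) {
  IntegerVector d = spatial_dims(x);
  const int C = d[0], X = d[1], Y = d[2], Z = d[3];
  IntegerVector dw = w.attr("dim");
  if (dw[0] != C) stop("convtrans3d: channel mismatch");
  const int Cout = dw[1];
  const int X2 = 2 * X, Y2 = 2 * Y, Z2 = 2 * Z;
  NumericVector out((size_t)Cout * X2 * Y2 * Z2);
  double* yp = out.begin();
  for (size_t i = 0; i < (size_t)out.size(); i += Cout)
    for (int c = 0; c < Cout; ++c) yp[i + c] = b[c];
  const double* xp = x.begin();
  const double* wp = w.begin();
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int xx = 0; xx < X; ++xx) {
        const double* xv = xp + (size_t)C * (xx + (size_t)X * (y + (size_t)Y * z));
        for (int l = 0; l < 2; ++l)
          for (int j = 0; j < 2; ++j)
            for (int i = 0; i < 2; ++i) {
              double* dst = yp + (size_t)Cout *
                ((2 * xx + i) + (size_t)X2 * ((2 * y + j) + (size_t)Y2 * (2 * z + l)));
              const double* wv = wp + (size_t)C * Cout * (i + 2 * (j + 2 * l));
              for (int co = 0; co < Cout; ++co) {
                double a = 0.0;
                for (int ci = 0; ci < C; ++ci)
                  a += wv[ci + (size_t)C * co] * xv[ci];
                dst[co] += a;
              }
            }
      }
  out.attr("dim") = IntegerVector::create(Cout, X2, Y2, Z2);
  return out;
}

// [[Rcpp::export(name = ".convtrans3d_bwd")]]
List convtrans3d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector d = spatial_dims(x);
  const int C = d[0], X = d[1], Y = d[2], Z = d[3];
  IntegerVector dw = w.attr("dim");
  const int Cout = dw[1];
  const int X2 = 2 * X, Y2 = 2 * Y;
  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();
  for (size_t i = 0; i < (size_t)gy.size(); i += Cout)
    for (int c = 0; c < Cout; ++c) gb[c] += gyp[i + c];
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int xx = 0; xx < X; ++xx) {
        const size_t xi = (size_t)C * (xx + (size_t)X * (y + (size_t)Y * z));
        const double* xv = xp + xi;
        double* gxv = gxp + xi;
        for (int l = 0; l < 2; ++l)
          for (int j = 0; j < 2; ++j)
            for (int i = 0; i < 2; ++i) {
              const double* gv = gyp + (size_t)Cout *
                ((2 * xx + i) + (size_t)X2 * ((2 * y + j) + (size_t)Y2 * (2 * z + l)));
              const size_t wo = (size_t)C * Cout * (i + 2 * (j + 2 * l));
              for (int co = 0; co < Cout; ++co) {
                const double g = gv[co];
                const double* wc = wp + wo + (size_t)C * co;
                double* gwc = gwp + wo + (size_t)C * co;
                for (int ci = 0; ci < C; ++ci) {
                  gxv[ci] += wc[ci] * g;
                  gwc[ci] += xv[ci] * g;
                }
              }
            }
      }
  gx.attr("dim") = x.attr("dim");
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling; returns pooled values and 1-based argmax indices into
// the flattened input so the backward pass can route gradients.
// [[Rcpp::export(name = ".maxpool3d_fwd")]]
List maxpool3d_fwd(NumericVector x) {
  IntegerVector d = spatial_dims(x);
  const int C = d[0], X = d[1], Y = d[2], Z = d[3];
  if (X % 2 || Y % 2 || Z % 2) stop("maxpool3d: spatial dims must be even");
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector out((size_t)C * Xo * Yo * Zo);
  IntegerVector arg(out.size());
  const double* xp = x.begin();
  double* yp = out.begin();
  int* ap = arg.begin();
  for (int z = 0; z < Zo; ++z)
    for (int y = 0; y < Yo; ++y)
      for (int xx = 0; xx < Xo; ++xx)
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          size_t best_i = 0;
          for (int l = 0; l < 2; ++l)
            for (int j = 0; j < 2; ++j)
              for (int i = 0; i < 2; ++i) {
                const size_t ii = c + (size_t)C *
                  ((2 * xx + i) + (size_t)X * ((2 * y + j) + (size_t)Y * (2 * z + l)));
                if (xp[ii] > best) { best = xp[ii]; best_i = ii; }
              }
          const size_t oo = c + (size_t)C * (xx + (size_t)Xo * (y + (size_t)Yo * z));
          yp[oo] = best;
          ap[oo] = (int)best_i + 1;
        }
  out.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo);
  return List::create(_["y"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool3d_bwd")]]
NumericVector maxpool3d_bwd(NumericVector gy, IntegerVector argmax,
                            IntegerVector in_dim) {
  size_t n = 1;
  for (int i = 0; i < in_dim.size(); ++i) n *= in_dim[i];
  NumericVector gx(n);
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    gx[argmax[i] - 1] += gy[i];
  gx.attr("dim") = in_dim;
  return gx;
}
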