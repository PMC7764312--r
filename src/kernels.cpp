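// Low-level numerical kernels for the segmentation network and resamplers.
// Feature grids are column-major double arrays with dim (X, Y, Z, C, B);
// GEMM work is done in single precision through Armadillo (BLAS sgemm),
// which roughly halves memory traffic relative to double on these
// memory-bound im2col matrices. All kernels are single-threaded and
// deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

IntegerVector dims_of(const NumericVector& a) {
  return a.attr("dim");
}

} // namespace

namespace {

// Copy one sample (XYZ x C doubles) into a zero-bordered padded float
// buffer of (Xp*Yp*Zp x C).
void pad_to_float(const double* x, int X, int Y, int Z, int C, int pad,
                  float* xp) {
  const int Xp = X + 2 * pad, Yp = Y + 2 * pad, Zp = Z + 2 * pad;
  const R_xlen_t Np = (R_xlen_t)Xp * Yp * Zp;
  std::fill(xp, xp + Np * C, 0.0f);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (R_xlen_t)c * X * Y * Z;
    float* pc = xp + (R_xlen_t)c * Np;
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y) {
        const double* s = xc + ((R_xlen_t)z * Y + y) * X;
        float* d = pc + (((R_xlen_t)(z + pad) * Yp) + (y + pad)) * Xp + pad;
        for (int xx = 0; xx < X; ++xx) d[xx] = (float)s[xx];
      }
  }
}

} // namespace

// 3D convolution, stride 1, kernel k in {1,3,...}, zero padding (k-1)/2 so
// spatial size is preserved. x: (X,Y,Z,Cin,B); w: (k,k,k,Cin,Cout); b: Cout.
// Implemented as one small (Cin x Cout) GEMM per kernel offset over a
// zero-padded float copy of the input, followed by shifted span
// accumulation -- far less memory traffic than an im2col expansion.
// [[Rcpp::export]]
NumericVector cpp_conv3d_forward(NumericVector x, NumericVector w,
                                 NumericVector bias) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3],
            B = xd.size() > 4 ? xd[4] : 1;
  const int k = wd[0], Cout = wd[4];
  const int pad = (k - 1) / 2;
  if (wd[3] != Cin) stop("conv3d: weight input channels do not match input");
  const int Xp = X + 2 * pad, Yp = Y + 2 * pad, Zp = Z + 2 * pad;
  const R_xlen_t XYZ = (R_xlen_t)X * Y * Z;
  const R_xlen_t Np = (R_xlen_t)Xp * Yp * Zp;
  const int KK = k * k * k;

  // per-offset weight slices W_o (Cin x Cout)
  std::vector<arma::fmat> Wo(KK);
  for (int o = 0; o < KK; ++o) {
    Wo[o].set_size(Cin, Cout);
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        Wo[o](ci, co) = (float)w[o + (R_xlen_t)KK * (ci + (R_xlen_t)Cin * co)];
  }

  std::vector<float> xpad(Np * Cin);
  std::vector<float> acc(XYZ * Cout);
  arma::fmat Zo; // Np x Cout scratch

  NumericVector out(XYZ * Cout * (R_xlen_t)B);
  out.attr("dim") = IntegerVector::create(X, Y, Z, Cout, B);

  for (int b = 0; b < B; ++b) {
    pad_to_float(&x[0] + (R_xlen_t)b * XYZ * Cin, X, Y, Z, Cin, pad,
                 xpad.data());
    arma::fmat Xm(xpad.data(), Np, Cin, false, true);
    for (int co = 0; co < Cout; ++co)
      std::fill(acc.begin() + (R_xlen_t)co * XYZ,
                acc.begin() + (R_xlen_t)(co + 1) * XYZ, (float)bias[co]);
    int o = 0;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx, ++o) {
          Zo = Xm * Wo[o]; // Np x Cout
          for (int co = 0; co < Cout; ++co) {
            const float* zc = Zo.colptr(co);
            float* ac = acc.data() + (R_xlen_t)co * XYZ;
            for (int z = 0; z < Z; ++z)
              for (int y = 0; y < Y; ++y) {
                const float* s = zc +
                  (((R_xlen_t)(z + kz) * Yp) + (y + ky)) * Xp + kx;
                float* d = ac + ((R_xlen_t)z * Y + y) * X;
                for (int xx = 0; xx < X; ++xx) d[xx] += s[xx];
              }
          }
        }
    double* op = &out[0] + (R_xlen_t)b * XYZ * Cout;
    for (R_xlen_t i = 0; i < XYZ * Cout; ++i) op[i] = (double)acc[i];
  }
  return out;
}

// Backward pass of cpp_conv3d_forward. Returns gx, gw, gb. Set
// `need_gx = false` when the input is a graph leaf to skip the input
// gradient.
// [[Rcpp::export]]
List cpp_conv3d_backward(NumericVector x, NumericVector w, NumericVector gy,
                         bool need_gx = true) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int X = xd[0], Y = xd[1], Z = xd[2], Cin = xd[3],
            B = xd.size() > 4 ? xd[4] : 1;
  const int k = wd[0], Cout = wd[4];
  const int pad = (k - 1) / 2;
  const int Xp = X + 2 * pad, Yp = Y + 2 * pad, Zp = Z + 2 * pad;
  const R_xlen_t XYZ = (R_xlen_t)X * Y * Z;
  const R_xlen_t Np = (R_xlen_t)Xp * Yp * Zp;
  const int KK = k * k * k;

  std::vector<arma::fmat> Wo(KK);
  for (int o = 0; o < KK; ++o) {
    Wo[o].set_size(Cin, Cout);
    for (int co = 0; co < Cout; ++co)
      for (int ci = 0; ci < Cin; ++ci)
        Wo[o](ci, co) = (float)w[o + (R_xlen_t)KK * (ci + (R_xlen_t)Cin * co)];
  }

  // slack so that pointer-shifted views of xpad stay inside the buffer
  const R_xlen_t slack = (R_xlen_t)(k - 1) * (1 + Xp + (R_xlen_t)Xp * Yp);
  std::vector<float> xpad(Np * Cin + slack, 0.0f);
  std::vector<float> gypad(Np * Cout), gyf(XYZ * Cout);
  std::vector<float> gxpad;
  if (need_gx) gxpad.resize(Np * Cin);
  std::vector<arma::fmat> GWo(KK);
  for (int o = 0; o < KK; ++o) GWo[o].zeros(Cin, Cout);
  arma::fmat Go;

  NumericVector gx(need_gx ? x.size() : 0);
  if (need_gx) gx.attr("dim") = xd;
  NumericVector gb(Cout);

  for (int b = 0; b < B; ++b) {
    const double* gyb = &gy[0] + (R_xlen_t)b * XYZ * Cout;
    for (R_xlen_t i = 0; i < XYZ * Cout; ++i) gyf[i] = (float)gyb[i];
    arma::fmat GY(gyf.data(), XYZ, Cout, false, true);
    for (int co = 0; co < Cout; ++co) {
      double s = 0;
      const double* gc = gyb + (R_xlen_t)co * XYZ;
      for (R_xlen_t i = 0; i < XYZ; ++i) s += gc[i];
      gb[co] += s;
    }

    pad_to_float(&x[0] + (R_xlen_t)b * XYZ * Cin, X, Y, Z, Cin, pad,
                 xpad.data());
    if (need_gx) std::fill(gxpad.begin(), gxpad.end(), 0.0f);

    // embed gy once at the padded-grid origin; per-offset weight
    // gradients then use pointer-shifted views of xpad:
    //   gW_o = sum_v xpad[v + o] gy[v] = Xshift(delta_o)^T GYpad0,
    // reads past a channel column hit rows where gypad0 is zero.
    std::fill(gypad.begin(), gypad.end(), 0.0f);
    for (int co = 0; co < Cout; ++co) {
      const float* s = gyf.data() + (R_xlen_t)co * XYZ;
      float* d = gypad.data() + (R_xlen_t)co * Np;
      for (int z = 0; z < Z; ++z)
        for (int y = 0; y < Y; ++y)
          std::copy(s + ((R_xlen_t)z * Y + y) * X,
                    s + ((R_xlen_t)z * Y + y) * X + X,
                    d + ((R_xlen_t)z * Yp + y) * Xp);
    }
    arma::fmat GYp0(gypad.data(), Np, Cout, false, true);

    int o = 0;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx, ++o) {
          const R_xlen_t delta = kx + (R_xlen_t)ky * Xp +
                                 (R_xlen_t)kz * Xp * Yp;
          arma::fmat Xsh(xpad.data() + delta, Np, Cin, false, true);
          GWo[o] += Xsh.t() * GYp0;

          if (need_gx) {
            Go = GY * Wo[o].t(); // XYZ x Cin
            for (int ci = 0; ci < Cin; ++ci) {
              const float* s = Go.colptr(ci);
              float* d = gxpad.data() + (R_xlen_t)ci * Np;
              for (int z = 0; z < Z; ++z)
                for (int y = 0; y < Y; ++y) {
                  const float* srow = s + ((R_xlen_t)z * Y + y) * X;
                  float* drow = d +
                    (((R_xlen_t)(z + kz) * Yp) + (y + ky)) * Xp + kx;
                  for (int xx = 0; xx < X; ++xx) drow[xx] += srow[xx];
                }
            }
          }
        }

    if (need_gx) {
      // crop the padded gradient back to the input grid
      double* gxs = &gx[0] + (R_xlen_t)b * XYZ * Cin;
      for (int ci = 0; ci < Cin; ++ci) {
        const float* pc = gxpad.data() + (R_xlen_t)ci * Np;
        double* gc = gxs + (R_xlen_t)ci * XYZ;
        for (int z = 0; z < Z; ++z)
          for (int y = 0; y < Y; ++y) {
            const float* s = pc +
              (((R_xlen_t)(z + pad) * Yp) + (y + pad)) * Xp + pad;
            double* d = gc + ((R_xlen_t)z * Y + y) * X;
            for (int xx = 0; xx < X; ++xx) d[xx] = (double)s[xx];
          }
      }
    }
  }

  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int o = 0; o < KK; ++o)
        gw[o + (R_xlen_t)KK * (ci + (R_xlen_t)Cin * co)] = GWo[o](ci, co);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling, stride 2. Returns pooled values and the linear
// (0-based, within-sample) argmax indices needed by the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  IntegerVector xd = dims_of(x);
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3],
            B = xd.size() > 4 ? xd[4] : 1;
  if (X % 2 || Y % 2 || Z % 2) stop("maxpool2: odd spatial dimension");
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  const R_xlen_t XYZ = (R_xlen_t)X * Y * Z;
  const R_xlen_t XYZo = (R_xlen_t)Xo * Yo * Zo;

  NumericVector out(XYZo * C * (R_xlen_t)B);
  IntegerVector idx(out.size());
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C, B);

  R_xlen_t o = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xc = &x[0] + ((R_xlen_t)b * C + c) * XYZ;
      for (int z = 0; z < Zo; ++z)
        for (int y = 0; y < Yo; ++y)
          for (int xx = 0; xx < Xo; ++xx, ++o) {
            double best = -1e300;
            R_xlen_t besti = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  R_xlen_t i = ((R_xlen_t)(2 * z + dz) * Y + (2 * y + dy)) * X +
                               (2 * xx + dx);
                  if (xc[i] > best) { best = xc[i]; besti = i; }
                }
            out[o] = best;
            idx[o] = (int)((R_xlen_t)c * XYZ + besti); // within-sample index
          }
    }
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector gy, IntegerVector idx,
                                    IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3],
            B = xdim.size() > 4 ? xdim[4] : 1;
  const R_xlen_t XYZC = (R_xlen_t)X * Y * Z * C;
  NumericVector gx(XYZC * B);
  gx.attr("dim") = xdim;
  const R_xlen_t per = gy.size() / B;
  for (int b = 0; b < B; ++b) {
    double* g = &gx[0] + (R_xlen_t)b * XYZC;
    const double* gyb = &gy[0] + (R_xlen_t)b * per;
    const int* ib = &idx[0] + (R_xlen_t)b * per;
    for (R_xlen_t i = 0; i < per; ++i) g[ib[i]] += gyb[i];
  }
  return gx;
}

namespace {
// two-tap weights for 2x trilinear upsampling, align_corners = FALSE:
// source coordinate of output index i is (i + 0.5)/2 - 0.5.
struct Tap { int i0, i1; double w0, w1; };
std::vector<Tap> up_taps(int n_out, int n_in) {
  std::vector<Tap> t(n_out);
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) * 0.5 - 0.5;
    int i0 = (int)std::floor(s);
    double f = s - i0;
    int i1 = i0 + 1;
    t[i].i0 = clampi(i0, 0, n_in - 1);
    t[i].i1 = clampi(i1, 0, n_in - 1);
    t[i].w0 = 1.0 - f;
    t[i].w1 = f;
  }
  return t;
}
} // namespace

// Trilinear 2x upsampling of (X,Y,Z,C,B).
// [[Rcpp::export]]
NumericVector cpp_upsample2_forward(NumericVector x) {
  IntegerVector xd = dims_of(x);
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3],
            B = xd.size() > 4 ? xd[4] : 1;
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  const R_xlen_t XYZ = (R_xlen_t)X * Y * Z, XYZo = (R_xlen_t)Xo * Yo * Zo;
  auto tx = up_taps(Xo, X), ty = up_taps(Yo, Y), tz = up_taps(Zo, Z);

  NumericVector out(XYZo * C * (R_xlen_t)B);
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C, B);
  R_xlen_t o = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* xc = &x[0] + ((R_xlen_t)b * C + c) * XYZ;
      for (int z = 0; z < Zo; ++z)
        for (int y = 0; y < Yo; ++y) {
          const Tap &az = tz[z], &ay = ty[y];
          const double* p00 = xc + ((R_xlen_t)az.i0 * Y + ay.i0) * X;
          const double* p01 = xc + ((R_xlen_t)az.i0 * Y + ay.i1) * X;
          const double* p10 = xc + ((R_xlen_t)az.i1 * Y + ay.i0) * X;
          const double* p11 = xc + ((R_xlen_t)az.i1 * Y + ay.i1) * X;
          for (int xx = 0; xx < Xo; ++xx, ++o) {
            const Tap& ax = tx[xx];
            double v00 = az.w0 * (ay.w0 * p00[ax.i0] + ay.w1 * p01[ax.i0]) +
                         az.w1 * (ay.w0 * p10[ax.i0] + ay.w1 * p11[ax.i0]);
            double v01 = az.w0 * (ay.w0 * p00[ax.i1] + ay.w1 * p01[ax.i1]) +
                         az.w1 * (ay.w0 * p10[ax.i1] + ay.w1 * p11[ax.i1]);
            out[o] = ax.w0 * v00 + ax.w1 * v01;
          }
        }
    }
  return out;
}

// Adjoint of cpp_upsample2_forward.
// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector gy, IntegerVector xdim) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3],
            B = xdim.size() > 4 ? xdim[4] : 1;
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  const R_xlen_t XYZ = (R_xlen_t)X * Y * Z;
  auto tx = up_taps(Xo, X), ty = up_taps(Yo, Y), tz = up_taps(Zo, Z);

  NumericVector gx(XYZ * C * (R_xlen_t)B);
  gx.attr("dim") = xdim;
  R_xlen_t o = 0;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double* gc = &gx[0] + ((R_xlen_t)b * C + c) * XYZ;
      for (int z = 0; z < Zo; ++z)
        for (int y = 0; y < Yo; ++y) {
          const Tap &az = tz[z], &ay = ty[y];
          for (int xx = 0; xx < Xo; ++xx, ++o) {
            const Tap& ax = tx[xx];
            const double g = gy[o];
            gc[((R_xlen_t)az.i0 * Y + ay.i0) * X + ax.i0] += g * az.w0 * ay.w0 * ax.w0;
            gc[((R_xlen_t)az.i0 * Y + ay.i0) * X + ax.i1] += g * az.w0 * ay.w0 * ax.w1;
            gc[((R_xlen_t)az.i0 * Y + ay.i1) * X + ax.i0] += g * az.w0 * ay.w1 * ax.w0;
            gc[((R_xlen_t)az.i0 * Y + ay.i1) * X + ax.i1] += g * az.w0 * ay.w1 * ax.w1;
            gc[((R_xlen_t)az.i1 * Y + ay.i0) * X + ax.i0] += g * az.w1 * ay.w0 * ax.w0;
            gc[((R_xlen_t)az.i1 * Y + ay.i0) * X + ax.i1] += g * az.w1 * ay.w0 * ax.w1;
            gc[((R_xlen_t)az.i1 * Y + ay.i1) * X + ax.i0] += g * az.w1 * ay.w1 * ax.w0;
            gc[((R_xlen_t)az.i1 * Y + ay.i1) * X + ax.i1] += g * az.w1 * ay.w1 * ax.w1;
          }
        }
    }
  return gx;
}

namespace {
inline double sample_trilinear(const double* v, int X, int Y, int Z,
                               double sx, double sy, double sz, double fill) {
  if (sx < -0.5 || sy < -0.5 || sz < -0.5 ||
      sx > X - 0.5 || sy > Y - 0.5 || sz > Z - 0.5)
    return fill;
  int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
      z0 = (int)std::floor(sz);
  double fx = sx - x0, fy = sy - y0, fz = sz - z0;
  int x1 = x0 + 1, y1 = y0 + 1, z1 = z0 + 1;
  x0 = clampi(x0, 0, X - 1); x1 = clampi(x1, 0, X - 1);
  y0 = clampi(y0, 0, Y - 1); y1 = clampi(y1, 0, Y - 1);
  z0 = clampi(z0, 0, Z - 1); z1 = clampi(z1, 0, Z - 1);
  auto at = [&](int x, int y, int z) {
    return v[((R_xlen_t)z * Y + y) * X + x];
  };
  double c00 = at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx;
  double c10 = at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx;
  double c01 = at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx;
  double c11 = at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

inline double sample_nn(const double* v, int X, int Y, int Z,
                        double sx, double sy, double sz, double fill) {
  int x = (int)std::lround(sx), y = (int)std::lround(sy),
      z = (int)std::lround(sz);
  if (x < 0 || y < 0 || z < 0 || x >= X || y >= Y || z >= Z) return fill;
  return v[((R_xlen_t)z * Y + y) * X + x];
}
} // namespace

// Resample a 3D volume under a voxel-to-voxel map: for each output voxel
// o (0-based), source coords = M %*% c(o, 1). method: 0 nearest, 1 trilinear.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, NumericMatrix M,
                                  IntegerVector outdim, int method,
                                  double fill) {
  IntegerVector vd = dims_of(vol);
  const int X = vd[0], Y = vd[1], Z = vd[2];
  const int Xo = outdim[0], Yo = outdim[1], Zo = outdim[2];
  NumericVector out((R_xlen_t)Xo * Yo * Zo);
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo);
  const double* v = &vol[0];
  R_xlen_t o = 0;
  for (int z = 0; z < Zo; ++z)
    for (int y = 0; y < Yo; ++y)
      for (int x = 0; x < Xo; ++x, ++o) {
        double sx = M(0, 0) * x + M(0, 1) * y + M(0, 2) * z + M(0, 3);
        double sy = M(1, 0) * x + M(1, 1) * y + M(1, 2) * z + M(1, 3);
        double sz = M(2, 0) * x + M(2, 1) * y + M(2, 2) * z + M(2, 3);
        out[o] = method == 1 ? sample_trilinear(v, X, Y, Z, sx, sy, sz, fill)
                             : sample_nn(v, X, Y, Z, sx, sy, sz, fill);
      }
  return out;
}

// Resample under a dense displacement field: source voxel coords =
// output voxel coords + disp (disp has dim (X,Y,Z,3), in voxels).
// [[Rcpp::export]]
NumericVector cpp_resample_disp(NumericVector vol, NumericVector disp,
                                int method, double fill) {
  IntegerVector vd = dims_of(vol);
  const int X = vd[0], Y = vd[1], Z = vd[2];
  const R_xlen_t XYZ = (R_xlen_t)X * Y * Z;
  NumericVector out(XYZ);
  out.attr("dim") = IntegerVector::create(X, Y, Z);
  const double* v = &vol[0];
  const double *dx = &disp[0], *dy = dx + XYZ, *dz = dy + XYZ;
  R_xlen_t o = 0;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x, ++o) {
        double sx = x + dx[o], sy = y + dy[o], sz = z + dz[o];
        out[o] = method == 1 ? sample_trilinear(v, X, Y, Z, sx, sy, sz, fill)
                             : sample_nn(v, X, Y, Z, sx, sy, sz, fill);
      }
  return out;
}

// For each row of A (n x 3, physical mm coordinates), the Euclidean
// distance to the nearest row of B. Brute force; used for surface
// distances on voxel boundary sets.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  std::vector<double> bx(m), by(m), bz(m);
  for (int j = 0; j < m; ++j) {
    bx[j] = B(j, 0); by[j] = B(j, 1); bz[j] = B(j, 2);
  }
  for (int i = 0; i < n; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double d0 = ax - bx[j], d1 = ay - by[j], d2 = az - bz[j];
      const double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// EvoNorm-S0 forward: y = gamma * x * sigmoid(v x) / sqrt(var_g + eps) + beta
// with the variance over each contiguous channel group and all spatial
// positions, per sample. Returns y plus the per-(group, sample) mean and
// std needed by the backward pass.
// [[Rcpp::export]]
List cpp_evonorm_forward(NumericVector x, NumericVector gamma,
                         NumericVector beta, NumericVector v, int groups,
                         double eps) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3],
            B = xd.size() > 4 ? xd[4] : 1;
  if (C % groups) stop("channels not divisible by norm groups");
  const R_xlen_t XYZ = (R_xlen_t)X * Y * Z;
  const int cg = C / groups;
  const R_xlen_t M = XYZ * cg;

  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericMatrix mu(groups, B), sd(groups, B);
  for (int b = 0; b < B; ++b) {
    const double* xb = &x[0] + (R_xlen_t)b * XYZ * C;
    double* yb = &y[0] + (R_xlen_t)b * XYZ * C;
    for (int g = 0; g < groups; ++g) {
      const double* xg = xb + (R_xlen_t)g * M;
      double s1 = 0, s2 = 0;
      for (R_xlen_t i = 0; i < M; ++i) { s1 += xg[i]; s2 += xg[i] * xg[i]; }
      const double m = s1 / M;
      double var = s2 / M - m * m;
      if (var < 0) var = 0;
      const double s = std::sqrt(var + eps);
      mu(g, b) = m;
      sd(g, b) = s;
      for (int cc = 0; cc < cg; ++cc) {
        const int c = g * cg + cc;
        const double ga = gamma[c], be = beta[c], vv = v[c];
        const double* xr = xg + (R_xlen_t)cc * XYZ;
        double* yr = yb + (R_xlen_t)c * XYZ;
        for (R_xlen_t i = 0; i < XYZ; ++i) {
          const double sig = 1.0 / (1.0 + std::exp(-vv * xr[i]));
          yr[i] = ga * xr[i] * sig / s + be;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["sd"] = sd);
}

// Backward of cpp_evonorm_forward. Recomputes the swish gate from x.
// [[Rcpp::export]]
List cpp_evonorm_backward(NumericVector g, NumericVector x,
                          NumericVector gamma, NumericVector v, int groups,
                          NumericMatrix mu, NumericMatrix sd) {
  IntegerVector xd = x.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3],
            B = xd.size() > 4 ? xd[4] : 1;
  const R_xlen_t XYZ = (R_xlen_t)X * Y * Z;
  const int cg = C / groups;
  const R_xlen_t M = XYZ * cg;

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector ggamma(C), gbeta(C), gv(C);

  for (int b = 0; b < B; ++b) {
    const double* xb = &x[0] + (R_xlen_t)b * XYZ * C;
    const double* gb = &g[0] + (R_xlen_t)b * XYZ * C;
    double* gxb = &gx[0] + (R_xlen_t)b * XYZ * C;
    for (int gr = 0; gr < groups; ++gr) {
      const double s = sd(gr, b), m = mu(gr, b);
      const double inv_s = 1.0 / s;
      // pass 1: T = sum over group of g * gamma * n, plus per-channel sums
      double T = 0;
      for (int cc = 0; cc < cg; ++cc) {
        const int c = gr * cg + cc;
        const double ga = gamma[c], vv = v[c];
        const double* xr = xb + (R_xlen_t)c * XYZ;
        const double* grow = gb + (R_xlen_t)c * XYZ;
        double sg = 0, sb = 0, sv = 0;
        for (R_xlen_t i = 0; i < XYZ; ++i) {
          const double sig = 1.0 / (1.0 + std::exp(-vv * xr[i]));
          const double n = xr[i] * sig;
          const double gi = grow[i];
          sg += gi * n;
          sb += gi;
          sv += gi * xr[i] * xr[i] * sig * (1.0 - sig);
          T += gi * ga * n;
        }
        ggamma[c] += sg * inv_s;
        gbeta[c] += sb;
        gv[c] += sv * ga * inv_s;
      }
      const double k = T / (M * s * s * s);
      for (int cc = 0; cc < cg; ++cc) {
        const int c = gr * cg + cc;
        const double ga = gamma[c], vv = v[c];
        const double* xr = xb + (R_xlen_t)c * XYZ;
        const double* grow = gb + (R_xlen_t)c * XYZ;
        double* gxr = gxb + (R_xlen_t)c * XYZ;
        for (R_xlen_t i = 0; i < XYZ; ++i) {
          const double sig = 1.0 / (1.0 + std::exp(-vv * xr[i]));
          const double dndx = sig * (1.0 + vv * xr[i] * (1.0 - sig));
          gxr[i] = ga * dndx * grow[i] * inv_s - (xr[i] - m) * k;
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta, _["gv"] = gv);
}

// Per-voxel softmax over the channel axis of (X,Y,Z,N,B) logits.
// [[Rcpp::export]]
NumericVector cpp_softmax_channels(NumericVector logits) {
  IntegerVector d = logits.attr("dim");
  const int X = d[0], Y = d[1], Z = d[2], N = d[3],
            B = d.size() > 4 ? d[4] : 1;
  const R_xlen_t XYZ = (R_xlen_t)X * Y * Z;
  NumericVector out(logits.size());
  out.attr("dim") = d;
  std::vector<double> row(N);
  for (int b = 0; b < B; ++b) {
    const double* lb = &logits[0] + (R_xlen_t)b * XYZ * N;
    double* ob = &out[0] + (R_xlen_t)b * XYZ * N;
    for (R_xlen_t v = 0; v < XYZ; ++v) {
      double mx = -1e300;
      for (int c = 0; c < N; ++c) {
        row[c] = lb[v + (R_xlen_t)c * XYZ];
        if (row[c] > mx) mx = row[c];
      }
      double s = 0;
      for (int c = 0; c < N; ++c) { row[c] = std::exp(row[c] - mx); s += row[c]; }
      for (int c = 0; c < N; ++c) ob[v + (R_xlen_t)c * XYZ] = row[c] / s;
    }
  }
  return out;
}

// Fused per-voxel softmax + mean cross-entropy. target: (X,Y,Z,B) 0-based
// integer class ids. Returns the scalar loss and d(loss)/d(logits).
// [[Rcpp::export]]
List cpp_softmax_ce(NumericVector logits, IntegerVector target) {
  IntegerVector d = logits.attr("dim");
  const int X = d[0], Y = d[1], Z = d[2], N = d[3],
            B = d.size() > 4 ? d[4] : 1;
  const R_xlen_t XYZ = (R_xlen_t)X * Y * Z;
  const double nvox = (double)XYZ * B;
  NumericVector grad(logits.size());
  grad.attr("dim") = d;
  std::vector<double> row(N);
  double loss = 0;
  for (int b = 0; b < B; ++b) {
    const double* lb = &logits[0] + (R_xlen_t)b * XYZ * N;
    double* gb = &grad[0] + (R_xlen_t)b * XYZ * N;
    const int* tb = &target[0] + (R_xlen_t)b * XYZ;
    for (R_xlen_t v = 0; v < XYZ; ++v) {
      const int t = tb[v];
      if (t < 0 || t >= N) stop("target label id outside [0, N)");
      double mx = -1e300;
      for (int c = 0; c < N; ++c) {
        row[c] = lb[v + (R_xlen_t)c * XYZ];
        if (row[c] > mx) mx = row[c];
      }
      double s = 0;
      for (int c = 0; c < N; ++c) { row[c] = std::exp(row[c] - mx); s += row[c]; }
      loss -= std::log(row[t] / s);
      for (int c = 0; c < N; ++c) {
        double p = row[c] / s;
        gb[v + (R_xlen_t)c * XYZ] = (p - (c == t ? 1.0 : 0.0)) / nvox;
      }
    }
  }
  return List::create(_["loss"] = loss / nvox, _["grad"] = grad);
}
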