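#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dense 3D kernels shared by the registration stack. Arrays follow R's
// column-major layout: volumes are (X,Y,Z), multi-channel stacks and vector
// fields are (X,Y,Z,C) with displacement components in voxel units along the
// array axes. All voxel indices are 0-based internally.

static inline R_xlen_t id3(int x, int y, int z, int X, int Y) {
  return (R_xlen_t)x + (R_xlen_t)X * ((R_xlen_t)y + (R_xlen_t)Y * (R_xlen_t)z);
}

static void get_dims4(const NumericVector& a, int& X, int& Y, int& Z, int& C) {
  IntegerVector d = a.attr("dim");
  if (d.size() == 3) {
    X = d[0]; Y = d[1]; Z = d[2]; C = 1;
  } else if (d.size() == 4) {
    X = d[0]; Y = d[1]; Z = d[2]; C = d[3];
  } else {
    stop("expected a 3D or 4D array");
  }
}

// ---------------------------------------------------------------------------
// Trilinear warp: out(x) = src(x + u(x)). boundary: 0 = zero-fill outside,
// 1 = clamp sample coordinates to the grid (used for field self-composition).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_warp_linear(NumericVector src, NumericVector disp,
                              int boundary) {
  int X, Y, Z, C, dX, dY, dZ, dC;
  get_dims4(src, X, Y, Z, C);
  get_dims4(disp, dX, dY, dZ, dC);
  if (dX != X || dY != Y || dZ != Z || dC != 3)
    stop("displacement field dimensions must be (X,Y,Z,3) matching the image");
  R_xlen_t n = (R_xlen_t)X * Y * Z;
  NumericVector out(n * C);
  out.attr("dim") = src.attr("dim");
  const double* s = src.begin();
  const double* u = disp.begin();
  double* o = out.begin();

  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        R_xlen_t i = id3(x, y, z, X, Y);
        double px = x + u[i], py = y + u[i + n], pz = z + u[i + 2 * n];
        if (boundary == 1) {
          px = px < 0 ? 0 : (px > X - 1 ? X - 1 : px);
          py = py < 0 ? 0 : (py > Y - 1 ? Y - 1 : py);
          pz = pz < 0 ? 0 : (pz > Z - 1 ? Z - 1 : pz);
        }
        int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
            z0 = (int)std::floor(pz);
        double fx = px - x0, fy = py - y0, fz = pz - z0;
        for (int c = 0; c < C; ++c) {
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                int cx = x0 + dx, cy = y0 + dy, cz = z0 + dz;
                double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                           (dz ? fz : 1 - fz);
                if (w == 0.0) continue;
                double v;
                if (cx < 0 || cy < 0 || cz < 0 || cx >= X || cy >= Y ||
                    cz >= Z) {
                  if (boundary == 1) {
                    int qx = cx < 0 ? 0 : (cx >= X ? X - 1 : cx);
                    int qy = cy < 0 ? 0 : (cy >= Y ? Y - 1 : cy);
                    int qz = cz < 0 ? 0 : (cz >= Z ? Z - 1 : cz);
                    v = s[id3(qx, qy, qz, X, Y) + (R_xlen_t)c * n];
                  } else {
                    v = 0.0;
                  }
                } else {
                  v = s[id3(cx, cy, cz, X, Y) + (R_xlen_t)c * n];
                }
                acc += w * v;
              }
          o[i + (R_xlen_t)c * n] = acc;
        }
      }
  return out;
}

// Backward pass of cpp_warp_linear: given d(loss)/d(out), accumulate
// gradients with respect to the source image and the displacement field.

// [[Rcpp::export]]
List cpp_warp_linear_bwd(NumericVector src, NumericVector disp,
                         NumericVector gout, int boundary) {
  int X, Y, Z, C, dX, dY, dZ, dC;
  get_dims4(src, X, Y, Z, C);
  get_dims4(disp, dX, dY, dZ, dC);
  R_xlen_t n = (R_xlen_t)X * Y * Z;
  NumericVector gsrc(n * C), gdisp(n * 3);
  gsrc.attr("dim") = src.attr("dim");
  gdisp.attr("dim") = disp.attr("dim");
  const double* s = src.begin();
  const double* u = disp.begin();
  const double* g = gout.begin();
  double* gs = gsrc.begin();
  double* gu = gdisp.begin();

  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        R_xlen_t i = id3(x, y, z, X, Y);
        double px = x + u[i], py = y + u[i + n], pz = z + u[i + 2 * n];
        bool clx = false, cly = false, clz = false;
        if (boundary == 1) {
          if (px < 0) { px = 0; clx = true; }
          if (px > X - 1) { px = X - 1; clx = true; }
          if (py < 0) { py = 0; cly = true; }
          if (py > Y - 1) { py = Y - 1; cly = true; }
          if (pz < 0) { pz = 0; clz = true; }
          if (pz > Z - 1) { pz = Z - 1; clz = true; }
        }
        int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
            z0 = (int)std::floor(pz);
        double fx = px - x0, fy = py - y0, fz = pz - z0;
        double gpx = 0.0, gpy = 0.0, gpz = 0.0;
        for (int c = 0; c < C; ++c) {
          double gc = g[i + (R_xlen_t)c * n];
          if (gc == 0.0) continue;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                int cx = x0 + dx, cy = y0 + dy, cz = z0 + dz;
                double wx = dx ? fx : 1 - fx;
                double wy = dy ? fy : 1 - fy;
                double wz = dz ? fz : 1 - fz;
                double sx = dx ? 1.0 : -1.0;
                double sy = dy ? 1.0 : -1.0;
                double sz = dz ? 1.0 : -1.0;
                bool inside = !(cx < 0 || cy < 0 || cz < 0 || cx >= X ||
                                cy >= Y || cz >= Z);
                double v = 0.0;
                R_xlen_t ic = 0;
                if (inside) {
                  ic = id3(cx, cy, cz, X, Y) + (R_xlen_t)c * n;
                  v = s[ic];
                } else if (boundary == 1) {
                  int qx = cx < 0 ? 0 : (cx >= X ? X - 1 : cx);
                  int qy = cy < 0 ? 0 : (cy >= Y ? Y - 1 : cy);
                  int qz = cz < 0 ? 0 : (cz >= Z ? Z - 1 : cz);
                  ic = id3(qx, qy, qz, X, Y) + (R_xlen_t)c * n;
                  v = s[ic];
                  inside = true; // clamped corner still receives gradient
                }
                double w = wx * wy * wz;
                if (inside && w != 0.0) gs[ic] += gc * w;
                gpx += gc * v * sx * wy * wz;
                gpy += gc * v * wx * sy * wz;
                gpz += gc * v * wx * wy * sz;
              }
        }
        gu[i] = clx ? 0.0 : gpx;
        gu[i + n] = cly ? 0.0 : gpy;
        gu[i + 2 * n] = clz ? 0.0 : gpz;
      }
  return List::create(_["gsrc"] = gsrc, _["gdisp"] = gdisp);
}

// [[Rcpp::export]]
NumericVector cpp_warp_nearest(NumericVector src, NumericVector disp) {
  int X, Y, Z, C, dX, dY, dZ, dC;
  get_dims4(src, X, Y, Z, C);
  get_dims4(disp, dX, dY, dZ, dC);
  R_xlen_t n = (R_xlen_t)X * Y * Z;
  NumericVector out(n * C);
  out.attr("dim") = src.attr("dim");
  const double* s = src.begin();
  const double* u = disp.begin();
  double* o = out.begin();
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        R_xlen_t i = id3(x, y, z, X, Y);
        int cx = (int)std::lround(x + u[i]);
        int cy = (int)std::lround(y + u[i + n]);
        int cz = (int)std::lround(z + u[i + 2 * n]);
        bool inside = !(cx < 0 || cy < 0 || cz < 0 || cx >= X || cy >= Y ||
                        cz >= Z);
        for (int c = 0; c < C; ++c)
          o[i + (R_xlen_t)c * n] =
              inside ? s[id3(cx, cy, cz, X, Y) + (R_xlen_t)c * n] : 0.0;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Grid-to-grid resampling for axis-aligned grids. The continuous source index
// along axis a of target voxel i is off[a] + sc[a] * i.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector tdim,
                           NumericVector off, NumericVector sc, int nearest,
                           int clamp) {
  int X, Y, Z, C;
  get_dims4(src, X, Y, Z, C);
  if (C != 1) stop("cpp_resample expects a single-channel volume");
  int TX = tdim[0], TY = tdim[1], TZ = tdim[2];
  NumericVector out((R_xlen_t)TX * TY * TZ);
  out.attr("dim") = IntegerVector::create(TX, TY, TZ);
  const double* s = src.begin();
  double* o = out.begin();
  for (int z = 0; z < TZ; ++z)
    for (int y = 0; y < TY; ++y)
      for (int x = 0; x < TX; ++x) {
        double px = off[0] + sc[0] * x;
        double py = off[1] + sc[1] * y;
        double pz = off[2] + sc[2] * z;
        if (clamp) {
          px = px < 0 ? 0 : (px > X - 1 ? X - 1 : px);
          py = py < 0 ? 0 : (py > Y - 1 ? Y - 1 : py);
          pz = pz < 0 ? 0 : (pz > Z - 1 ? Z - 1 : pz);
        }
        R_xlen_t i = id3(x, y, z, TX, TY);
        if (nearest) {
          int cx = (int)std::lround(px), cy = (int)std::lround(py),
              cz = (int)std::lround(pz);
          o[i] = (cx < 0 || cy < 0 || cz < 0 || cx >= X || cy >= Y || cz >= Z)
                     ? 0.0
                     : s[id3(cx, cy, cz, X, Y)];
        } else {
          int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
              z0 = (int)std::floor(pz);
          double fx = px - x0, fy = py - y0, fz = pz - z0;
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                int cx = x0 + dx, cy = y0 + dy, cz = z0 + dz;
                double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                           (dz ? fz : 1 - fz);
                if (w == 0.0 || cx < 0 || cy < 0 || cz < 0 || cx >= X ||
                    cy >= Y || cz >= Z)
                  continue;
                acc += w * s[id3(cx, cy, cz, X, Y)];
              }
          o[i] = acc;
        }
      }
  return out;
}

// ---------------------------------------------------------------------------
// 3D convolution, stride 1, same zero padding, odd kernel size.
// x: (X,Y,Z,Cin), w: (K,K,K,Cin,Cout), b: (Cout).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv3d(NumericVector x, NumericVector w, NumericVector b) {
  int X, Y, Z, Cin;
  get_dims4(x, X, Y, Z, Cin);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5) stop("weights must be a 5D array");
  int K = wd[0], Co = wd[4];
  if (wd[1] != K || wd[2] != K || wd[3] != Cin || K % 2 == 0)
    stop("weight dims must be (K,K,K,Cin,Cout) with odd K");
  int H = K / 2;
  R_xlen_t n = (R_xlen_t)X * Y * Z;
  NumericVector out(n * Co);
  out.attr("dim") = IntegerVector::create(X, Y, Z, Co);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* op = out.begin();

  for (int co = 0; co < Co; ++co) {
    double bv = b[co];
    double* oc = op + (R_xlen_t)co * n;
    for (R_xlen_t i = 0; i < n; ++i) oc[i] = bv;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + (R_xlen_t)ci * n;
      for (int kz = 0; kz < K; ++kz)
        for (int ky = 0; ky < K; ++ky)
          for (int kx = 0; kx < K; ++kx) {
            double wv = wp[kx + K * (ky + K * (kz + K * (ci + (R_xlen_t)Cin * co)))];
            if (wv == 0.0) continue;
            int dx = kx - H, dy = ky - H, dz = kz - H;
            int xs = dx < 0 ? -dx : 0, xe = dx > 0 ? X - dx : X;
            int ys = dy < 0 ? -dy : 0, ye = dy > 0 ? Y - dy : Y;
            int zs = dz < 0 ? -dz : 0, ze = dz > 0 ? Z - dz : Z;
            for (int z = zs; z < ze; ++z)
              for (int y = ys; y < ye; ++y) {
                double* orow = oc + id3(xs, y, z, X, Y);
                const double* xrow = xc + id3(xs + dx, y + dy, z + dz, X, Y);
                int len = xe - xs;
                for (int t = 0; t < len; ++t) orow[t] += wv * xrow[t];
              }
          }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gout) {
  int X, Y, Z, Cin;
  get_dims4(x, X, Y, Z, Cin);
  IntegerVector wd = w.attr("dim");
  int K = wd[0], Co = wd[4];
  int H = K / 2;
  R_xlen_t n = (R_xlen_t)X * Y * Z;
  NumericVector gx(n * Cin), gw((R_xlen_t)K * K * K * Cin * Co), gb(Co);
  gx.attr("dim") = x.attr("dim");
  gw.attr("dim") = w.attr("dim");
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = gout.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();

  for (int co = 0; co < Co; ++co) {
    const double* gc = gp + (R_xlen_t)co * n;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) acc += gc[i];
    gb[co] = acc;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + (R_xlen_t)ci * n;
      double* gxc = gxp + (R_xlen_t)ci * n;
      for (int kz = 0; kz < K; ++kz)
        for (int ky = 0; ky < K; ++ky)
          for (int kx = 0; kx < K; ++kx) {
            R_xlen_t wi =
                kx + K * (ky + K * (kz + K * (ci + (R_xlen_t)Cin * co)));
            double wv = wp[wi];
            int dx = kx - H, dy = ky - H, dz = kz - H;
            int xs = dx < 0 ? -dx : 0, xe = dx > 0 ? X - dx : X;
            int ys = dy < 0 ? -dy : 0, ye = dy > 0 ? Y - dy : Y;
            int zs = dz < 0 ? -dz : 0, ze = dz > 0 ? Z - dz : Z;
            double wacc = 0.0;
            for (int z = zs; z < ze; ++z)
              for (int y = ys; y < ye; ++y) {
                const double* grow = gc + id3(xs, y, z, X, Y);
                const double* xrow = xc + id3(xs + dx, y + dy, z + dz, X, Y);
                double* gxrow = gxc + id3(xs + dx, y + dy, z + dz, X, Y);
                int len = xe - xs;
                for (int t = 0; t < len; ++t) {
                  wacc += grow[t] * xrow[t];
                  gxrow[t] += wv * grow[t];
                }
              }
            gwp[wi] += wacc;
          }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// 2x average pooling / nearest upsampling (encoder-decoder resolution ladder).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_avgpool2(NumericVector x) {
  int X, Y, Z, C;
  get_dims4(x, X, Y, Z, C);
  if (X % 2 || Y % 2 || Z % 2) stop("avgpool2 needs even dimensions");
  int OX = X / 2, OY = Y / 2, OZ = Z / 2;
  R_xlen_t n = (R_xlen_t)X * Y * Z, m = (R_xlen_t)OX * OY * OZ;
  NumericVector out(m * C);
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < OZ; ++z)
      for (int y = 0; y < OY; ++y)
        for (int x0 = 0; x0 < OX; ++x0) {
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx)
                acc += xp[id3(2 * x0 + dx, 2 * y + dy, 2 * z + dz, X, Y) +
                          (R_xlen_t)c * n];
          op[id3(x0, y, z, OX, OY) + (R_xlen_t)c * m] = acc / 8.0;
        }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bwd(NumericVector g, IntegerVector xdim) {
  int OX, OY, OZ, C;
  get_dims4(g, OX, OY, OZ, C);
  int X = xdim[0], Y = xdim[1], Z = xdim[2];
  R_xlen_t n = (R_xlen_t)X * Y * Z, m = (R_xlen_t)OX * OY * OZ;
  NumericVector out(n * C);
  out.attr("dim") = IntegerVector::create(X, Y, Z, C);
  const double* gp = g.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < OZ; ++z)
      for (int y = 0; y < OY; ++y)
        for (int x0 = 0; x0 < OX; ++x0) {
          double gv =
              gp[id3(x0, y, z, OX, OY) + (R_xlen_t)c * m] / 8.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx)
                op[id3(2 * x0 + dx, 2 * y + dy, 2 * z + dz, X, Y) +
                   (R_xlen_t)c * n] = gv;
        }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_nearest(NumericVector x) {
  int X, Y, Z, C;
  get_dims4(x, X, Y, Z, C);
  int OX = 2 * X, OY = 2 * Y, OZ = 2 * Z;
  R_xlen_t n = (R_xlen_t)X * Y * Z, m = (R_xlen_t)OX * OY * OZ;
  NumericVector out(m * C);
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, C);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < OZ; ++z)
      for (int y = 0; y < OY; ++y)
        for (int x0 = 0; x0 < OX; ++x0)
          op[id3(x0, y, z, OX, OY) + (R_xlen_t)c * m] =
              xp[id3(x0 / 2, y / 2, z / 2, X, Y) + (R_xlen_t)c * n];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_nearest_bwd(NumericVector g) {
  int OX, OY, OZ, C;
  get_dims4(g, OX, OY, OZ, C);
  int X = OX / 2, Y = OY / 2, Z = OZ / 2;
  R_xlen_t n = (R_xlen_t)X * Y * Z, m = (R_xlen_t)OX * OY * OZ;
  NumericVector out(n * C);
  out.attr("dim") = IntegerVector::create(X, Y, Z, C);
  const double* gp = g.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < OZ; ++z)
      for (int y = 0; y < OY; ++y)
        for (int x0 = 0; x0 < OX; ++x0)
          op[id3(x0 / 2, y / 2, z / 2, X, Y) + (R_xlen_t)c * n] +=
              gp[id3(x0, y, z, OX, OY) + (R_xlen_t)c * m];
  return out;
}

// ---------------------------------------------------------------------------
// Sliding-window box sum (window 2r+1, zero padded) — LNCC building block.
// ---------------------------------------------------------------------------

static void boxsum_axis(const double* in, double* out, int X, int Y, int Z,
                        int axis, int r) {
  int dims[3] = {X, Y, Z};
  R_xlen_t strides[3] = {1, (R_xlen_t)X, (R_xlen_t)X * Y};
  int L = dims[axis];
  R_xlen_t sa = strides[axis];
  int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  std::vector<double> cs(L + 1);
  for (int j = 0; j < dims[a2]; ++j)
    for (int i = 0; i < dims[a1]; ++i) {
      R_xlen_t base = (R_xlen_t)i * strides[a1] + (R_xlen_t)j * strides[a2];
      cs[0] = 0.0;
      for (int t = 0; t < L; ++t) cs[t + 1] = cs[t] + in[base + sa * t];
      for (int t = 0; t < L; ++t) {
        int lo = t - r < 0 ? 0 : t - r;
        int hi = t + r + 1 > L ? L : t + r + 1;
        out[base + sa * t] = cs[hi] - cs[lo];
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_boxsum(NumericVector x, int r) {
  int X, Y, Z, C;
  get_dims4(x, X, Y, Z, C);
  if (C != 1) stop("boxsum expects a 3D array");
  R_xlen_t n = (R_xlen_t)X * Y * Z;
  NumericVector tmp(n), out(n);
  out.attr("dim") = x.attr("dim");
  boxsum_axis(x.begin(), out.begin(), X, Y, Z, 0, r);
  std::copy(out.begin(), out.end(), tmp.begin());
  boxsum_axis(tmp.begin(), out.begin(), X, Y, Z, 1, r);
  std::copy(out.begin(), out.end(), tmp.begin());
  boxsum_axis(tmp.begin(), out.begin(), X, Y, Z, 2, r);
  return out;
}

// ---------------------------------------------------------------------------
// Separable correlation with a symmetric 1D kernel, edge-renormalized so a
// constant input stays constant (Gaussian smoothing of phantom fields).
// ---------------------------------------------------------------------------

static void sepconv_axis(const double* in, double* out, int X, int Y, int Z,
                         int axis, const std::vector<double>& k) {
  int dims[3] = {X, Y, Z};
  R_xlen_t strides[3] = {1, (R_xlen_t)X, (R_xlen_t)X * Y};
  int L = dims[axis];
  R_xlen_t sa = strides[axis];
  int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  int r = ((int)k.size() - 1) / 2;
  for (int j = 0; j < dims[a2]; ++j)
    for (int i = 0; i < dims[a1]; ++i) {
      R_xlen_t base = (R_xlen_t)i * strides[a1] + (R_xlen_t)j * strides[a2];
      for (int t = 0; t < L; ++t) {
        double acc = 0.0, wsum = 0.0;
        int lo = t - r < 0 ? -t : -r;
        int hi = t + r >= L ? L - 1 - t : r;
        for (int d = lo; d <= hi; ++d) {
          double w = k[d + r];
          acc += w * in[base + sa * (t + d)];
          wsum += w;
        }
        out[base + sa * t] = acc / wsum;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector x, double sigma) {
  int X, Y, Z, C;
  get_dims4(x, X, Y, Z, C);
  if (C != 1) stop("gauss smooth expects a 3D array");
  if (sigma <= 0) return clone(x);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  for (int d = -r; d <= r; ++d) k[d + r] = std::exp(-0.5 * d * d / (sigma * sigma));
  R_xlen_t n = (R_xlen_t)X * Y * Z;
  NumericVector tmp(n), out(n);
  out.attr("dim") = x.attr("dim");
  sepconv_axis(x.begin(), out.begin(), X, Y, Z, 0, k);
  std::copy(out.begin(), out.end(), tmp.begin());
  sepconv_axis(tmp.begin(), out.begin(), X, Y, Z, 1, k);
  std::copy(out.begin(), out.end(), tmp.begin());
  sepconv_axis(tmp.begin(), out.begin(), X, Y, Z, 2, k);
  return out;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
// anisotropic spacing in mm. Input: 1 where the feature set lies.
// ---------------------------------------------------------------------------

static void edt_1d(std::vector<double>& f, std::vector<double>& d, double s,
                   int L) {
  std::vector<int> v(L);
  std::vector<double> z(L + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < L; ++q) {
    if (f[q] == std::numeric_limits<double>::infinity()) continue;
    double qs = q * s;
    while (true) {
      int p = v[k];
      if (f[p] == std::numeric_limits<double>::infinity()) {
        // only happens before any finite parabola was added
        v[k] = q;
        break;
      }
      double ps = p * s;
      double inter = ((f[q] + qs * qs) - (f[p] + ps * ps)) / (2 * qs - 2 * ps);
      if (inter <= z[k]) {
        --k;
        continue;
      }
      ++k;
      v[k] = q;
      z[k] = inter;
      z[k + 1] = std::numeric_limits<double>::infinity();
      break;
    }
  }
  int j = 0;
  for (int q = 0; q < L; ++q) {
    double qs = q * s;
    while (z[j + 1] < qs) ++j;
    int p = v[j];
    double ps = p * s;
    d[q] = f[p] == std::numeric_limits<double>::infinity()
               ? std::numeric_limits<double>::infinity()
               : (qs - ps) * (qs - ps) + f[p];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(NumericVector mask, NumericVector spacing) {
  int X, Y, Z, C;
  get_dims4(mask, X, Y, Z, C);
  if (C != 1) stop("edt expects a 3D array");
  R_xlen_t n = (R_xlen_t)X * Y * Z;
  NumericVector out(n);
  out.attr("dim") = mask.attr("dim");
  double* o = out.begin();
  const double* m = mask.begin();
  double inf = std::numeric_limits<double>::infinity();
  for (R_xlen_t i = 0; i < n; ++i) o[i] = m[i] != 0.0 ? 0.0 : inf;
  int dims[3] = {X, Y, Z};
  R_xlen_t strides[3] = {1, (R_xlen_t)X, (R_xlen_t)X * Y};
  for (int axis = 0; axis < 3; ++axis) {
    int L = dims[axis];
    R_xlen_t sa = strides[axis];
    int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
    std::vector<double> f(L), d(L);
    for (int j = 0; j < dims[a2]; ++j)
      for (int i = 0; i < dims[a1]; ++i) {
        R_xlen_t base = (R_xlen_t)i * strides[a1] + (R_xlen_t)j * strides[a2];
        bool any = false;
        for (int t = 0; t < L; ++t) {
          f[t] = o[base + sa * t];
          if (f[t] != inf) any = true;
        }
        if (!any) continue;
        edt_1d(f, d, spacing[axis], L);
        for (int t = 0; t < L; ++t) o[base + sa * t] = d[t];
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// im2col / col2im for GEMM-based convolution (same zero padding, odd K).
// Column j of the (N, K^3*Cin) matrix corresponds to flattened (kx,ky,kz,ci)
// in R array order, so matrix(w, K^3*Cin, Cout) matches directly.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int K) {
  int X, Y, Z, Cin;
  get_dims4(x, X, Y, Z, Cin);
  int H = K / 2;
  R_xlen_t n = (R_xlen_t)X * Y * Z;
  NumericMatrix col(n, (R_xlen_t)K * K * K * Cin);
  const double* xp = x.begin();
  double* cp = col.begin();
  R_xlen_t j = 0;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = xp + (R_xlen_t)ci * n;
    for (int kz = 0; kz < K; ++kz)
      for (int ky = 0; ky < K; ++ky)
        for (int kx = 0; kx < K; ++kx, ++j) {
          double* cj = cp + j * n;
          int dx = kx - H, dy = ky - H, dz = kz - H;
          int xs = dx < 0 ? -dx : 0, xe = dx > 0 ? X - dx : X;
          int ys = dy < 0 ? -dy : 0, ye = dy > 0 ? Y - dy : Y;
          int zs = dz < 0 ? -dz : 0, ze = dz > 0 ? Z - dz : Z;
          for (int z = zs; z < ze; ++z)
            for (int y = ys; y < ye; ++y) {
              std::copy(xc + id3(xs + dx, y + dy, z + dz, X, Y),
                        xc + id3(xe + dx, y + dy, z + dz, X, Y),
                        cj + id3(xs, y, z, X, Y));
            }
        }
  }
  return col;
}

// scatter-add adjoint of im2col: g is (N, K^3*Cin), returns (X,Y,Z,Cin)
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix g, IntegerVector xdim, int K) {
  int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  int H = K / 2;
  R_xlen_t n = (R_xlen_t)X * Y * Z;
  NumericVector out(n * Cin);
  out.attr("dim") = xdim;
  const double* gp = g.begin();
  double* op = out.begin();
  R_xlen_t j = 0;
  for (int ci = 0; ci < Cin; ++ci) {
    double* oc = op + (R_xlen_t)ci * n;
    for (int kz = 0; kz < K; ++kz)
      for (int ky = 0; ky < K; ++ky)
        for (int kx = 0; kx < K; ++kx, ++j) {
          const double* gj = gp + j * n;
          int dx = kx - H, dy = ky - H, dz = kz - H;
          int xs = dx < 0 ? -dx : 0, xe = dx > 0 ? X - dx : X;
          int ys = dy < 0 ? -dy : 0, ye = dy > 0 ? Y - dy : Y;
          int zs = dz < 0 ? -dz : 0, ze = dz > 0 ? Z - dz : Z;
          for (int z = zs; z < ze; ++z)
            for (int y = ys; y < ye; ++y) {
              const double* gr = gj + id3(xs, y, z, X, Y);
              double* orow = oc + id3(xs + dx, y + dy, z + dz, X, Y);
              int len = xe - xs;
              for (int t = 0; t < len; ++t) orow[t] += gr[t];
            }
        }
  }
  return out;
}
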