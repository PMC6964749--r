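#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bilinear interpolation on a regular grid. Rows index y, columns index x;
// value(i, j) sits at x = x0 + j*dx, y = y0 + i*dy. Returns NA outside.
static inline double bilerp(const NumericMatrix &v, double x0, double y0,
                            double dx, double dy, double x, double y) {
  double fx = (x - x0) / dx, fy = (y - y0) / dy;
  int nr = v.nrow(), nc = v.ncol();
  if (fx < 0 || fy < 0 || fx > nc - 1 || fy > nr - 1) return NA_REAL;
  int j0 = (int)std::floor(fx), i0 = (int)std::floor(fy);
  if (j0 >= nc - 1) j0 = nc - 2;
  if (i0 >= nr - 1) i0 = nr - 2;
  if (nc == 1) j0 = 0;
  if (nr == 1) i0 = 0;
  double tx = fx - j0, ty = fy - i0;
  if (nc == 1) tx = 0;
  if (nr == 1) ty = 0;
  double v00 = v(i0, j0);
  double v01 = (nc > 1) ? v(i0, j0 + 1) : v00;
  double v10 = (nr > 1) ? v(i0 + 1, j0) : v00;
  double v11 = (nr > 1 && nc > 1) ? v(i0 + 1, j0 + 1) : v00;
  return v00 * (1 - tx) * (1 - ty) + v01 * tx * (1 - ty) +
         v10 * (1 - tx) * ty + v11 * tx * ty;
}

// Gamma-index minimization for a set of reference points against an
// evaluated dose grid. Offsets must be sorted by ascending distance so the
// search can stop once the distance term alone exceeds the running minimum.
// dd_abs is the per-point absolute dose-difference criterion in Gy.
// [[Rcpp::export]]
NumericVector cpp_gamma_search(NumericVector ref_x, NumericVector ref_y,
                               NumericVector ref_dose, NumericVector dd_abs,
                               NumericMatrix eval, double ex0, double ey0,
                               double edx, double edy,
                               NumericVector off_x, NumericVector off_y,
                               NumericVector off_d, double dta, double cap) {
  int n = ref_x.size(), m = off_x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best2 = cap * cap;
    double x = ref_x[i], y = ref_y[i], d = ref_dose[i], dd = dd_abs[i];
    for (int k = 0; k < m; ++k) {
      double dist2 = (off_d[k] / dta) * (off_d[k] / dta);
      if (dist2 >= best2) break;
      double ev = bilerp(eval, ex0, ey0, edx, edy, x + off_x[k], y + off_y[k]);
      if (ISNA(ev)) continue;
      double delta = (ev - d) / dd;
      double g2 = dist2 + delta * delta;
      if (g2 < best2) best2 = g2;
    }
    out[i] = std::sqrt(best2);
  }
  return out;
}

// 1D squared Euclidean distance transform (lower-envelope algorithm),
// sample spacing s. f holds squared distances; result overwrites d.
static void dt1d(std::vector<double> &f, std::vector<double> &d, double s) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double sx;
    while (true) {
      int p = v[k];
      sx = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (sx <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sx;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = s2 * (q - p) * (q - p) + f[p];
  }
}

// Euclidean distance (mm) from every voxel to the nearest TRUE voxel of a
// 3D mask, with anisotropic spacing. Inf where the mask is empty.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  // large finite stand-in for +Inf keeps the envelope intersections finite
  const double BIG = 1e20;
  std::vector<double> f(n);
  for (long i = 0; i < n; ++i) f[i] = mask[i] ? 0.0 : BIG;
  // pass along x (fastest index)
  {
    std::vector<double> line(nx), out(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        long base = (long)z * nx * ny + (long)y * nx;
        for (int x = 0; x < nx; ++x) line[x] = f[base + x];
        dt1d(line, out, spacing[0]);
        for (int x = 0; x < nx; ++x) f[base + x] = out[x];
      }
  }
  // pass along y
  {
    std::vector<double> line(ny), out(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        long base = (long)z * nx * ny + x;
        for (int y = 0; y < ny; ++y) line[y] = f[base + (long)y * nx];
        dt1d(line, out, spacing[1]);
        for (int y = 0; y < ny; ++y) f[base + (long)y * nx] = out[y];
      }
  }
  // pass along z
  {
    std::vector<double> line(nz), out(nz);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        long base = (long)y * nx + x;
        for (int z = 0; z < nz; ++z) line[z] = f[base + (long)z * nx * ny];
        dt1d(line, out, spacing[2]);
        for (int z = 0; z < nz; ++z) f[base + (long)z * nx * ny] = out[z];
      }
  }
  NumericVector res(n);
  for (long i = 0; i < n; ++i) {
    double d = std::sqrt(f[i]);
    res[i] = (d >= 1e9) ? R_PosInf : d;
  }
  return res;
}
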