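#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Voxel grids are column-major (x fastest), 0-based internally; voxel center
// of index (i,j,k) is origin + spacing * (i,j,k). All physical units mm.

static inline long long lidx(int i, int j, int k, int nx, int ny) {
  return (long long)i + (long long)nx * ((long long)j + (long long)ny * k);
}

struct Vec3 { double x, y, z; };
static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
static inline double norm3(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// Rasterize swept rectangular cross-sections along polyline centerlines.
// half_u: half thickness along the radial direction (from the cylinder
// axis, assumed to be the z axis through x=y=0 of physical coordinates);
// half_v: half width along the binormal. Marks voxels whose center lies
// inside the sweep of any polyline piece.
// [[Rcpp::export]]
IntegerVector cpp_voxelize(IntegerVector dims, double spacing,
                           NumericVector origin, List polylines,
                           double half_u, double half_v) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  const double pad = std::sqrt(half_u * half_u + half_v * half_v) +
                     0.5 * spacing;
  for (int pl = 0; pl < polylines.size(); ++pl) {
    NumericMatrix P = polylines[pl];
    for (int r = 0; r + 1 < P.nrow(); ++r) {
      Vec3 p = {P(r, 0), P(r, 1), P(r, 2)};
      Vec3 q = {P(r + 1, 0), P(r + 1, 1), P(r + 1, 2)};
      Vec3 d = sub(q, p);
      double dd = dot(d, d);
      if (dd <= 0) continue;
      double lox = std::min(p.x, q.x) - pad, hix = std::max(p.x, q.x) + pad;
      double loy = std::min(p.y, q.y) - pad, hiy = std::max(p.y, q.y) + pad;
      double loz = std::min(p.z, q.z) - pad, hiz = std::max(p.z, q.z) + pad;
      int i0 = std::max(0, (int)std::ceil((lox - origin[0]) / spacing));
      int i1 = std::min(nx - 1, (int)std::floor((hix - origin[0]) / spacing));
      int j0 = std::max(0, (int)std::ceil((loy - origin[1]) / spacing));
      int j1 = std::min(ny - 1, (int)std::floor((hiy - origin[1]) / spacing));
      int k0 = std::max(0, (int)std::ceil((loz - origin[2]) / spacing));
      int k1 = std::min(nz - 1, (int)std::floor((hiz - origin[2]) / spacing));
      for (int k = k0; k <= k1; ++k) {
        double zc = origin[2] + spacing * k;
        for (int j = j0; j <= j1; ++j) {
          double yc = origin[1] + spacing * j;
          for (int i = i0; i <= i1; ++i) {
            double xc = origin[0] + spacing * i;
            Vec3 x = {xc, yc, zc};
            double s = dot(sub(x, p), d) / dd;
            if (s < 0.0 || s > 1.0) continue;
            Vec3 c = {p.x + s * d.x, p.y + s * d.y, p.z + s * d.z};
            Vec3 off = sub(x, c);
            Vec3 dhat = {d.x / std::sqrt(dd), d.y / std::sqrt(dd),
                         d.z / std::sqrt(dd)};
            // radial direction at the closest centerline point
            double rxy = std::sqrt(c.x * c.x + c.y * c.y);
            Vec3 u;
            if (rxy > 1e-9) u = {c.x / rxy, c.y / rxy, 0.0};
            else u = {1.0, 0.0, 0.0};
            // orthonormalize u against the tangent
            double ud = dot(u, dhat);
            Vec3 up = {u.x - ud * dhat.x, u.y - ud * dhat.y,
                       u.z - ud * dhat.z};
            double nup = norm3(up);
            if (nup < 1e-12) { up = {1.0, 0.0, 0.0}; nup = 1.0; }
            up = {up.x / nup, up.y / nup, up.z / nup};
            Vec3 v = cross(dhat, up);
            double a = std::fabs(dot(off, up));
            double b = std::fabs(dot(off, v));
            if (a <= half_u && b <= half_v) {
              out[lidx(i, j, k, nx, ny)] = 1;
            }
          }
        }
      }
    }
  }
  return out;
}

// Analytic depth below the swept-solid surface: for every voxel center
// inside the sweep of some polyline piece, the maximum over covering pieces
// of min(half_u - |a|, half_v - |b|) (mm); -1 outside. Continuum-accurate
// isotropic erosion: voxels with depth <= d are exactly those removed by
// shrinking the cross-section by d per face.
// [[Rcpp::export]]
NumericVector cpp_voxelize_depth(IntegerVector dims, double spacing,
                                 NumericVector origin, List polylines,
                                 double half_u, double half_v) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz, -1.0);
  const double pad = std::sqrt(half_u * half_u + half_v * half_v) +
                     0.5 * spacing;
  for (int pl = 0; pl < polylines.size(); ++pl) {
    NumericMatrix P = polylines[pl];
    for (int r = 0; r + 1 < P.nrow(); ++r) {
      Vec3 p = {P(r, 0), P(r, 1), P(r, 2)};
      Vec3 q = {P(r + 1, 0), P(r + 1, 1), P(r + 1, 2)};
      Vec3 d = sub(q, p);
      double dd = dot(d, d);
      if (dd <= 0) continue;
      double lox = std::min(p.x, q.x) - pad, hix = std::max(p.x, q.x) + pad;
      double loy = std::min(p.y, q.y) - pad, hiy = std::max(p.y, q.y) + pad;
      double loz = std::min(p.z, q.z) - pad, hiz = std::max(p.z, q.z) + pad;
      int i0 = std::max(0, (int)std::ceil((lox - origin[0]) / spacing));
      int i1 = std::min(nx - 1, (int)std::floor((hix - origin[0]) / spacing));
      int j0 = std::max(0, (int)std::ceil((loy - origin[1]) / spacing));
      int j1 = std::min(ny - 1, (int)std::floor((hiy - origin[1]) / spacing));
      int k0 = std::max(0, (int)std::ceil((loz - origin[2]) / spacing));
      int k1 = std::min(nz - 1, (int)std::floor((hiz - origin[2]) / spacing));
      for (int k = k0; k <= k1; ++k) {
        double zc = origin[2] + spacing * k;
        for (int j = j0; j <= j1; ++j) {
          double yc = origin[1] + spacing * j;
          for (int i = i0; i <= i1; ++i) {
            double xc = origin[0] + spacing * i;
            Vec3 x = {xc, yc, zc};
            double s = dot(sub(x, p), d) / dd;
            if (s < 0.0 || s > 1.0) continue;
            Vec3 c = {p.x + s * d.x, p.y + s * d.y, p.z + s * d.z};
            Vec3 off = sub(x, c);
            Vec3 dhat = {d.x / std::sqrt(dd), d.y / std::sqrt(dd),
                         d.z / std::sqrt(dd)};
            double rxy = std::sqrt(c.x * c.x + c.y * c.y);
            Vec3 u;
            if (rxy > 1e-9) u = {c.x / rxy, c.y / rxy, 0.0};
            else u = {1.0, 0.0, 0.0};
            double ud = dot(u, dhat);
            Vec3 up = {u.x - ud * dhat.x, u.y - ud * dhat.y,
                       u.z - ud * dhat.z};
            double nup = norm3(up);
            if (nup < 1e-12) { up = {1.0, 0.0, 0.0}; nup = 1.0; }
            up = {up.x / nup, up.y / nup, up.z / nup};
            Vec3 v = cross(dhat, up);
            double a = std::fabs(dot(off, up));
            double b = std::fabs(dot(off, v));
            if (a <= half_u && b <= half_v) {
              double depth = std::min(half_u - a, half_v - b);
              R_xlen_t t = lidx(i, j, k, nx, ny);
              if (depth > out[t]) out[t] = depth;
            }
          }
        }
      }
    }
  }
  return out;
}

// Linear (1-based) indices of voxels whose center lies within `radius` of a
// polyline — the capture tube used for per-segment continuity checks.
// [[Rcpp::export]]
IntegerVector cpp_near_polyline(IntegerVector dims, double spacing,
                                NumericVector origin, NumericMatrix P,
                                double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<char> hit((size_t)nx * ny * nz, 0);
  const double pad = radius + 0.5 * spacing;
  const double r2 = radius * radius;
  for (int r = 0; r + 1 < P.nrow(); ++r) {
    Vec3 p = {P(r, 0), P(r, 1), P(r, 2)};
    Vec3 q = {P(r + 1, 0), P(r + 1, 1), P(r + 1, 2)};
    Vec3 d = sub(q, p);
    double dd = dot(d, d);
    double lox = std::min(p.x, q.x) - pad, hix = std::max(p.x, q.x) + pad;
    double loy = std::min(p.y, q.y) - pad, hiy = std::max(p.y, q.y) + pad;
    double loz = std::min(p.z, q.z) - pad, hiz = std::max(p.z, q.z) + pad;
    int i0 = std::max(0, (int)std::ceil((lox - origin[0]) / spacing));
    int i1 = std::min(nx - 1, (int)std::floor((hix - origin[0]) / spacing));
    int j0 = std::max(0, (int)std::ceil((loy - origin[1]) / spacing));
    int j1 = std::min(ny - 1, (int)std::floor((hiy - origin[1]) / spacing));
    int k0 = std::max(0, (int)std::ceil((loz - origin[2]) / spacing));
    int k1 = std::min(nz - 1, (int)std::floor((hiz - origin[2]) / spacing));
    for (int k = k0; k <= k1; ++k) {
      double zc = origin[2] + spacing * k;
      for (int j = j0; j <= j1; ++j) {
        double yc = origin[1] + spacing * j;
        for (int i = i0; i <= i1; ++i) {
          double xc = origin[0] + spacing * i;
          Vec3 x = {xc, yc, zc};
          double s = dd > 0 ? dot(sub(x, p), d) / dd : 0.0;
          if (s < 0.0) s = 0.0;
          if (s > 1.0) s = 1.0;
          Vec3 c = {p.x + s * d.x, p.y + s * d.y, p.z + s * d.z};
          Vec3 off = sub(x, c);
          if (dot(off, off) <= r2) hit[lidx(i, j, k, nx, ny)] = 1;
        }
      }
    }
  }
  std::vector<int> idx;
  for (size_t t = 0; t < hit.size(); ++t) {
    if (hit[t]) idx.push_back((int)(t + 1));
  }
  return wrap(idx);
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int kk = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * q) - (f[v[kk]] + v[kk] * v[kk])) /
               (2.0 * q - 2.0 * v[kk]);
    while (s <= z[kk]) {
      --kk;
      s = ((f[q] + q * q) - (f[v[kk]] + v[kk] * v[kk])) /
          (2.0 * q - 2.0 * v[kk]);
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = std::numeric_limits<double>::infinity();
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    d[q] = (q - v[kk]) * (double)(q - v[kk]) + f[v[kk]];
  }
}

// Squared Euclidean distance (voxel units) from every voxel to the nearest
// voxel where mask == 0. Used for isotropic surface erosion.
// [[Rcpp::export]]
NumericVector cpp_sqdist_to_zero(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e18;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector D(n);
  for (R_xlen_t t = 0; t < n; ++t) D[t] = mask[t] ? INF : 0.0;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = D[lidx(i, j, k, nx, ny)];
      dt1d(f, d, nx);
      for (int i = 0; i < nx; ++i) D[lidx(i, j, k, nx, ny)] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = D[lidx(i, j, k, nx, ny)];
      dt1d(f, d, ny);
      for (int j = 0; j < ny; ++j) D[lidx(i, j, k, nx, ny)] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = D[lidx(i, j, k, nx, ny)];
      dt1d(f, d, nz);
      for (int k = 0; k < nz; ++k) D[lidx(i, j, k, nx, ny)] = d[k];
    }
  return D;
}

// Connected-component labelling (iterative flood fill). connectivity is 6
// or 26 in 3D; on a single-slice volume 26 degenerates to 8-connectivity.
// Labels start at 1; background (mask == 0) stays 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int connectivity = 26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<long long> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) > 1)
          continue;
        offs.push_back(lidx(dx, dy, dz, nx, ny));
      }
  std::vector<long long> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      long long cur = stack.back();
      stack.pop_back();
      int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / ((long long)nx * ny);
      for (size_t m = 0; m < offs.size(); ++m) {
        // recompute neighbor coordinates to avoid wrap-around
        long long nb = cur + offs[m];
        if (nb < 0 || nb >= (long long)n) continue;
        int ni = nb % nx, nj = (nb / nx) % ny, nk = nb / ((long long)nx * ny);
        if (std::abs(ni - ci) > 1 || std::abs(nj - cj) > 1 ||
            std::abs(nk - ck) > 1)
          continue;
        if (mask[nb] && !lab[nb]) {
          lab[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Separable isotropic Gaussian blur, kernel truncated at 3 sigma and
// renormalized at the borders (reflecting nothing in: border handling is
// renormalization, adequate for phantoms padded with background).
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector img, IntegerVector dims,
                                double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) return clone(img);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double s2 = 2.0 * sigma * sigma, ksum = 0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-(double)t * t / s2);
    ksum += ker[t + rad];
  }
  for (int t = 0; t < 2 * rad + 1; ++t) ker[t] /= ksum;

  NumericVector a = clone(img), b(n);
  // pass along each axis in turn: a -> b, then swap
  for (int axis = 0; axis < 3; ++axis) {
    int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
    long long stride = axis == 0 ? 1 : (axis == 1 ? nx : (long long)nx * ny);
    int o1 = axis == 0 ? ny : nx;
    int o2 = axis == 2 ? ny : nz;
    long long st1 = axis == 0 ? nx : 1;
    long long st2 = axis == 2 ? nx : (long long)nx * ny;
    for (int c2 = 0; c2 < o2; ++c2) {
      for (int c1 = 0; c1 < o1; ++c1) {
        long long base = c1 * st1 + c2 * st2;
        for (int p = 0; p < len; ++p) {
          double acc = 0, wsum = 0;
          int lo = std::max(0, p - rad), hi = std::min(len - 1, p + rad);
          for (int q = lo; q <= hi; ++q) {
            double w = ker[q - p + rad];
            acc += w * a[base + (long long)q * stride];
            wsum += w;
          }
          b[base + (long long)p * stride] = acc / wsum;
        }
      }
    }
    std::swap(a, b);
  }
  return a;
}
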