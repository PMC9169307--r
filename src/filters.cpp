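#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 1D Gaussian convolution along one axis with reflecting boundary.
// The kernel is truncated at ceil(3*sigma) and renormalized to sum 1.
static void gauss_axis(std::vector<double>& src, std::vector<double>& dst,
                       const int n0, const int n1, const int n2,
                       const R_xlen_t s0, const R_xlen_t s1, const R_xlen_t s2,
                       double sigma) {
  if (sigma <= 0.0) { dst = src; return; }
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double ksum = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    ksum += k[i + r];
  }
  for (double& v : k) v /= ksum;
  for (int i2 = 0; i2 < n2; ++i2) {
    for (int i1 = 0; i1 < n1; ++i1) {
      const R_xlen_t base = s1 * i1 + s2 * i2;
      for (int i0 = 0; i0 < n0; ++i0) {
        double acc = 0.0;
        for (int d = -r; d <= r; ++d) {
          int j = i0 + d;
          if (j < 0) j = -j - 1;            // reflect
          if (j >= n0) j = 2 * n0 - j - 1;
          acc += k[d + r] * src[base + s0 * j];
        }
        dst[base + s0 * i0] = acc;
      }
    }
  }
}

// Separable 3D Gaussian blur; sigma per axis in voxels, order (y, x, z).
// dims = c(ny, nx, nz), column-major.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector img, IntegerVector dims,
                             double sigma_y, double sigma_x, double sigma_z) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  std::vector<double> a(img.begin(), img.end()), b(n);
  // along y: stride 1, outer loops over x (stride ny) and z (stride ny*nx)
  gauss_axis(a, b, ny, nx, nz, 1, ny, (R_xlen_t)ny * nx, sigma_y);
  // along x
  gauss_axis(b, a, nx, ny, nz, ny, 1, (R_xlen_t)ny * nx, sigma_x);
  // along z
  gauss_axis(a, b, nz, ny, nx, (R_xlen_t)ny * nx, 1, ny, sigma_z);
  return NumericVector(b.begin(), b.end());
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas) with grid spacing w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    const double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Anisotropic Euclidean distance transform of a binary mask: for each
// foreground voxel, the distance (in physical units) to the nearest
// background voxel center. The caller is expected to pad the mask with a
// one-voxel background shell if the image boundary should count as
// background. dims = c(ny, nx, nz); spacing = c(dy, dx, dz).
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const double dy = spacing[0], dx = spacing[1], dz = spacing[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  // large finite sentinel instead of infinity: keeps the parabola
  // intersection arithmetic NaN-free when whole runs are foreground
  const double BIG = 1e15;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? BIG : 0.0;

  std::vector<double> f, d;
  // along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = (R_xlen_t)ny * (x + (R_xlen_t)nx * z);
      for (int y = 0; y < ny; ++y) f[y] = g[base + y];
      dt1d(f, d, ny, dy);
      for (int y = 0; y < ny; ++y) g[base + y] = d[y];
    }
  // along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (R_xlen_t)y + (R_xlen_t)ny * nx * (R_xlen_t)z;
      for (int x = 0; x < nx; ++x) f[x] = g[base + (R_xlen_t)ny * x];
      dt1d(f, d, nx, dx);
      for (int x = 0; x < nx; ++x) g[base + (R_xlen_t)ny * x] = d[x];
    }
  // along z
  f.resize(nz); d.resize(nz);
  const R_xlen_t sz = (R_xlen_t)ny * nx;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (R_xlen_t)y + (R_xlen_t)ny * x;
      for (int z = 0; z < nz; ++z) f[z] = g[base + sz * z];
      dt1d(f, d, nz, dz);
      for (int z = 0; z < nz; ++z) g[base + sz * z] = d[z];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}
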