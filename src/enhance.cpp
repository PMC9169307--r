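#include <Rcpp.h>
using namespace Rcpp;

// Masked local-contrast enhancement: for every in-mask voxel x,
//   delta(x) = (1/s) * sum over neighbors y in the cubic window of radius s
//              (center excluded, in-bounds, in-mask) of (v_x - v_y).
// Out-of-mask voxels are set to 0 and never contribute as neighbors.
// Arrays are column-major with dims = c(ny, nx, nz).
// [[Rcpp::export]]
NumericVector cpp_enhance(NumericVector raw, IntegerVector mask,
                          IntegerVector dims, int s) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  NumericVector out(raw.size());
  const double inv_s = 1.0 / (double)s;
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        const R_xlen_t idx = (R_xlen_t)y + (R_xlen_t)ny * (x + (R_xlen_t)nx * z);
        if (!mask[idx]) { out[idx] = 0.0; continue; }
        const double vx = raw[idx];
        double acc = 0.0;
        const int z0 = std::max(z - s, 0), z1 = std::min(z + s, nz - 1);
        const int x0 = std::max(x - s, 0), x1 = std::min(x + s, nx - 1);
        const int y0 = std::max(y - s, 0), y1 = std::min(y + s, ny - 1);
        for (int zz = z0; zz <= z1; ++zz) {
          for (int xx = x0; xx <= x1; ++xx) {
            const R_xlen_t base = (R_xlen_t)ny * (xx + (R_xlen_t)nx * zz);
            for (int yy = y0; yy <= y1; ++yy) {
              if (yy == y && xx == x && zz == z) continue;
              const R_xlen_t j = (R_xlen_t)yy + base;
              if (!mask[j]) continue;
              acc += vx - raw[j];
            }
          }
        }
        out[idx] = acc * inv_s;
      }
    }
  }
  return out;
}
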