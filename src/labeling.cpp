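#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling by iterative flood fill.
// Labels are assigned 1..n in first-encounter order of a raster scan with
// z slowest, then y, then x. connectivity is 6 (faces), 18 (faces+edges)
// or 26 (full cube). dims = c(ny, nx, nz), column-major.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector bin, IntegerVector dims,
                                   int connectivity) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  IntegerVector lab(bin.size());

  // neighbor offsets for the requested connectivity
  std::vector<int> off_y, off_x, off_z;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        const int ord = std::abs(dz) + std::abs(dx) + std::abs(dy);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        off_y.push_back(dy); off_x.push_back(dx); off_z.push_back(dz);
      }
  const int n_off = (int)off_y.size();

  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t idx = (R_xlen_t)y + (R_xlen_t)ny * (x + (R_xlen_t)nx * z);
        if (!bin[idx] || lab[idx]) continue;
        ++next_label;
        lab[idx] = next_label;
        stack.clear();
        stack.push_back(idx);
        while (!stack.empty()) {
          const R_xlen_t cur = stack.back();
          stack.pop_back();
          const int cy = (int)(cur % ny);
          const int cx = (int)((cur / ny) % nx);
          const int cz = (int)(cur / ((R_xlen_t)ny * nx));
          for (int k = 0; k < n_off; ++k) {
            const int yy = cy + off_y[k];
            const int xx = cx + off_x[k];
            const int zz = cz + off_z[k];
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
              continue;
            const R_xlen_t j = (R_xlen_t)yy + (R_xlen_t)ny * (xx + (R_xlen_t)nx * zz);
            if (bin[j] && !lab[j]) {
              lab[j] = next_label;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  lab.attr("n_objects") = next_label;
  return lab;
}
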