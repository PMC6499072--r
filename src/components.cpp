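#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling on a binary voxel grid.
// `mask` is a logical vector with dim (nz, ny, nx); nz == 1 gives the 2D case.
// connectivity: 8 (2D) / 26 (3D) when full == true, else 4 / 6.
// Labels are assigned in raster-scan order, so output is deterministic.

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   bool full) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  auto idx = [&](int z, int y, int x) -> R_xlen_t {
    return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
  };

  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx(z, y, x);
        if (!mask[i] || labels[i] != 0) continue;
        ++next_label;
        labels[i] = next_label;
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back();
          stack.pop_back();
          int cz = (int)(cur % nz);
          int cy = (int)((cur / nz) % ny);
          int cx = (int)(cur / ((R_xlen_t)nz * ny));
          for (int dz = -1; dz <= 1; ++dz) {
            for (int dy = -1; dy <= 1; ++dy) {
              for (int dx = -1; dx <= 1; ++dx) {
                if (dz == 0 && dy == 0 && dx == 0) continue;
                int nsteps = std::abs(dz) + std::abs(dy) + std::abs(dx);
                if (!full && nsteps > 1) continue;
                int zz = cz + dz, yy = cy + dy, xx = cx + dx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                    xx < 0 || xx >= nx) continue;
                R_xlen_t j = idx(zz, yy, xx);
                if (mask[j] && labels[j] == 0) {
                  labels[j] = next_label;
                  stack.push_back(j);
                }
              }
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
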