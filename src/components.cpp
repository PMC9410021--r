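#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Connected-component labeling of a binary voxel grid (2D or 3D).
// Components are numbered 1..n in order of their first (lexicographically
// smallest, column-major) voxel, which fixes the tie-break contract used by
// the largest-component post-processing.
//
// connectivity: 1 = face neighbours (4 in 2D, 6 in 3D)
//               3 = full neighbourhood (8 in 2D, 26 in 3D)
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nd = dims.size();
  if (nd != 2 && nd != 3) stop("mask must be 2D or 3D");
  const int nx = dims[0], ny = dims[1], nz = (nd == 3) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");

  // neighbour offsets
  std::vector<std::array<int,3>> offs;
  const int r = 1;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (nd == 2 && dz != 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 1 && manh > 1) continue;
        offs.push_back({dx, dy, dz});
      }

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (auto &o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
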