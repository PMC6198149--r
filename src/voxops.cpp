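#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 6-connected (or per-section 4-connected when dz == 1 slices are passed)
// component labeling of a logical 3D array. Labels are 1..k in order of
// first-encountered voxel (column-major scan order); background is 0.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / sz);
      R_xlen_t nb;
      if (x > 0)      { nb = v - sx; if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); } }
      if (x < nx - 1) { nb = v + sx; if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); } }
      if (y > 0)      { nb = v - sy; if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); } }
      if (y < ny - 1) { nb = v + sy; if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); } }
      if (z > 0)      { nb = v - sz; if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); } }
      if (z < nz - 1) { nb = v + sz; if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); } }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
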