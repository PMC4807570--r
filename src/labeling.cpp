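#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connectivity connected-component labelling on a 3D mask stored
// column-major with dims (nz, ny, nx). Iterative BFS; labels start at 1.
// [[Rcpp::export]]
IntegerVector label3d_26(IntegerVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (mask[start] == 0 || lab[start] != 0) continue;
    ++next;
    lab[start] = next;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      int z = cur % nz;
      int y = (cur / nz) % ny;
      int x = cur / ((R_xlen_t)nz * ny);
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            R_xlen_t nb = (R_xlen_t)(xx) * nz * ny + (R_xlen_t)yy * nz + zz;
            if (mask[nb] != 0 && lab[nb] == 0) {
              lab[nb] = next;
              queue.push_back(nb);
            }
          }
        }
      }
    }
  }
  return lab;
}
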