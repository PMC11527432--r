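#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling, 6-connectivity, iterative BFS.
// mask: logical array of dim (nx, ny, nz); returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    queue.clear();
    queue.push_back(s);
    lab[s] = next;
    while (!queue.empty()) {
      R_xlen_t v = queue.back();
      queue.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && !lab[w]) {
          lab[w] = next;
          queue.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
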