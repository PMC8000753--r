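#include <Rcpp.h>
#include <vector>

// Label connected components of a 3-D logical mask (column-major, dims nx,ny,nz).
// connectivity: 6 (face) or 26 (face+edge+corner). Labels start at 1; background 0.
// Iterative BFS so deep components cannot overflow the call stack.
// [[Rcpp::export]]
Rcpp::IntegerVector label3d_cpp(Rcpp::LogicalVector mask,
                                Rcpp::IntegerVector dims,
                                int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) Rcpp::stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) Rcpp::stop("connectivity must be 6 or 26");

  std::vector<int> off_x, off_y, off_z;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        off_x.push_back(dx); off_y.push_back(dy); off_z.push_back(dz);
      }
  const int nn = (int)off_x.size();

  Rcpp::IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int k = 0; k < nn; ++k) {
        int xx = x + off_x[k], yy = y + off_y[k], zz = z + off_z[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("n_components") = current;
  return labels;
}
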