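#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labeling of a 3D mask (non-zero = foreground) by
// iterative flood fill. Labels are assigned in raster-scan order of the
// first voxel of each component, so output is deterministic for a given
// mask.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
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
      int k = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v - (R_xlen_t)k * nx * ny);
      int j = rem / nx;
      int i = rem - j * nx;
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            if (di == 0 && dj == 0 && dk == 0) continue;
            R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[w] && labels[w] == 0) {
              labels[w] = current;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  labels.attr("n_components") = current;
  return labels;
}
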