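#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling over an integer raster: two pixels are in the
// same component iff they hold the same nonzero value and are 4- (or 8-)
// adjacent.  Components are numbered in row-major raster-scan order of their
// first pixel, which is the package-wide canonical label order.

// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(IntegerMatrix x, int connectivity) {
  int nr = x.nrow(), nc = x.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix out(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;

  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = connectivity == 4 ? dr4 : dr8;
  const int* dc = connectivity == 4 ? dc4 : dc8;
  int nd = connectivity;

  // raster scan: row-major (rows outer) so first-pixel order is canonical
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      int val = x(r, c);
      if (val == 0 || out(r, c) != 0) continue;
      next++;
      out(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int d = 0; d < nd; d++) {
          int r2 = rr + dr[d], c2 = cc + dc[d];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (x(r2, c2) == val && out(r2, c2) == 0) {
            out(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return out;
}
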