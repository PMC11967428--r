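#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher)
// specialised to nearest-instance label assignment.  Distances are integer
// squared pixel offsets held in doubles, so cross-label comparisons are
// exact and the documented tie rule (lowest label id wins) is bit-stable.

static const double DT_INF = 1e20;

// 1D squared distance transform of a sampled function f, n samples.
static void dt1d(const std::vector<double>& f, int n,
                 std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
List nearest_site_cpp(IntegerMatrix labels, LogicalMatrix support) {
  int nr = labels.nrow(), nc = labels.ncol();
  if (support.nrow() != nr || support.ncol() != nc)
    stop("labels and support must have identical dimensions");
  int K = 0;
  for (int i = 0; i < nr * nc; i++) if (labels[i] > K) K = labels[i];

  std::vector<double> best(nr * nc, DT_INF);
  IntegerMatrix owner(nr, nc);
  if (K > 0) {
    std::vector<double> g(nr * nc);           // per-column row distances
    std::vector<double> f(std::max(nr, nc)), drow(std::max(nr, nc));
    std::vector<int> v(std::max(nr, nc) + 1);
    std::vector<double> z(std::max(nr, nc) + 2);

    for (int k = 1; k <= K; k++) {
      bool any = false;
      // phase 1: nearest site row-distance within each column
      for (int c = 0; c < nc; c++) {
        double d = DT_INF;
        for (int r = 0; r < nr; r++) {
          if (labels(r, c) == k) { d = 0; any = true; }
          else if (d < DT_INF) d += 1;
          g[(size_t)c * nr + r] = d;
        }
        d = DT_INF;
        for (int r = nr - 1; r >= 0; r--) {
          if (labels(r, c) == k) d = 0;
          else if (d < DT_INF) d += 1;
          double& gv = g[(size_t)c * nr + r];
          if (d < gv) gv = d;
        }
      }
      if (!any) continue;
      // phase 2: 1D squared DT along each row over column offsets
      for (int r = 0; r < nr; r++) {
        for (int c = 0; c < nc; c++) {
          double gv = g[(size_t)c * nr + r];
          f[c] = (gv >= DT_INF) ? DT_INF : gv * gv;
        }
        dt1d(f, nc, drow, v, z);
        for (int c = 0; c < nc; c++) {
          size_t idx = (size_t)c * nr + r;
          if (drow[c] < best[idx]) {   // strict: earlier (lower) label keeps ties
            best[idx] = drow[c];
            owner[idx] = k;
          }
        }
      }
    }
  }
  NumericMatrix dist2(nr, nc);
  for (int i = 0; i < nr * nc; i++) {
    if (!support[i]) { owner[i] = 0; dist2[i] = NA_REAL; }
    else dist2[i] = best[i] >= DT_INF ? NA_REAL : best[i];
  }
  return List::create(_["owner"] = owner, _["dist2"] = dist2);
}
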