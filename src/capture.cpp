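#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Assign each synapse to one cell chosen uniformly among cells within
// `radius` (Euclidean sheet distance). Returns 0-based cell indices,
// -1 when no cell is in range. Uses a uniform spatial hash with bucket
// size = radius so each query touches a 3x3 neighbourhood. Draws come
// from the R RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector capture_assign_cpp(NumericVector sx, NumericVector sy,
                                 NumericVector cx, NumericVector cy,
                                 double radius) {
  const int ns = sx.size(), nc = cx.size();
  IntegerVector out(ns, -1);
  if (nc == 0 || ns == 0) return out;
  double xmin = cx[0], ymin = cy[0], xmax = cx[0], ymax = cy[0];
  for (int i = 1; i < nc; ++i) {
    xmin = std::min(xmin, cx[i]); xmax = std::max(xmax, cx[i]);
    ymin = std::min(ymin, cy[i]); ymax = std::max(ymax, cy[i]);
  }
  const double h = radius;
  const int nx = std::max(1, (int)std::floor((xmax - xmin) / h) + 1);
  const int ny = std::max(1, (int)std::floor((ymax - ymin) / h) + 1);
  std::vector<int> head((size_t)nx * ny, -1), nxt(nc, -1);
  for (int i = 0; i < nc; ++i) {
    int bx = std::min(nx - 1, std::max(0, (int)((cx[i] - xmin) / h)));
    int by = std::min(ny - 1, std::max(0, (int)((cy[i] - ymin) / h)));
    size_t b = (size_t)by * nx + bx;
    nxt[i] = head[b];
    head[b] = i;
  }
  const double r2 = radius * radius;
  std::vector<int> cand;
  RNGScope scope;
  for (int s = 0; s < ns; ++s) {
    cand.clear();
    int bx = (int)std::floor((sx[s] - xmin) / h);
    int by = (int)std::floor((sy[s] - ymin) / h);
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = by + dy;
      if (yy < 0 || yy >= ny) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = bx + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int i = head[(size_t)yy * nx + xx]; i >= 0; i = nxt[i]) {
          double ddx = cx[i] - sx[s], ddy = cy[i] - sy[s];
          if (ddx * ddx + ddy * ddy <= r2) cand.push_back(i);
        }
      }
    }
    if (!cand.empty()) {
      int k = (int)(unif_rand() * cand.size());
      if (k >= (int)cand.size()) k = cand.size() - 1;
      out[s] = cand[k];
    }
  }
  return out;
}
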