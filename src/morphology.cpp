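#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a binary raster by flood fill.
// connectivity: 4 or 8. Labels are contiguous positive integers in
// raster scan order of each component's first pixel; background = 0.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int n_off = (connectivity == 8) ? 8 : 4;
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next_label = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next_label;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next_label;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc_ = idx / nr;
        for (int k = 0; k < n_off; ++k) {
          int rr = cr + dr[k], ccc = cc_ + dc[k];
          if (rr < 0 || rr >= nr || ccc < 0 || ccc >= nc) continue;
          if (mask(rr, ccc) && lab(rr, ccc) == 0) {
            lab(rr, ccc) = next_label;
            stack.push_back(rr + ccc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Binary dilation with a disk structuring element of the given radius
// (pixels at Euclidean distance <= radius are set).
// [[Rcpp::export(name = ".binary_dilate")]]
LogicalMatrix binary_dilate(LogicalMatrix mask, double radius) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  if (radius < 0) stop("radius must be >= 0");
  const int ir = (int)std::floor(radius);
  std::vector<std::pair<int, int> > se;
  for (int dr = -ir; dr <= ir; ++dr)
    for (int dc = -ir; dc <= ir; ++dc)
      if ((double)dr * dr + (double)dc * dc <= radius * radius)
        se.push_back(std::make_pair(dr, dc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      for (size_t k = 0; k < se.size(); ++k) {
        int rr = r + se[k].first, ccc = c + se[k].second;
        if (rr >= 0 && rr < nr && ccc >= 0 && ccc < nc) out(rr, ccc) = true;
      }
    }
  }
  return out;
}
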