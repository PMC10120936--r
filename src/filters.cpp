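#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <vector>
using namespace Rcpp;

// Median filter with ImageJ-style radius: window is the (2r+1)x(2r+1)
// square, clipped at image borders (truncated neighbourhoods, no padding).
// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(NumericMatrix x, int radius) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int j = 0; j < nc; ++j) {
    int j0 = std::max(0, j - radius), j1 = std::min(nc - 1, j + radius);
    for (int i = 0; i < nr; ++i) {
      int i0 = std::max(0, i - radius), i1 = std::min(nr - 1, i + radius);
      buf.clear();
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii)
          buf.push_back(x(ii, jj));
      size_t n = buf.size();
      std::sort(buf.begin(), buf.end());
      // R's median: mean of the two central order statistics when n is even
      out(i, j) = (n % 2 == 1) ? buf[n / 2]
                               : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask (two-pass union-find).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);

  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int best = 0;
      // previously-visited 8-neighbours in column-major order
      int di[4] = {-1, -1, 0, 1};
      int dj[4] = {0, -1, -1, -1};
      for (int k = 0; k < 4; ++k) {
        int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        int l = lab(ii, jj);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        int nl = (int)parent.size();
        parent.push_back(nl);
        lab(i, j) = nl;
      } else {
        lab(i, j) = best;
      }
    }
  }
  // relabel consecutively
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        int r = find(lab(i, j));
        if (remap[r] == 0) remap[r] = ++next;
        lab(i, j) = remap[r];
      }
  return lab;
}
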