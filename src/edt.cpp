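#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

// 1-D squared Euclidean distance transform (Felzenszwalb & Huttenlocher).
// f: input costs (0 at sites, INF elsewhere); d: output; n: length.
static void edt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = (f[v[k]] == INF) ? INF : dq * dq + f[v[k]];
  }
}

// 2-D squared EDT on a (h x w) grid stored column-major; INF where no site.
static void edt2d(std::vector<double>& g, int h, int w) {
  std::vector<double> f(std::max(h, w)), d(std::max(h, w));
  // columns
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) f[r] = g[c * h + r];
    edt1d(f, d, h);
    for (int r = 0; r < h; ++r) g[c * h + r] = d[r];
  }
  // rows
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) f[c] = g[c * h + r];
    edt1d(f, d, w);
    for (int c = 0; c < w; ++c) g[c * h + r] = d[c];
  }
}

// Capped Euclidean distance-to-edge labels.
// For each pixel p inside region k, the distance (center-to-center) to the
// nearest pixel whose ID differs from k (background or another region),
// capped at d_max; 0 on background. Regions are processed on a bounding box
// padded by ceil(d_max)+1, which is exact because farther sites exceed the cap.
// [[Rcpp::export]]
NumericMatrix cpp_edge_distance(IntegerMatrix ids, double d_max) {
  const int H = ids.nrow(), W = ids.ncol();
  NumericMatrix out(H, W); // zero-initialized
  const double INF = std::numeric_limits<double>::infinity();

  // bounding boxes per positive id
  std::unordered_map<int, std::array<int, 4>> bbox; // rmin, rmax, cmin, cmax
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int k = ids(r, c);
      if (k <= 0) continue;
      auto it = bbox.find(k);
      if (it == bbox.end())
        bbox[k] = {r, r, c, c};
      else {
        auto& b = it->second;
        b[0] = std::min(b[0], r); b[1] = std::max(b[1], r);
        b[2] = std::min(b[2], c); b[3] = std::max(b[3], c);
      }
    }

  const int pad = (int)std::ceil(d_max) + 1;
  std::vector<int> keys;
  keys.reserve(bbox.size());
  for (auto& kv : bbox) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());

  std::vector<double> g;
  for (int k : keys) {
    auto& b = bbox[k];
    int r0 = std::max(0, b[0] - pad), r1 = std::min(H - 1, b[1] + pad);
    int c0 = std::max(0, b[2] - pad), c1 = std::min(W - 1, b[3] + pad);
    int h = r1 - r0 + 1, w = c1 - c0 + 1;
    g.assign((size_t)h * w, INF);
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r)
        if (ids(r, c) != k) g[(size_t)(c - c0) * h + (r - r0)] = 0.0;
    edt2d(g, h, w);
    for (int c = b[2]; c <= b[3]; ++c)
      for (int r = b[0]; r <= b[1]; ++r)
        if (ids(r, c) == k) {
          double d2 = g[(size_t)(c - c0) * h + (r - r0)];
          out(r, c) = (d2 == INF) ? d_max : std::min(d_max, std::sqrt(d2));
        }
  }
  return out;
}
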