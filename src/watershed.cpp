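#include <Rcpp.h>
#include <queue>
#include <vector>
#include <tuple>
#include <cstdint>

using namespace Rcpp;

// 8-connected component labeling of a boolean mask, labels assigned in
// row-major raster-scan order of each component's first pixel (1..K).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.emplace_back(r, c);
      lab(r, c) = next;
      while (!stack.empty()) {
        auto [pr, pc] = stack.back();
        stack.pop_back();
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int nr = pr + dr, nc = pc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              stack.emplace_back(nr, nc);
            }
          }
      }
    }
  return lab;
}

struct QItem {
  double d;
  uint64_t order;
  int r, c, label;
};
struct QCmp {
  // max-heap on d; FIFO on insertion order among equal d (deterministic)
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.d != b.d) return a.d < b.d;
    return a.order > b.order;
  }
};

// Marker-based watershed of the foreground on an inverted height field -d:
// markers are 8-connected components of {d >= marker_level} within the
// foreground; flooding proceeds from high d downward, 8-connected, ties
// resolved by insertion order (markers enqueued in label order). Basins
// smaller than min_region_px are deleted; surviving labels are renumbered
// 1..K in row-major raster-scan order of each basin's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(LogicalMatrix fg, NumericMatrix dmap,
                            double marker_level, int min_region_px) {
  const int H = fg.nrow(), W = fg.ncol();
  LogicalMatrix seed(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      seed(r, c) = fg(r, c) && dmap(r, c) >= marker_level;
  IntegerMatrix lab = cpp_label_components(seed);

  std::priority_queue<QItem, std::vector<QItem>, QCmp> q;
  uint64_t order = 0;
  // enqueue marker pixels in label order, raster scan within label
  int nmark = 0;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) nmark = std::max(nmark, lab(r, c));
  if (nmark > 0) {
    std::vector<std::vector<std::pair<int, int>>> bylab(nmark + 1);
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c)
        if (lab(r, c) > 0) bylab[lab(r, c)].emplace_back(r, c);
    for (int k = 1; k <= nmark; ++k)
      for (auto& rc : bylab[k])
        q.push({dmap(rc.first, rc.second), order++, rc.first, rc.second, k});
  }

  while (!q.empty()) {
    QItem it = q.top();
    q.pop();
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        if (dr == 0 && dc == 0) continue;
        int nr = it.r + dr, nc = it.c + dc;
        if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
        if (fg(nr, nc) && lab(nr, nc) == 0) {
          lab(nr, nc) = it.label;
          q.push({dmap(nr, nc), order++, nr, nc, it.label});
        }
      }
  }

  // basin sizes
  std::vector<int> size(nmark + 1, 0);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (lab(r, c) > 0) ++size[lab(r, c)];

  // delete small basins, renumber survivors by raster order of first pixel
  std::vector<int> renum(nmark + 1, 0);
  int next = 0;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      int k = lab(r, c);
      if (k == 0) continue;
      if (size[k] < min_region_px) continue;
      if (renum[k] == 0) renum[k] = ++next;
    }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      lab(r, c) = renum[lab(r, c)];
  return lab;
}
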