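// Bottom-up multiresolution region merging and connected-component labelling.
// The merging criterion is the standard colour/shape heterogeneity increase:
//   f = w_color * sum_b (n_m s_m,b - n_1 s_1,b - n_2 s_2,b)
//     + (1 - w_color) * [ w_cmp * d(compactness) + (1-w_cmp) * d(smoothness) ]
// with compactness l/sqrt(n) and smoothness l/b (b = bounding-box perimeter),
// each weighted by object size. Merging is globally lowest-cost-first and
// stops when the cheapest fusion exceeds scale^2. Ties break on the lower
// (then higher) segment id so results are fully deterministic.

#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

namespace {

struct Seg {
  double n = 0;                    // pixel count
  std::vector<double> sum, sumsq;  // per-band accumulators
  double perim = 0;                // boundary length (pixel edges)
  int rmin = 0, rmax = 0, cmin = 0, cmax = 0;
  int version = 0;
  bool alive = false;
  std::unordered_map<int, double> nb;  // neighbour id -> shared edge length
};

struct Cand {
  double cost;
  int a, b, va, vb;
};
struct CandCmp {
  bool operator()(const Cand& x, const Cand& y) const {
    if (x.cost != y.cost) return x.cost > y.cost;
    int xlo = std::min(x.a, x.b), ylo = std::min(y.a, y.b);
    if (xlo != ylo) return xlo > ylo;
    return std::max(x.a, x.b) > std::max(y.a, y.b);
  }
};

double heterogeneity(const Seg& s, int B, double wColor, double wCmp) {
  double hcol = 0.0;
  for (int b = 0; b < B; ++b) {
    double mean = s.sum[b] / s.n;
    double var = s.sumsq[b] / s.n - mean * mean;
    if (var < 0) var = 0;
    hcol += s.n * std::sqrt(var);
  }
  double bbox = 2.0 * ((s.rmax - s.rmin + 1) + (s.cmax - s.cmin + 1));
  double cmp = s.n * (s.perim / std::sqrt(s.n));
  double smo = s.n * (s.perim / bbox);
  return wColor * hcol + (1.0 - wColor) * (wCmp * cmp + (1.0 - wCmp) * smo);
}

Seg merged(const Seg& a, const Seg& b, int B, double shared) {
  Seg m;
  m.n = a.n + b.n;
  m.sum.resize(B);
  m.sumsq.resize(B);
  for (int k = 0; k < B; ++k) {
    m.sum[k] = a.sum[k] + b.sum[k];
    m.sumsq[k] = a.sumsq[k] + b.sumsq[k];
  }
  m.perim = a.perim + b.perim - 2.0 * shared;
  m.rmin = std::min(a.rmin, b.rmin);
  m.rmax = std::max(a.rmax, b.rmax);
  m.cmin = std::min(a.cmin, b.cmin);
  m.cmax = std::max(a.cmax, b.cmax);
  return m;
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_segment_mr(NumericVector bands, int nrow, int ncol,
                             int nband, double scale, double w_color,
                             double w_compact, LogicalMatrix mask) {
  const int N = nrow * ncol;
  std::vector<Seg> segs(N + 1);
  std::vector<int> parent(N + 1);
  for (int i = 0; i <= N; ++i) parent[i] = i;

  auto px = [&](int r, int c) { return r + c * nrow; };
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      if (!mask(r, c)) continue;
      int id = px(r, c) + 1;
      Seg& s = segs[id];
      s.alive = true;
      s.n = 1;
      s.sum.resize(nband);
      s.sumsq.resize(nband);
      for (int b = 0; b < nband; ++b) {
        double v = bands[px(r, c) + (double)b * N];
        s.sum[b] = v;
        s.sumsq[b] = v * v;
      }
      s.perim = 4;
      s.rmin = s.rmax = r;
      s.cmin = s.cmax = c;
    }
  }
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      if (!mask(r, c)) continue;
      int id = px(r, c) + 1;
      if (r + 1 < nrow && mask(r + 1, c)) {
        int jd = px(r + 1, c) + 1;
        segs[id].nb[jd] += 1;
        segs[jd].nb[id] += 1;
      }
      if (c + 1 < ncol && mask(r, c + 1)) {
        int jd = px(r, c + 1) + 1;
        segs[id].nb[jd] += 1;
        segs[jd].nb[id] += 1;
      }
    }
  }

  const double thresh = scale * scale;
  std::priority_queue<Cand, std::vector<Cand>, CandCmp> heap;
  auto push_pair = [&](int a, int b) {
    if (a > b) std::swap(a, b);
    auto it = segs[a].nb.find(b);
    if (it == segs[a].nb.end()) return;
    Seg m = merged(segs[a], segs[b], nband, it->second);
    double cost = heterogeneity(m, nband, w_color, w_compact) -
                  heterogeneity(segs[a], nband, w_color, w_compact) -
                  heterogeneity(segs[b], nband, w_color, w_compact);
    heap.push({cost, a, b, segs[a].version, segs[b].version});
  };
  for (int id = 1; id <= N; ++id) {
    if (!segs[id].alive) continue;
    for (auto& kv : segs[id].nb)
      if (kv.first > id) push_pair(id, kv.first);
  }

  long iter = 0;
  while (!heap.empty()) {
    Cand c = heap.top();
    if (c.cost >= thresh) break;
    heap.pop();
    Seg& A = segs[c.a];
    Seg& B = segs[c.b];
    if (!A.alive || !B.alive || A.version != c.va || B.version != c.vb)
      continue;
    double shared = A.nb[c.b];
    Seg m = merged(A, B, nband, shared);
    m.alive = true;
    m.version = c.va + 1;
    m.nb = std::move(A.nb);
    m.nb.erase(c.b);
    for (auto& kv : B.nb) {
      if (kv.first == c.a) continue;
      m.nb[kv.first] += kv.second;
      segs[kv.first].nb.erase(c.b);
      segs[kv.first].nb[c.a] += kv.second;
    }
    B.alive = false;
    B.nb.clear();
    B.sum.clear();
    B.sumsq.clear();
    segs[c.a] = std::move(m);
    parent[c.b] = c.a;
    for (auto& kv : segs[c.a].nb) push_pair(c.a, kv.first);
    if ((++iter & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // path-compressing find over the merge-parent forest
  auto find = [&](int x) {
    int root = x;
    while (parent[root] != root) root = parent[root];
    while (parent[x] != root) {
      int nxt = parent[x];
      parent[x] = root;
      x = nxt;
    }
    return root;
  };

  IntegerMatrix out(nrow, ncol);
  std::unordered_map<int, int> relabel;
  int next = 0;
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      if (!mask(r, c)) {
        out(r, c) = 0;
        continue;
      }
      int root = find(px(r, c) + 1);
      auto it = relabel.find(root);
      if (it == relabel.end()) {
        relabel[root] = ++next;
        out(r, c) = next;
      } else {
        out(r, c) = it->second;
      }
    }
  }
  return out;
}

// 4-connected component labelling of a logical mask; labels assigned in
// column-major scan order (deterministic), 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int nrow = mask.nrow(), ncol = mask.ncol();
  IntegerMatrix lab(nrow, ncol);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  for (int c = 0; c < ncol; ++c) {
    for (int r = 0; r < nrow; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.push_back({r, c});
      lab(r, c) = next;
      while (!stack.empty()) {
        auto rc = stack.back();
        stack.pop_back();
        for (int k = 0; k < 4; ++k) {
          int r2 = rc.first + dr[k], c2 = rc.second + dc[k];
          if (r2 < 0 || r2 >= nrow || c2 < 0 || c2 >= ncol) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back({r2, c2});
          }
        }
      }
    }
  }
  return lab;
}
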