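#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Bottom-up pairwise region merging over a multiband image.
//
// Each valid pixel starts as its own object. A merge of neighbouring objects
// a,b is allowed while the weighted increase in heterogeneity stays below
// `scale`:
//   df = (1 - shape_wt) * dh_color + shape_wt * dh_shape
//   dh_color = sum_b [ n_m*sd_m,b - n_a*sd_a,b - n_b*sd_b,b ]
//   dh_shape = cmpct_wt * dh_compact + (1 - cmpct_wt) * dh_smooth
//   compact  = perimeter / sqrt(n),  smooth = perimeter / bbox_perimeter
// Merge order: scan objects by ascending id, each merges with its best-fitting
// neighbour (minimum df, ties to the lowest id) provided the fit is mutual.
// Deterministic by construction.

namespace {

struct Stats {
  double n = 0;
  std::vector<double> sum, sum2;
  double perim = 0;                       // exposed pixel edges
  int rmin = 0, rmax = 0, cmin = 0, cmax = 0;
};

int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

double obj_hetero(const Stats& s, double shape_wt, double cmpct_wt) {
  double h_color = 0;
  for (size_t b = 0; b < s.sum.size(); ++b) {
    double mu = s.sum[b] / s.n;
    double v = s.sum2[b] / s.n - mu * mu;
    if (v < 0) v = 0;
    h_color += std::sqrt(v);
  }
  double compact = s.perim / std::sqrt(s.n);
  double bbox = 2.0 * ((s.rmax - s.rmin + 1) + (s.cmax - s.cmin + 1));
  double smooth = s.perim / bbox;
  double h_shape = cmpct_wt * compact + (1 - cmpct_wt) * smooth;
  return (1 - shape_wt) * s.n * h_color + shape_wt * s.n * h_shape;
}

Stats merged_stats(const Stats& a, const Stats& b, double shared) {
  Stats m;
  m.n = a.n + b.n;
  m.sum.resize(a.sum.size());
  m.sum2.resize(a.sum.size());
  for (size_t k = 0; k < a.sum.size(); ++k) {
    m.sum[k] = a.sum[k] + b.sum[k];
    m.sum2[k] = a.sum2[k] + b.sum2[k];
  }
  m.perim = a.perim + b.perim - 2.0 * shared;
  m.rmin = std::min(a.rmin, b.rmin);
  m.rmax = std::max(a.rmax, b.rmax);
  m.cmin = std::min(a.cmin, b.cmin);
  m.cmax = std::max(a.cmax, b.cmax);
  return m;
}

double merge_cost(const Stats& a, const Stats& b, double shared,
                  double shape_wt, double cmpct_wt) {
  Stats m = merged_stats(a, b, shared);
  return obj_hetero(m, shape_wt, cmpct_wt) -
         obj_hetero(a, shape_wt, cmpct_wt) -
         obj_hetero(b, shape_wt, cmpct_wt);
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_segment(List bands, LogicalMatrix valid, double scale,
                          double shape_wt, double cmpct_wt) {
  int nr = valid.nrow(), nc = valid.ncol();
  int nb = bands.size();
  std::vector<NumericMatrix> B(nb);
  for (int b = 0; b < nb; ++b) B[b] = as<NumericMatrix>(bands[b]);

  int N = nr * nc;
  std::vector<int> parent(N);
  std::vector<Stats> st(N);
  // shared edge counts between current roots
  std::vector<std::unordered_map<int, double>> adj(N);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int id = r + c * nr;
      parent[id] = id;
      if (!valid(r, c)) continue;
      Stats& s = st[id];
      s.n = 1;
      s.sum.resize(nb);
      s.sum2.resize(nb);
      for (int b = 0; b < nb; ++b) {
        double v = B[b](r, c);
        s.sum[b] = v;
        s.sum2[b] = v * v;
      }
      s.perim = 4;
      s.rmin = s.rmax = r;
      s.cmin = s.cmax = c;
    }
  }
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!valid(r, c)) continue;
      int id = r + c * nr;
      if (r + 1 < nr && valid(r + 1, c)) {
        adj[id][id + 1] += 1;
        adj[id + 1][id] += 1;
      }
      if (c + 1 < nc && valid(r, c + 1)) {
        adj[id][id + nr] += 1;
        adj[id + nr][id] += 1;
      }
    }
  }

  auto best_neighbour = [&](int a, double& best_df) {
    best_df = R_PosInf;
    int best = -1;
    for (auto& kv : adj[a]) {
      double df = merge_cost(st[a], st[kv.first], kv.second, shape_wt, cmpct_wt);
      if (df < best_df || (df == best_df && (best < 0 || kv.first < best))) {
        best_df = df;
        best = kv.first;
      }
    }
    return best;
  };

  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 10000) {
    changed = false;
    for (int a = 0; a < N; ++a) {
      if (parent[a] != a || st[a].n == 0) continue;
      double df_a;
      int b = best_neighbour(a, df_a);
      if (b < 0 || !(df_a < scale)) continue;
      double df_b;
      int back = best_neighbour(b, df_b);
      if (back != a) continue;          // require mutual best fit
      // merge higher id into lower id
      int lo = std::min(a, b), hi = std::max(a, b);
      double shared = adj[lo][hi];
      st[lo] = merged_stats(st[lo], st[hi], shared);
      adj[lo].erase(hi);
      adj[hi].erase(lo);
      for (auto& kv : adj[hi]) {
        int x = kv.first;
        adj[lo][x] += kv.second;
        adj[x].erase(hi);
        adj[x][lo] += kv.second;
      }
      adj[hi].clear();
      st[hi] = Stats();
      parent[hi] = lo;
      changed = true;
    }
  }

  // compact labels in root-id order
  IntegerMatrix out(nr, nc);
  std::unordered_map<int, int> relabel;
  int next = 0;
  for (int id = 0; id < N; ++id)
    if (parent[id] == id && st[id].n > 0) relabel[id] = ++next;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int id = r + c * nr;
      if (!valid(r, c)) {
        out(r, c) = NA_INTEGER;
      } else {
        out(r, c) = relabel[find_root(parent, id)];
      }
    }
  return out;
}

// 4-connected components of equal integer values; NA cells get NA.
// [[Rcpp::export]]
IntegerMatrix cpp_components(IntegerMatrix grid) {
  int nr = grid.nrow(), nc = grid.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), NA_INTEGER);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (grid(r0, c0) == NA_INTEGER || lab(r0, c0) != NA_INTEGER) continue;
      int val = grid(r0, c0);
      ++next;
      stack.clear();
      stack.push_back({r0, c0});
      lab(r0, c0) = next;
      while (!stack.empty()) {
        auto rc = stack.back();
        stack.pop_back();
        int r = rc.first, c = rc.second;
        const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
        for (int k = 0; k < 4; ++k) {
          int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (grid(r2, c2) == NA_INTEGER || lab(r2, c2) != NA_INTEGER) continue;
          if (grid(r2, c2) != val) continue;
          lab(r2, c2) = next;
          stack.push_back({r2, c2});
        }
      }
    }
  }
  return lab;
}
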