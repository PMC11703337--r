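#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Left-right planarity test (de Fraysseix & Rosenstiehl criterion,
// Brandes' formulation). Decision version only: no embedding is produced.

namespace lr {

struct Interval {
  int low = -1, high = -1;
  bool empty() const { return low == -1 && high == -1; }
};

struct ConflictPair {
  Interval L, R;
};

class Planarity {
public:
  int n, m;
  std::vector<std::vector<std::pair<int,int>>> adj; // (neighbour, edge id)
  std::vector<int> esrc, etgt;
  std::vector<char> oriented;
  std::vector<int> height, parent_edge;
  std::vector<int> lowpt, lowpt2, nesting, ref_;
  std::vector<int> lowpt_edge, stack_bottom;
  std::vector<ConflictPair> S;
  std::vector<std::vector<int>> ordered;
  std::vector<int> roots;

  Planarity(int n_, const std::vector<std::pair<int,int>>& edges) : n(n_) {
    m = (int)edges.size();
    adj.assign(n, {});
    esrc.assign(m, -1); etgt.assign(m, -1);
    oriented.assign(m, 0);
    for (int e = 0; e < m; ++e) {
      adj[edges[e].first].push_back({edges[e].second, e});
      adj[edges[e].second].push_back({edges[e].first, e});
    }
    height.assign(n, -1);
    parent_edge.assign(n, -1);
    lowpt.assign(m, 0); lowpt2.assign(m, 0); nesting.assign(m, 0);
    ref_.assign(m, -1); lowpt_edge.assign(m, -1); stack_bottom.assign(m, -1);
  }

  void dfs1(int v0) {
    // iterative DFS to avoid deep recursion on large graphs
    std::vector<std::pair<int, size_t>> stack; // (vertex, adjacency index)
    stack.push_back({v0, 0});
    while (!stack.empty()) {
      int v = stack.back().first;
      size_t& idx = stack.back().second;
      if (idx < adj[v].size()) {
        int w = adj[v][idx].first, id = adj[v][idx].second;
        ++idx;
        if (oriented[id]) continue;
        oriented[id] = 1; esrc[id] = v; etgt[id] = w;
        lowpt[id] = height[v]; lowpt2[id] = height[v];
        if (height[w] == -1) { // tree edge
          parent_edge[w] = id;
          height[w] = height[v] + 1;
          stack.push_back({w, 0});
        } else {               // back edge
          lowpt[id] = height[w];
          finish_edge(v, id);
        }
      } else {
        stack.pop_back();
        int e = parent_edge[v];
        if (e != -1) finish_edge(esrc[e], e);
      }
    }
  }

  // update nesting depth of edge id out of v, fold into parent edge of v
  void finish_edge(int v, int id) {
    nesting[id] = 2 * lowpt[id];
    if (lowpt2[id] < height[v]) nesting[id] += 1; // chordal
    int e = parent_edge[v];
    if (e != -1) {
      if (lowpt[id] < lowpt[e]) {
        lowpt2[e] = std::min(lowpt[e], lowpt2[id]);
        lowpt[e] = lowpt[id];
      } else if (lowpt[id] > lowpt[e]) {
        lowpt2[e] = std::min(lowpt2[e], lowpt[id]);
      } else {
        lowpt2[e] = std::min(lowpt2[e], lowpt2[id]);
      }
    }
  }

  bool conflicting(const Interval& I, int b) const {
    return !I.empty() && lowpt[I.high] > lowpt[b];
  }

  int lowest(const ConflictPair& P) const {
    if (P.L.empty()) return lowpt[P.R.low];
    if (P.R.empty()) return lowpt[P.L.low];
    return std::min(lowpt[P.L.low], lowpt[P.R.low]);
  }

  bool add_constraints(int b, int e) {
    ConflictPair P;
    // merge return edges of b into P.R
    while ((int)S.size() > stack_bottom[b]) {
      ConflictPair Q = S.back(); S.pop_back();
      if (!Q.L.empty()) std::swap(Q.L, Q.R);
      if (!Q.L.empty()) return false; // not planar
      if (lowpt[Q.R.low] > lowpt[e]) { // merge intervals
        if (P.R.empty()) P.R.high = Q.R.high;
        else ref_[P.R.low] = Q.R.high;
        P.R.low = Q.R.low;
      } else { // align
        ref_[Q.R.low] = lowpt_edge[e];
      }
    }
    // merge conflicting return edges of previous siblings into P.L
    while (!S.empty() &&
           (conflicting(S.back().L, b) || conflicting(S.back().R, b))) {
      ConflictPair Q = S.back(); S.pop_back();
      if (conflicting(Q.R, b)) std::swap(Q.L, Q.R);
      if (conflicting(Q.R, b)) return false; // not planar
      // merge interval below lowpt(b) into P.R
      if (P.R.low != -1) ref_[P.R.low] = Q.R.high;
      if (Q.R.low != -1) P.R.low = Q.R.low;
      if (P.L.empty()) P.L.high = Q.L.high;
      else ref_[P.L.low] = Q.L.high;
      P.L.low = Q.L.low;
    }
    if (!(P.L.empty() && P.R.empty())) S.push_back(P);
    return true;
  }

  void trim_back_edges(int u) {
    // drop entire conflict pairs
    while (!S.empty() && lowest(S.back()) == height[u]) S.pop_back();
    if (!S.empty()) {
      ConflictPair P = S.back(); S.pop_back();
      // trim left interval
      while (P.L.high != -1 && etgt[P.L.high] == u) P.L.high = ref_[P.L.high];
      if (P.L.high == -1 && P.L.low != -1) {
        ref_[P.L.low] = P.R.low;
        P.L.low = -1;
      }
      // trim right interval
      while (P.R.high != -1 && etgt[P.R.high] == u) P.R.high = ref_[P.R.high];
      if (P.R.high == -1 && P.R.low != -1) {
        ref_[P.R.low] = P.L.low;
        P.R.low = -1;
      }
      S.push_back(P);
    }
  }

  bool dfs2(int v0) {
    std::vector<std::pair<int, size_t>> stack;
    stack.push_back({v0, 0});
    while (!stack.empty()) {
      int v = stack.back().first;
      size_t& idx = stack.back().second;
      int e = parent_edge[v];
      bool descended = false;
      while (idx < ordered[v].size()) {
        int id = ordered[v][idx];
        ++idx;
        int w = etgt[id];
        if (id == parent_edge[w]) { // tree edge: descend, resume later
          stack_bottom[id] = (int)S.size();
          stack.push_back({w, 0});
          descended = true;
          break;
        } else { // back edge
          stack_bottom[id] = (int)S.size();
          lowpt_edge[id] = id;
          ConflictPair Pn; Pn.R.low = id; Pn.R.high = id;
          S.push_back(Pn);
          if (lowpt[id] < height[v]) { // has return edge
            if (id == ordered[v][0]) lowpt_edge[e] = lowpt_edge[id];
            else if (!add_constraints(id, e)) return false;
          }
        }
      }
      if (descended) continue;
      stack.pop_back();
      if (e != -1) {
        int u = esrc[e];
        trim_back_edges(u);
        // resume the constraint integration for tree edge e at parent level
        if (lowpt[e] < height[u]) { // e has a return edge, so u is not a root
          if (e == ordered[u][0]) {
            lowpt_edge[parent_edge[u]] = lowpt_edge[e];
          } else if (!add_constraints(e, parent_edge[u])) {
            return false;
          }
        }
      }
    }
    return true;
  }

  bool run() {
    if (n <= 4 || m <= 8) {
      // any simple graph with <= 4 vertices or <= 8 edges is planar
      if (n <= 4) return true;
    }
    if (m > 3 * n - 6) return false; // Euler bound
    for (int v = 0; v < n; ++v)
      if (height[v] == -1) {
        height[v] = 0;
        roots.push_back(v);
        dfs1(v);
      }
    ordered.assign(n, {});
    for (int e = 0; e < m; ++e)
      if (esrc[e] >= 0) ordered[esrc[e]].push_back(e);
    for (int v = 0; v < n; ++v)
      std::stable_sort(ordered[v].begin(), ordered[v].end(),
                       [&](int a, int b) { return nesting[a] < nesting[b]; });
    for (int r : roots)
      if (!dfs2(r)) return false;
    return true;
  }
};

} // namespace lr

static bool planar_impl(int n, const std::vector<std::pair<int,int>>& edges) {
  lr::Planarity P(n, edges);
  return P.run();
}

// [[Rcpp::export]]
bool lr_is_planar(int n, IntegerMatrix edges) {
  std::vector<std::pair<int,int>> ev;
  ev.reserve(edges.nrow());
  for (int i = 0; i < edges.nrow(); ++i)
    ev.push_back({edges(i, 0) - 1, edges(i, 1) - 1});
  return planar_impl(n, ev);
}

// Greedy planar maximally filtered graph: candidates must arrive pre-sorted
// (decreasing weight with deterministic tie-break). Returns logical vector of
// accepted candidates; stops once 3(n-2) edges are present.
// [[Rcpp::export]]
LogicalVector pmfg_accept(int n, IntegerVector src, IntegerVector tgt) {
  int nc = src.size();
  LogicalVector keep(nc, false);
  int target = (n <= 2) ? (n - 1) : 3 * (n - 2);
  std::vector<std::pair<int,int>> acc;
  int got = 0;
  for (int i = 0; i < nc && got < target; ++i) {
    acc.push_back({src[i] - 1, tgt[i] - 1});
    if (planar_impl(n, acc)) {
      keep[i] = true;
      ++got;
    } else {
      acc.pop_back();
    }
  }
  return keep;
}
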