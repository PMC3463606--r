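// Compiled kernels for the graph-heavy inner loops: all-pairs BFS metrics
// (Brandes betweenness, reachability, path lengths), directed clustering
// coefficients, ESU size-3 subgraph enumeration with typed canonical
// labelling, and the typed degree-preserving edge swap.
//
// Conventions: nodes are 1-based integer indices on the R side, 0-based
// here; node types are coded 1 = TF, 2 = miRNA, 3 = gene. All graphs are
// simple (no self-loops, no duplicate arcs) -- enforced by the R
// constructors before any of these functions are called.

#include <Rcpp.h>
#include <unordered_set>
#include <map>
#include <queue>
#include <vector>
#include <climits>

using namespace Rcpp;

typedef std::vector< std::vector<int> > AdjList;

static AdjList build_adj(int n, const IntegerVector& from,
                         const IntegerVector& to, bool reverse = false) {
  AdjList adj(n);
  for (int e = 0; e < from.size(); ++e) {
    int f = from[e] - 1, t = to[e] - 1;
    if (reverse) adj[t].push_back(f); else adj[f].push_back(t);
  }
  return adj;
}

// Brandes accumulation for exact directed betweenness, plus per-source
// reachable-node counts and shortest-path length sums from the same BFS.
// [[Rcpp::export]]
List cpp_path_metrics(int n, IntegerVector from, IntegerVector to) {
  AdjList adj = build_adj(n, from, to);
  NumericVector bw(n);
  IntegerVector reach(n);
  double apl_sum = 0.0, n_pairs = 0.0;

  std::vector<int> d(n), order(n);
  std::vector<double> sigma(n), delta(n);
  std::vector< std::vector<int> > pred(n);

  for (int s = 0; s < n; ++s) {
    std::fill(d.begin(), d.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    int top = 0;
    std::queue<int> Q;
    d[s] = 0; sigma[s] = 1.0; Q.push(s);
    while (!Q.empty()) {
      int v = Q.front(); Q.pop();
      order[top++] = v;
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
        if (d[w] < 0) { d[w] = d[v] + 1; Q.push(w); }
        if (d[w] == d[v] + 1) { sigma[w] += sigma[v]; pred[w].push_back(v); }
      }
    }
    for (int i = top - 1; i >= 0; --i) {
      int w = order[i];
      for (size_t k = 0; k < pred[w].size(); ++k) {
        int v = pred[w][k];
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) bw[w] += delta[w];
    }
    for (int t = 0; t < n; ++t) {
      if (t != s && d[t] > 0) { reach[s]++; apl_sum += d[t]; n_pairs += 1.0; }
    }
  }
  return List::create(_["betweenness"] = bw,
                      _["reach_count"] = reach,
                      _["apl_sum"] = apl_sum,
                      _["n_reachable_pairs"] = n_pairs);
}

// Directed clustering coefficient over the union neighborhood N(v):
// realized ordered arcs among N(v) divided by |N(v)|(|N(v)|-1); 0 when
// |N(v)| < 2.
// [[Rcpp::export]]
NumericVector cpp_clustering_coeff(int n, IntegerVector from, IntegerVector to) {
  AdjList out = build_adj(n, from, to);
  AdjList in  = build_adj(n, from, to, true);
  NumericVector cc(n);
  std::vector<char> mark(n, 0);
  std::vector<int> nbrs;

  for (int v = 0; v < n; ++v) {
    nbrs.clear();
    for (size_t k = 0; k < out[v].size(); ++k) {
      int u = out[v][k];
      if (!mark[u]) { mark[u] = 1; nbrs.push_back(u); }
    }
    for (size_t k = 0; k < in[v].size(); ++k) {
      int u = in[v][k];
      if (!mark[u]) { mark[u] = 1; nbrs.push_back(u); }
    }
    int deg = (int) nbrs.size();
    if (deg < 2) {
      cc[v] = 0.0;
    } else {
      long cnt = 0;
      for (size_t k = 0; k < nbrs.size(); ++k) {
        int u = nbrs[k];
        for (size_t j = 0; j < out[u].size(); ++j)
          if (mark[out[u][j]]) cnt++;   // arc u -> w with both u, w in N(v)
      }
      cc[v] = (double) cnt / ((double) deg * (deg - 1));
    }
    for (size_t k = 0; k < nbrs.size(); ++k) mark[nbrs[k]] = 0;
  }
  return cc;
}

// ---- typed canonical labels for 3-node subgraphs --------------------------

static const int PERMS[6][3] = {
  {0,1,2}, {0,2,1}, {1,0,2}, {1,2,0}, {2,0,1}, {2,1,0}
};

// Serialization: ((t1-1)*3 + (t2-1))*3 + (t3-1), then 6 adjacency bits in
// pair order (1,2),(1,3),(2,1),(2,3),(3,1),(3,2); canonical code is the
// minimum over the 6 node permutations.
static int canon_code(const int t[3], const int a[3][3]) {
  int best = INT_MAX;
  for (int p = 0; p < 6; ++p) {
    const int* pm = PERMS[p];
    int bits = (a[pm[0]][pm[1]] << 5) | (a[pm[0]][pm[2]] << 4) |
               (a[pm[1]][pm[0]] << 3) | (a[pm[1]][pm[2]] << 2) |
               (a[pm[2]][pm[0]] << 1) |  a[pm[2]][pm[1]];
    int code = (((t[pm[0]] - 1) * 3 + (t[pm[1]] - 1)) * 3 + (t[pm[2]] - 1)) * 64 + bits;
    if (code < best) best = code;
  }
  return best;
}

// [[Rcpp::export]]
int cpp_canonical_code(IntegerVector types, IntegerMatrix adj) {
  int t[3] = { types[0], types[1], types[2] };
  int a[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      a[i][j] = adj(i, j) ? 1 : 0;
  return canon_code(t, a);
}

// ESU (Wernicke) specialization for k = 3: every connected (direction-blind)
// 3-node induced subgraph is visited exactly once.
template <typename F>
static void esu3(int n, const AdjList& out, const AdjList& in, F yield) {
  AdjList und(n);
  std::vector< std::unordered_set<int> > undset(n);
  for (int v = 0; v < n; ++v) {
    for (size_t k = 0; k < out[v].size(); ++k) {
      int u = out[v][k];
      if (undset[v].insert(u).second) und[v].push_back(u);
    }
    for (size_t k = 0; k < in[v].size(); ++k) {
      int u = in[v][k];
      if (undset[v].insert(u).second) und[v].push_back(u);
    }
  }
  std::vector<int> ext;
  for (int v = 0; v < n; ++v) {
    ext.clear();
    for (size_t k = 0; k < und[v].size(); ++k)
      if (und[v][k] > v) ext.push_back(und[v][k]);
    for (size_t i = 0; i < ext.size(); ++i) {
      int w = ext[i];
      for (size_t j = i + 1; j < ext.size(); ++j)
        yield(v, w, ext[j]);
      for (size_t k = 0; k < und[w].size(); ++k) {
        int u = und[w][k];
        if (u > v && !undset[v].count(u))
          yield(v, w, u);
      }
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_esu_triples(int n, IntegerVector from, IntegerVector to) {
  AdjList out = build_adj(n, from, to);
  AdjList in  = build_adj(n, from, to, true);
  std::vector<int> xs, ys, zs;
  esu3(n, out, in, [&](int x, int y, int z) {
    xs.push_back(x + 1); ys.push_back(y + 1); zs.push_back(z + 1);
  });
  IntegerMatrix res(xs.size(), 3);
  for (size_t i = 0; i < xs.size(); ++i) {
    res(i, 0) = xs[i]; res(i, 1) = ys[i]; res(i, 2) = zs[i];
  }
  return res;
}

// Counts of canonical typed labels over all connected triples; optionally
// restricted to triples containing at least one TF and at least one miRNA.
// [[Rcpp::export]]
DataFrame cpp_count_motifs(int n, IntegerVector from, IntegerVector to,
                           IntegerVector type, bool require_both) {
  AdjList out = build_adj(n, from, to);
  AdjList in  = build_adj(n, from, to, true);
  std::unordered_set<long long> arcs;
  for (int e = 0; e < from.size(); ++e)
    arcs.insert((long long)(from[e] - 1) * n + (to[e] - 1));

  std::map<int, int> counts;   // ordered keys -> deterministic output order
  esu3(n, out, in, [&](int x, int y, int z) {
    int ids[3] = { x, y, z };
    if (require_both) {
      bool has_tf = false, has_mir = false;
      for (int i = 0; i < 3; ++i) {
        if (type[ids[i]] == 1) has_tf = true;
        else if (type[ids[i]] == 2) has_mir = true;
      }
      if (!has_tf || !has_mir) return;
    }
    int t[3] = { type[x], type[y], type[z] };
    int a[3][3] = { {0,0,0}, {0,0,0}, {0,0,0} };
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        if (i != j && arcs.count((long long) ids[i] * n + ids[j]))
          a[i][j] = 1;
    counts[canon_code(t, a)]++;
  });

  IntegerVector code(counts.size()), count(counts.size());
  int i = 0;
  for (std::map<int,int>::const_iterator it = counts.begin();
       it != counts.end(); ++it, ++i) {
    code[i] = it->first; count[i] = it->second;
  }
  return DataFrame::create(_["code"] = code, _["count"] = count);
}

// Typed degree-preserving double-arc swap. A partner arc must share the
// (source type, target type) class of the picked arc; a swap is rejected if
// it would create a self-loop or duplicate an existing arc. Preserves every
// node's in-degree, out-degree, and the type composition of its in- and
// out-neighborhoods. Uses the R RNG, so results are reproducible under
// set.seed().
// [[Rcpp::export]]
List cpp_typed_edge_swap(int n, IntegerVector from, IntegerVector to,
                         IntegerVector type, double n_attempts) {
  int m = from.size();
  std::vector<int> f(m), t(m);
  std::unordered_set<long long> present;
  for (int e = 0; e < m; ++e) {
    f[e] = from[e] - 1; t[e] = to[e] - 1;
    present.insert((long long) f[e] * n + t[e]);
  }
  std::vector< std::vector<int> > groups(9);
  std::vector<int> cls(m);
  for (int e = 0; e < m; ++e) {
    int c = (type[f[e]] - 1) * 3 + (type[t[e]] - 1);
    cls[e] = c;
    groups[c].push_back(e);
  }

  double n_swapped = 0;
  for (double a = 0; a < n_attempts; ++a) {
    int e1 = (int)(unif_rand() * m); if (e1 >= m) e1 = m - 1;
    const std::vector<int>& g = groups[cls[e1]];
    int gi = (int)(unif_rand() * g.size()); if (gi >= (int) g.size()) gi = (int) g.size() - 1;
    int e2 = g[gi];
    if (e1 == e2) continue;
    int f1 = f[e1], t1 = t[e1], f2 = f[e2], t2 = t[e2];
    if (f1 == f2 || t1 == t2) continue;     // no-op swap
    if (f1 == t2 || f2 == t1) continue;     // would create a self-loop
    long long k1 = (long long) f1 * n + t2, k2 = (long long) f2 * n + t1;
    if (present.count(k1) || present.count(k2)) continue;  // duplicates
    present.erase((long long) f1 * n + t1);
    present.erase((long long) f2 * n + t2);
    present.insert(k1); present.insert(k2);
    t[e1] = t2; t[e2] = t1;
    n_swapped += 1;
  }

  IntegerVector rf(m), rt(m);
  for (int e = 0; e < m; ++e) { rf[e] = f[e] + 1; rt[e] = t[e] + 1; }
  return List::create(_["from"] = rf, _["to"] = rt, _["n_swapped"] = n_swapped);
}
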