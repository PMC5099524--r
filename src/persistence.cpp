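#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Key for an undirected node pair (1-based ids, u < v).
static inline long long pair_key(int u, int v, int n) {
  return (long long)(u - 1) * n + (v - 1);
}

// Enumerate all triangles of the final graph incrementally: edges arrive in
// filtration order; when (u,v) enters, every common neighbour w already
// present closes a triangle whose entry step is the current (maximal) step.
// [[Rcpp::export]]
List hs_triangles_cpp(IntegerVector eu, IntegerVector ev,
                      IntegerVector estep, int n_nodes) {
  int m = eu.size();
  std::vector< std::vector<int> > adj(n_nodes + 1);
  std::vector<int> ta, tb, tc, ts;
  std::vector<char> present(n_nodes + 1, 0);
  for (int e = 0; e < m; ++e) {
    int u = eu[e], v = ev[e];
    // mark neighbours of u, then scan neighbours of v
    for (size_t i = 0; i < adj[u].size(); ++i) present[adj[u][i]] = 1;
    for (size_t i = 0; i < adj[v].size(); ++i) {
      int w = adj[v][i];
      if (present[w]) {
        int x = u, y = v, z = w;
        if (x > y) std::swap(x, y);
        if (y > z) std::swap(y, z);
        if (x > y) std::swap(x, y);
        ta.push_back(x); tb.push_back(y); tc.push_back(z);
        ts.push_back(estep[e]);
      }
    }
    for (size_t i = 0; i < adj[u].size(); ++i) present[adj[u][i]] = 0;
    adj[u].push_back(v);
    adj[v].push_back(u);
  }
  return List::create(_["a"] = wrap(ta), _["b"] = wrap(tb),
                      _["c"] = wrap(tc), _["step"] = wrap(ts));
}

struct UF {
  std::vector<int> parent;
  UF(int n) : parent(n + 1) { for (int i = 0; i <= n; ++i) parent[i] = i; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[a] = b;
    return true;
  }
};

// GF(2) persistence pairing in dimension 1.
// Edges must be in filtration order (step, then lexicographic); triangles in
// (step, then lexicographic) order with a < b < c. Returns, per edge, whether
// it is a spanning-forest edge and, for each cycle-creating edge, the death
// step (NA when the class survives the whole filtration).
// [[Rcpp::export]]
List hs_pairing_cpp(IntegerVector eu, IntegerVector ev, IntegerVector estep,
                    int n_nodes,
                    IntegerVector ta, IntegerVector tb, IntegerVector tc,
                    IntegerVector tstep) {
  int m = eu.size(), nt = ta.size();
  LogicalVector tree(m);
  IntegerVector death(m, NA_INTEGER);

  UF uf(n_nodes);
  std::unordered_map<long long, int> eidx; // pair -> edge index (0-based)
  eidx.reserve(m * 2);
  for (int e = 0; e < m; ++e) {
    tree[e] = uf.unite(eu[e], ev[e]);
    int u = eu[e], v = ev[e];
    if (u > v) std::swap(u, v);
    eidx[pair_key(u, v, n_nodes)] = e;
  }

  // reduced columns of paired triangles, indexed by their low edge
  std::unordered_map<int, std::vector<int> > low_col;
  low_col.reserve(nt);
  std::vector<int> col, tmp;
  for (int t = 0; t < nt; ++t) {
    col.clear();
    int a = ta[t], b = tb[t], c = tc[t];
    col.push_back(eidx[pair_key(a, b, n_nodes)]);
    col.push_back(eidx[pair_key(a, c, n_nodes)]);
    col.push_back(eidx[pair_key(b, c, n_nodes)]);
    std::sort(col.begin(), col.end());
    while (!col.empty()) {
      int low = col.back();
      std::unordered_map<int, std::vector<int> >::iterator it =
        low_col.find(low);
      if (it == low_col.end()) break;
      // symmetric difference (XOR over GF(2)) with the stored column
      const std::vector<int>& other = it->second;
      tmp.clear();
      std::set_symmetric_difference(col.begin(), col.end(),
                                    other.begin(), other.end(),
                                    std::back_inserter(tmp));
      col.swap(tmp);
    }
    if (!col.empty()) {
      int low = col.back();
      death[low] = tstep[t];
      low_col[low] = col;
    }
    // empty column: the triangle creates a 2-cycle, irrelevant for H1
  }
  return List::create(_["tree"] = tree, _["death"] = death);
}
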