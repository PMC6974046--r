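// Exhaustive enumeration of feasible coalitions: connected induced
// subgraphs of a given size (ESU-style extension, each set emitted once)
// and cliques. Vertices are 0-based internally; the R wrappers convert.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// Adjacency as vector<vector<int>>, 0-based, sorted not required.
std::vector<std::vector<int>> build_adj(const List& adj1, int n) {
  std::vector<std::vector<int>> adj(n);
  for (int v = 0; v < n; ++v) {
    IntegerVector nb = adj1[v];
    adj[v].reserve(nb.size());
    for (int j = 0; j < nb.size(); ++j) adj[v].push_back(nb[j] - 1);
  }
  return adj;
}

struct EsuState {
  const std::vector<std::vector<int>>* adj;
  int k;
  int root;
  std::vector<int> sub;          // current subset
  std::vector<char> in_sub;      // membership flag
  std::vector<char> in_ext_ever; // already placed in some extension set
  std::vector<int>* out;         // flat output, k ints per set
};

// Extend `sub` using the extension list `ext` (vertices > root, adjacent to
// sub, not previously offered). Classic ESU: each connected k-set with
// minimum vertex == root is emitted exactly once.
void esu_extend(EsuState& st, std::vector<int> ext) {
  if ((int)st.sub.size() == st.k) {
    for (int v : st.sub) st.out->push_back(v);
    return;
  }
  while (!ext.empty()) {
    int w = ext.back();
    ext.pop_back();
    std::vector<int> ext2 = ext;
    std::vector<int> added;
    for (int u : (*st.adj)[w]) {
      if (u > st.root && !st.in_sub[u] && !st.in_ext_ever[u]) {
        ext2.push_back(u);
        st.in_ext_ever[u] = 1;
        added.push_back(u);
      }
    }
    st.sub.push_back(w);
    st.in_sub[w] = 1;
    esu_extend(st, ext2);
    st.sub.pop_back();
    st.in_sub[w] = 0;
    for (int u : added) st.in_ext_ever[u] = 0;
  }
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix enum_connected_cpp(List adj1, int n, int k) {
  std::vector<std::vector<int>> adj = build_adj(adj1, n);
  std::vector<int> out;
  if (k == 1) {
    out.reserve(n);
    for (int v = 0; v < n; ++v) out.push_back(v);
  } else {
    EsuState st;
    st.adj = &adj;
    st.k = k;
    st.out = &out;
    st.in_sub.assign(n, 0);
    st.in_ext_ever.assign(n, 0);
    for (int v = 0; v < n; ++v) {
      st.root = v;
      st.sub.assign(1, v);
      st.in_sub[v] = 1;
      std::vector<int> ext;
      std::vector<int> offered;
      for (int u : adj[v])
        if (u > v) { ext.push_back(u); st.in_ext_ever[u] = 1; offered.push_back(u); }
      esu_extend(st, ext);
      st.in_sub[v] = 0;
      for (int u : offered) st.in_ext_ever[u] = 0;
    }
  }
  int m = out.size() / k;
  IntegerMatrix res(k, m);
  for (int c = 0; c < m; ++c) {
    // emit members sorted ascending, 1-based
    std::vector<int> col(out.begin() + (size_t)c * k, out.begin() + (size_t)(c + 1) * k);
    std::sort(col.begin(), col.end());
    for (int r = 0; r < k; ++r) res(r, c) = col[r] + 1;
  }
  return res;
}

namespace {

void clique_extend(const std::vector<std::vector<char>>& am, int n, int k,
                   std::vector<int>& sub, std::vector<int>& out) {
  if ((int)sub.size() == k) {
    for (int v : sub) out.push_back(v);
    return;
  }
  int last = sub.back();
  for (int w = last + 1; w < n; ++w) {
    bool ok = true;
    for (int v : sub)
      if (!am[v][w]) { ok = false; break; }
    if (ok) {
      sub.push_back(w);
      clique_extend(am, n, k, sub, out);
      sub.pop_back();
    }
  }
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix enum_cliques_cpp(List adj1, int n, int k) {
  std::vector<std::vector<int>> adj = build_adj(adj1, n);
  std::vector<int> out;
  if (k == 1) {
    for (int v = 0; v < n; ++v) out.push_back(v);
  } else {
    std::vector<std::vector<char>> am(n, std::vector<char>(n, 0));
    for (int v = 0; v < n; ++v)
      for (int u : adj[v]) am[v][u] = 1;
    std::vector<int> sub;
    for (int v = 0; v < n; ++v) {
      sub.assign(1, v);
      clique_extend(am, n, k, sub, out);
    }
  }
  int m = out.size() / k;
  IntegerMatrix res(k, m);
  for (int c = 0; c < m; ++c)
    for (int r = 0; r < k; ++r) res(r, c) = out[(size_t)c * k + r] + 1;
  return res;
}
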