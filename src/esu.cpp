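#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<std::vector<int> > AdjList;

static AdjList build_adj(const List& adjlist) {
  int n = adjlist.size();
  AdjList adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adjlist[i];
    adj[i].reserve(nb.size());
    for (int j = 0; j < nb.size(); ++j) adj[i].push_back(nb[j] - 1); // to 0-based
    std::sort(adj[i].begin(), adj[i].end());
  }
  return adj;
}

static inline bool has_edge(const AdjList& adj, int u, int v) {
  if (adj[u].size() <= adj[v].size())
    return std::binary_search(adj[u].begin(), adj[u].end(), v);
  return std::binary_search(adj[v].begin(), adj[v].end(), u);
}

struct EsuCtx {
  const AdjList* adj;
  int k;
  int root;
  std::vector<char> vis;      // marks root, N(sub) and everything ever placed in ext
  std::vector<int> sub;
  std::vector<int> out_nodes; // flattened occurrences, k ints each (1-based, sorted)
  std::vector<int> out_code;  // canonical code per occurrence
  const int* canon_map;       // code -> canonical code, -1 if disconnected
};

// upper-triangular bit index for pair (i<j) among k nodes
static inline int pair_bit(int i, int j, int k) {
  return i * (2 * k - i - 1) / 2 + (j - i - 1);
}

static void esu_record(EsuCtx& C) {
  std::vector<int> s(C.sub);
  std::sort(s.begin(), s.end());
  int code = 0;
  for (int i = 0; i < C.k; ++i)
    for (int j = i + 1; j < C.k; ++j)
      if (has_edge(*C.adj, s[i], s[j])) code |= (1 << pair_bit(i, j, C.k));
  for (int i = 0; i < C.k; ++i) C.out_nodes.push_back(s[i] + 1);
  C.out_code.push_back(C.canon_map[code]);
}

static void esu_extend(EsuCtx& C, std::vector<int>& ext) {
  if ((int)C.sub.size() == C.k) { esu_record(C); return; }
  while (!ext.empty()) {
    int w = ext.back();
    ext.pop_back();
    std::vector<int> ext2(ext);
    std::vector<int> newly;
    const std::vector<int>& nb = (*C.adj)[w];
    for (size_t i = 0; i < nb.size(); ++i) {
      int u = nb[i];
      if (u > C.root && !C.vis[u]) {
        C.vis[u] = 1;
        newly.push_back(u);
        ext2.push_back(u);
      }
    }
    C.sub.push_back(w);
    esu_extend(C, ext2);
    C.sub.pop_back();
    for (size_t i = 0; i < newly.size(); ++i) C.vis[newly[i]] = 0;
  }
}

// ESU enumeration of all connected k-node induced subgraphs.
// adjlist: list of 1-based sorted integer neighbour vectors.
// canon_map: integer vector of length 2^(k(k-1)/2), mapping an adjacency
//   bit code to its canonical code (-1 for disconnected codes).
// [[Rcpp::export]]
List esu_enumerate_cpp(List adjlist, int k, IntegerVector canon_map) {
  AdjList adj = build_adj(adjlist);
  int n = adj.size();
  EsuCtx C;
  C.adj = &adj;
  C.k = k;
  C.canon_map = INTEGER(canon_map);
  C.vis.assign(n, 0);
  for (int root = 0; root < n; ++root) {
    if (root % 256 == 0) Rcpp::checkUserInterrupt();
    C.root = root;
    std::vector<int> ext;
    std::vector<int> marked;
    C.vis[root] = 1;
    marked.push_back(root);
    const std::vector<int>& nb = adj[root];
    for (size_t i = 0; i < nb.size(); ++i) {
      int u = nb[i];
      if (u > root) {
        ext.push_back(u);
        C.vis[u] = 1;
        marked.push_back(u);
      }
    }
    C.sub.clear();
    C.sub.push_back(root);
    esu_extend(C, ext);
    for (size_t i = 0; i < marked.size(); ++i) C.vis[marked[i]] = 0;
  }
  int m = C.out_code.size();
  IntegerMatrix occ(m, k);
  for (int r = 0; r < m; ++r)
    for (int c = 0; c < k; ++c) occ(r, c) = C.out_nodes[(size_t)r * k + c];
  return List::create(_["nodes"] = occ, _["canon"] = wrap(C.out_code));
}

// Shuffle-greedy maximal independent set over motif occurrences.
// occ: m x k matrix of 1-based node ids; ord: 1-based processing order
// (the shuffle, drawn in R); policy: 1 = edge-disjoint, 2 = node-disjoint.
// Returns keep flags in the original occurrence order.
// [[Rcpp::export]]
LogicalVector mis_filter_cpp(IntegerMatrix occ, IntegerVector ord,
                             List adjlist, int policy) {
  AdjList adj = build_adj(adjlist);
  long long n = adj.size();
  int m = occ.nrow(), k = occ.ncol();
  LogicalVector keep(m);
  std::vector<char> used_node(n + 1, 0);
  std::unordered_set<long long> used_edge;
  std::vector<int> nodes(k);
  for (int idx = 0; idx < m; ++idx) {
    if (idx % 4096 == 0) Rcpp::checkUserInterrupt();
    int r = ord[idx] - 1;
    for (int c = 0; c < k; ++c) nodes[c] = occ(r, c);
    bool free_ = true;
    if (policy == 2) {
      for (int c = 0; c < k && free_; ++c)
        if (used_node[nodes[c]]) free_ = false;
      if (free_) {
        keep[r] = true;
        for (int c = 0; c < k; ++c) used_node[nodes[c]] = 1;
      }
    } else {
      std::vector<long long> keys;
      for (int i = 0; i < k && free_; ++i)
        for (int j = i + 1; j < k; ++j)
          if (has_edge(adj, nodes[i] - 1, nodes[j] - 1)) {
            long long key = (long long)nodes[i] * (n + 1) + nodes[j];
            if (used_edge.count(key)) { free_ = false; break; }
            keys.push_back(key);
          }
      if (free_) {
        keep[r] = true;
        for (size_t i = 0; i < keys.size(); ++i) used_edge.insert(keys[i]);
      }
    }
  }
  return keep;
}
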