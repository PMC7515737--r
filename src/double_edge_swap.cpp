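#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <utility>
using namespace Rcpp;

static inline int randIndex(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

static inline long long edgeKey(int a, int b, int n) {
  return (a < b) ? (long long)a * n + b : (long long)b * n + a;
}

static inline void adjRemove(std::vector<int> &v, int x) {
  for (size_t i = 0; i < v.size(); ++i) {
    if (v[i] == x) { v[i] = v.back(); v.pop_back(); return; }
  }
}

// Degree-preserving double-edge swaps with per-swap connectivity enforcement.
// edges: m x 2 matrix of 0-based endpoints of a connected simple graph.
// A swap replaces (u,v),(x,y) by (u,y),(x,v); it is rejected when endpoints
// clash, a created edge already exists, or the swapped graph is disconnected
// (rolled back). Connectivity after a swap only requires that u still reaches
// v and x still reaches y (every path through a removed edge can then be
// rerouted), so the check is an early-exit BFS to the removed partner.
// Uses R's RNG stream.
// [[Rcpp::export]]
List cpp_double_edge_swap(IntegerMatrix edges, int nNodes, double nAttempts) {
  const int m = edges.nrow();
  std::vector<std::pair<int, int> > el(m);
  std::vector<std::vector<int> > adj(nNodes);
  std::unordered_set<long long> eset;
  eset.reserve(2 * m);
  for (int i = 0; i < m; ++i) {
    int u = edges(i, 0), v = edges(i, 1);
    el[i] = std::make_pair(u, v);
    adj[u].push_back(v);
    adj[v].push_back(u);
    eset.insert(edgeKey(u, v, nNodes));
  }

  const long long attempts = (long long) nAttempts;
  long long accepted = 0, rejClash = 0, rejDisc = 0;
  std::vector<int> stamp(nNodes, -1);
  std::vector<int> queue(nNodes);
  int pass = 0;

  // BFS from s, early exit when t is found
  auto reaches = [&](int s, int t) -> bool {
    ++pass;
    int head = 0, tail = 0;
    queue[tail++] = s;
    stamp[s] = pass;
    while (head < tail) {
      int c = queue[head++];
      const std::vector<int> &nb = adj[c];
      for (size_t i = 0; i < nb.size(); ++i) {
        int w = nb[i];
        if (w == t) return true;
        if (stamp[w] != pass) { stamp[w] = pass; queue[tail++] = w; }
      }
    }
    return false;
  };

  for (long long a = 0; a < attempts; ++a) {
    int i = randIndex(m), j = randIndex(m);
    if (i == j) { ++rejClash; continue; }
    int u = el[i].first, v = el[i].second;
    int x = el[j].first, y = el[j].second;
    if (unif_rand() < 0.5) std::swap(u, v);
    if (unif_rand() < 0.5) std::swap(x, y);
    if (u == x || u == y || v == x || v == y) { ++rejClash; continue; }
    if (eset.count(edgeKey(u, y, nNodes)) ||
        eset.count(edgeKey(x, v, nNodes))) { ++rejClash; continue; }

    // apply: (u,v),(x,y) -> (u,y),(x,v)
    eset.erase(edgeKey(u, v, nNodes));
    eset.erase(edgeKey(x, y, nNodes));
    eset.insert(edgeKey(u, y, nNodes));
    eset.insert(edgeKey(x, v, nNodes));
    adjRemove(adj[u], v); adjRemove(adj[v], u);
    adjRemove(adj[x], y); adjRemove(adj[y], x);
    adj[u].push_back(y); adj[y].push_back(u);
    adj[x].push_back(v); adj[v].push_back(x);

    if (reaches(u, v) && reaches(x, y)) {
      el[i] = std::make_pair(u, y);
      el[j] = std::make_pair(x, v);
      ++accepted;
    } else {
      eset.erase(edgeKey(u, y, nNodes));
      eset.erase(edgeKey(x, v, nNodes));
      eset.insert(edgeKey(u, v, nNodes));
      eset.insert(edgeKey(x, y, nNodes));
      adjRemove(adj[u], y); adjRemove(adj[y], u);
      adjRemove(adj[x], v); adjRemove(adj[v], x);
      adj[u].push_back(v); adj[v].push_back(u);
      adj[x].push_back(y); adj[y].push_back(x);
      ++rejDisc;
    }
  }

  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = el[i].first;
    out(i, 1) = el[i].second;
  }
  return List::create(_["edges"] = out,
                      _["attempts"] = (double) attempts,
                      _["accepted"] = (double) accepted,
                      _["rejectedClash"] = (double) rejClash,
                      _["rejectedDisconnected"] = (double) rejDisc);
}
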