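// Core search machinery: unrooted-tree split hashing, SPR neighbourhood
// enumeration, breadth-first SPR edit distance, and the permutation screen
// statistics.  Trees arrive as ape edge matrices (1-based; tips 1..ntip).
// Leaf indexing must already be harmonised across trees by the R callers.

#include <Rcpp.h>
#include <array>
#include <cstring>
#include <queue>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <random>
#include <vector>

using namespace Rcpp;

typedef uint64_t mask_t;

struct UTree {
  int ntip;
  // adjacency; degree <= 3, unused slots = -1
  std::vector<std::array<int, 3>> nb;
};

static void add_edge(UTree &t, int u, int v) {
  for (int k = 0; k < 3; ++k)
    if (t.nb[u][k] < 0) { t.nb[u][k] = v; break; }
  for (int k = 0; k < 3; ++k)
    if (t.nb[v][k] < 0) { t.nb[v][k] = u; break; }
}

static int degree(const UTree &t, int u) {
  int d = 0;
  for (int k = 0; k < 3; ++k) if (t.nb[u][k] >= 0) ++d;
  return d;
}

// Build from an ape edge matrix.  Node ids are kept as-is (0-based after
// shifting); array sized to the max id.  Binary unrooted trees have
// 2*ntip-2 nodes but ape ids may exceed that for degree-2 roots, which the
// R side removes beforehand.
static UTree build_tree(const IntegerMatrix &edge, int ntip) {
  int maxid = 0;
  for (int i = 0; i < edge.nrow(); ++i) {
    maxid = std::max(maxid, edge(i, 0));
    maxid = std::max(maxid, edge(i, 1));
  }
  UTree t;
  t.ntip = ntip;
  t.nb.assign(maxid, {{-1, -1, -1}});
  for (int i = 0; i < edge.nrow(); ++i)
    add_edge(t, edge(i, 0) - 1, edge(i, 1) - 1);
  return t;
}

// Non-trivial splits as bit masks over tips, normalised to the side not
// containing tip 0, sorted ascending.  Works for multifurcating trees.
static std::vector<mask_t> tree_splits(const UTree &t) {
  int n = (int)t.nb.size();
  std::vector<mask_t> below(n, 0);
  std::vector<int> parent(n, -2), order;
  order.reserve(n);
  // iterative DFS from tip 0
  std::vector<int> stack;
  stack.push_back(0);
  parent[0] = -1;
  while (!stack.empty()) {
    int u = stack.back();
    stack.pop_back();
    order.push_back(u);
    for (int k = 0; k < 3; ++k) {
      int v = t.nb[u][k];
      if (v >= 0 && v != parent[u]) {
        parent[v] = u;
        stack.push_back(v);
      }
    }
  }
  for (int i = (int)order.size() - 1; i >= 0; --i) {
    int u = order[i];
    if (u < t.ntip) below[u] |= ((mask_t)1) << u;
    if (parent[u] >= 0) below[parent[u]] |= below[u];
  }
  mask_t full = (t.ntip >= 64) ? ~(mask_t)0 : ((((mask_t)1) << t.ntip) - 1);
  std::vector<mask_t> out;
  for (int u = 1; u < n; ++u) {
    if (parent[u] < 0 || parent[u] == -2) continue;
    mask_t m = below[u];
    int pc = __builtin_popcountll(m);
    if (pc <= 1 || pc >= t.ntip - 1) continue;
    if (m & 1) m = full & ~m;
    out.push_back(m);
  }
  std::sort(out.begin(), out.end());
  return out;
}

static std::string splits_key(const std::vector<mask_t> &s) {
  std::string key(s.size() * sizeof(mask_t), '\0');
  if (!s.empty()) std::memcpy(&key[0], s.data(), key.size());
  return key;
}

static std::string tree_key(const UTree &t) { return splits_key(tree_splits(t)); }

// a contains b? (both sorted ascending)
static bool contains_all(const std::vector<mask_t> &a, const std::vector<mask_t> &b) {
  size_t i = 0;
  for (mask_t m : b) {
    while (i < a.size() && a[i] < m) ++i;
    if (i == a.size() || a[i] != m) return false;
  }
  return true;
}

// All SPR neighbours of a binary unrooted tree (n >= 4).
static void spr_neighbours(const UTree &t, std::vector<UTree> &out) {
  out.clear();
  int n = (int)t.nb.size();
  // edge list u < v
  std::vector<std::pair<int, int>> edges;
  for (int u = 0; u < n; ++u)
    for (int k = 0; k < 3; ++k) {
      int v = t.nb[u][k];
      if (v > u) edges.push_back({u, v});
    }
  std::vector<char> inS(n);
  std::vector<int> stack;
  for (int p = 0; p < n; ++p) {
    if (degree(t, p) != 3) continue;
    for (int si = 0; si < 3; ++si) {
      int s = t.nb[p][si];
      int q = t.nb[p][(si + 1) % 3];
      int r = t.nb[p][(si + 2) % 3];
      // component containing s once edge p-s is cut
      std::fill(inS.begin(), inS.end(), 0);
      stack.clear();
      stack.push_back(s);
      inS[s] = 1;
      while (!stack.empty()) {
        int u = stack.back();
        stack.pop_back();
        for (int k = 0; k < 3; ++k) {
          int v = t.nb[u][k];
          if (v >= 0 && !inS[v] && !(u == s && v == p)) {
            inS[v] = 1;
            stack.push_back(v);
          }
        }
      }
      for (auto &e : edges) {
        int u = e.first, v = e.second;
        if (u == p || v == p || inS[u] || inS[v]) continue;
        UTree w = t;
        // contract p out of the remaining tree: q - r
        for (int k = 0; k < 3; ++k) {
          if (w.nb[q][k] == p) w.nb[q][k] = r;
          if (w.nb[r][k] == p) w.nb[r][k] = q;
        }
        // subdivide u - v with p, reattach s
        for (int k = 0; k < 3; ++k) {
          if (w.nb[u][k] == v) w.nb[u][k] = p;
          if (w.nb[v][k] == u) w.nb[v][k] = p;
        }
        w.nb[p] = {{u, v, s}};
        out.push_back(std::move(w));
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_tree_splits(IntegerMatrix edge, int ntip) {
  UTree t = build_tree(edge, ntip);
  std::vector<mask_t> s = tree_splits(t);
  NumericVector out(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = (double)s[i];
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_spr_neighbor_keys(IntegerMatrix edge, int ntip) {
  UTree t = build_tree(edge, ntip);
  std::vector<UTree> nbs;
  spr_neighbours(t, nbs);
  std::unordered_set<std::string> seen;
  std::vector<std::string> keys;
  for (auto &w : nbs) {
    std::vector<mask_t> s = tree_splits(w);
    std::string bin = splits_key(s);
    if (seen.insert(bin).second) {
      std::string dec;
      for (size_t i = 0; i < s.size(); ++i) {
        if (i) dec += ",";
        dec += std::to_string(s[i]);
      }
      keys.push_back(dec);
    }
  }
  CharacterVector out(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) out[i] = keys[i];
  return out;
}

struct SearchSide {
  std::unordered_map<std::string, int> visited;
  std::vector<UTree> frontier;
  int depth = 0;
};

// Exact SPR distance between binary unrooted trees by bidirectional
// layered BFS; or, when `displays` is true, the minimum number of SPR
// moves taking tree1 (binary) to any binary tree displaying all splits in
// `goal_splits` (unidirectional).
// Returns distance = -1 when the search exhausted d_max or max_nodes.
// [[Rcpp::export]]
List cpp_spr_distance(IntegerMatrix edge1, IntegerMatrix edge2, int ntip,
                      int d_max, double max_nodes, bool displays,
                      NumericVector goal_splits) {
  UTree t1 = build_tree(edge1, ntip);
  double explored = 0;
  std::vector<UTree> nbs;
  if (displays) {
    std::vector<mask_t> goal(goal_splits.size());
    for (int i = 0; i < goal_splits.size(); ++i) goal[i] = (mask_t)goal_splits[i];
    std::sort(goal.begin(), goal.end());
    if (contains_all(tree_splits(t1), goal))
      return List::create(_["distance"] = 0, _["resolved"] = true,
                          _["nodes"] = 1.0);
    std::unordered_set<std::string> visited;
    std::vector<UTree> frontier{t1};
    visited.insert(tree_key(t1));
    for (int depth = 1; depth <= d_max; ++depth) {
      std::vector<UTree> next;
      for (auto &t : frontier) {
        spr_neighbours(t, nbs);
        for (auto &w : nbs) {
          std::vector<mask_t> s = tree_splits(w);
          std::string key = splits_key(s);
          if (visited.count(key)) continue;
          if (contains_all(s, goal))
            return List::create(_["distance"] = depth, _["resolved"] = true,
                                _["nodes"] = explored);
          visited.insert(key);
          explored += 1;
          if (explored > max_nodes)
            return List::create(_["distance"] = -1, _["resolved"] = false,
                                _["nodes"] = explored);
          next.push_back(std::move(w));
        }
      }
      frontier.swap(next);
      if (frontier.empty()) break;
    }
    return List::create(_["distance"] = -1, _["resolved"] = false,
                        _["nodes"] = explored);
  }

  UTree t2 = build_tree(edge2, ntip);
  std::string k1 = tree_key(t1), k2 = tree_key(t2);
  if (k1 == k2)
    return List::create(_["distance"] = 0, _["resolved"] = true,
                        _["nodes"] = 2.0);
  SearchSide A, B;
  A.visited[k1] = 0;
  A.frontier.push_back(t1);
  B.visited[k2] = 0;
  B.frontier.push_back(t2);
  int best = INT_MAX;
  while (true) {
    if (A.depth + B.depth + 1 >= best)
      return List::create(_["distance"] = best, _["resolved"] = true,
                          _["nodes"] = explored);
    if (A.depth + B.depth + 1 > d_max)
      return List::create(_["distance"] = -1, _["resolved"] = false,
                          _["nodes"] = explored);
    SearchSide &ego = (A.frontier.size() <= B.frontier.size()) ? A : B;
    SearchSide &alt = (&ego == &A) ? B : A;
    if (ego.frontier.empty())
      return List::create(_["distance"] = -1, _["resolved"] = false,
                          _["nodes"] = explored);
    std::vector<UTree> next;
    int layer = ego.depth + 1;
    for (auto &t : ego.frontier) {
      spr_neighbours(t, nbs);
      for (auto &w : nbs) {
        std::string key = tree_key(w);
        auto hitEgo = ego.visited.find(key);
        if (hitEgo != ego.visited.end()) continue;
        auto hit = alt.visited.find(key);
        if (hit != alt.visited.end())
          best = std::min(best, layer + hit->second);
        ego.visited[key] = layer;
        explored += 1;
        if (explored > max_nodes) {
          if (best < INT_MAX)
            return List::create(_["distance"] = best, _["resolved"] = true,
                                _["nodes"] = explored);
          return List::create(_["distance"] = -1, _["resolved"] = false,
                              _["nodes"] = explored);
        }
        next.push_back(std::move(w));
      }
    }
    ego.frontier.swap(next);
    ego.depth = layer;
  }
}

// ---------------------------------------------------------------------------
// Permutation screen statistics.
//
// X: nseq x m matrix of state codes at parsimony-informative sites
//    (0..k-1; -1 = missing/gap).  pos: original alignment coordinate of
//    each column, ascending.  The pairwise refined incompatibility of two
//    columns is the cyclomatic number (edges - vertices + components) of
//    the bipartite state-pair graph, the minimum number of extra state
//    changes required on any tree; zero iff the two columns are
//    compatible (generalised four-gamete condition).

static int refined_incompat(const IntegerMatrix &X, int i, int j) {
  // states capped at 8 per column
  int idmap_i[8], idmap_j[8];
  for (int k = 0; k < 8; ++k) idmap_i[k] = idmap_j[k] = -1;
  int ni = 0, nj = 0;
  bool pairSeen[64];
  std::memset(pairSeen, 0, sizeof(pairSeen));
  int parent[16];
  int V = 0, E = 0;
  auto findp = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  int comp = 0;
  for (int s = 0; s < X.nrow(); ++s) {
    int a = X(s, i), b = X(s, j);
    if (a < 0 || b < 0) continue;
    if (a > 7) a = 7;
    if (b > 7) b = 7;
    if (idmap_i[a] < 0) { idmap_i[a] = ni++; parent[idmap_i[a]] = idmap_i[a]; ++V; ++comp; }
    if (idmap_j[b] < 0) { idmap_j[b] = 8 + nj++; parent[idmap_j[b]] = idmap_j[b]; ++V; ++comp; }
    int code = idmap_i[a] * 8 + (idmap_j[b] - 8);
    if (!pairSeen[code]) {
      pairSeen[code] = true;
      ++E;
      int ra = findp(idmap_i[a]), rb = findp(idmap_j[b]);
      if (ra != rb) { parent[ra] = rb; --comp; }
    }
  }
  return E - V + comp;
}

// [[Rcpp::export]]
List cpp_screen_stats(IntegerMatrix X, IntegerVector pos, int window,
                      int nperm, int seed) {
  int n = X.nrow(), m = X.ncol();
  if (m < 2) stop("need at least two informative sites");
  // refined incompatibility for all column pairs
  std::vector<std::vector<uint8_t>> RI(m, std::vector<uint8_t>(m, 0));
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j) {
      int ri = refined_incompat(X, i, j);
      RI[i][j] = RI[j][i] = (uint8_t)std::min(ri, 255);
    }
  // compatibility rows as bitsets (1 = incompatible)
  int W = (m + 63) / 64;
  std::vector<std::vector<uint64_t>> Crow(m, std::vector<uint64_t>(W, 0));
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j)
      if (RI[i][j] > 0) Crow[i][j / 64] |= ((uint64_t)1) << (j % 64);
  // PHI window pairs on the fixed position lattice
  std::vector<std::pair<int, int>> wpairs;
  for (int k = 0; k < m; ++k)
    for (int l = k + 1; l < m && pos[l] - pos[k] <= window; ++l)
      wpairs.push_back({k, l});
  // pairwise sequence difference indicators
  std::vector<std::pair<int, int>> spairs;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) spairs.push_back({a, b});
  int P = (int)spairs.size();
  std::vector<std::vector<uint8_t>> diff(P, std::vector<uint8_t>(m, 0));
  std::vector<int> D(P, 0);
  for (int p = 0; p < P; ++p) {
    int a = spairs[p].first, b = spairs[p].second;
    for (int s = 0; s < m; ++s) {
      int xa = X(a, s), xb = X(b, s);
      uint8_t d = (xa >= 0 && xb >= 0 && xa != xb) ? 1 : 0;
      diff[p][s] = d;
      D[p] += d;
    }
  }
  std::vector<int> perm(m);
  for (int i = 0; i < m; ++i) perm[i] = i;

  auto phi_stat = [&](const std::vector<int> &pm) {
    if (wpairs.empty()) return -1.0;
    double s = 0;
    for (auto &pr : wpairs) s += RI[pm[pr.first]][pm[pr.second]];
    return s / (double)wpairs.size();
  };
  auto nss_stat = [&](const std::vector<int> &pm) {
    double s = 0;
    for (int k = 0; k + 1 < m; ++k) {
      int u = pm[k], v = pm[k + 1];
      int diffbits = 0;
      for (int w = 0; w < W; ++w)
        diffbits += __builtin_popcountll(Crow[u][w] ^ Crow[v][w]);
      s += (m - diffbits) / (double)m;
    }
    return s / (double)(m - 1);
  };
  auto maxchi_stat = [&](const std::vector<int> &pm) {
    double best = 0;
    for (int p = 0; p < P; ++p) {
      if (D[p] == 0 || D[p] == m) continue;
      int dl = 0;
      for (int k = 0; k + 1 < m; ++k) {
        dl += diff[p][pm[k]];
        int L = k + 1, R = m - L, dr = D[p] - dl;
        double num = (double)dl * (R - dr) - (double)(L - dl) * dr;
        double chi = (double)m * num * num /
                     ((double)L * R * D[p] * (m - D[p]));
        if (chi > best) best = chi;
      }
    }
    return best;
  };

  double phi0 = phi_stat(perm), nss0 = nss_stat(perm), chi0 = maxchi_stat(perm);
  // mid-p: ties between observed and permuted statistics count half, so
  // the heavily tied discrete statistics stay calibrated at the nominal
  // level while p remains in (0, 1]
  double phi_b = 0, nss_b = 0, chi_b = 0;
  std::mt19937 rng((uint32_t)seed);
  const double eps = 1e-9;
  for (int r = 0; r < nperm; ++r) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double ph = phi_stat(perm), ns = nss_stat(perm), mc = maxchi_stat(perm);
    phi_b += (ph < phi0 - eps) ? 1.0 : (ph <= phi0 + eps ? 0.5 : 0.0);
    nss_b += (ns > nss0 + eps) ? 1.0 : (ns >= nss0 - eps ? 0.5 : 0.0);
    chi_b += (mc > chi0 + eps) ? 1.0 : (mc >= chi0 - eps ? 0.5 : 0.0);
  }
  double denom = nperm + 1.0;
  return List::create(
      _["phi"] = phi0, _["nss"] = nss0, _["maxchi"] = chi0,
      _["p_phi"] = (phi0 < 0) ? 1.0 : (phi_b + 1) / denom,
      _["p_nss"] = (nss_b + 1) / denom,
      _["p_maxchi"] = (chi_b + 1) / denom);
}
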