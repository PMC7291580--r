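// Atom-pair shingling core.
//
// A molecule arrives as parallel vectors (element symbol, formal charge,
// implicit H count) plus a bond table (i, j, order; 1-based, kekulized).
// For every non-hydrogen atom the circular substructure of radius 1..r is
// written as a canonical SMILES rooted at the center atom, and every
// unordered atom pair (j,k) yields, per radius, one shingle
//   min(CS,CS') | distance | max(CS,CS')
// where distance is the shortest-path bond count between j and k.
//
// The canonical rooted writer uses iterative invariant refinement
// (Weisfeiler-Lehman style) over written atom tokens and bond orders,
// followed by tie-break branching: each unresolved symmetry cell is broken
// one atom at a time, ranks are re-refined, and the lexicographically
// smallest of the resulting SMILES strings is kept. Environments are small
// (tens of atoms), so the bounded branching is cheap; if the branch budget
// is ever exceeded remaining ties fall back to subgraph index order, which
// is still deterministic because molecules are canonicalized upstream.
#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <map>
#include <queue>
#include <set>
#include <string>
#include <vector>

namespace {

struct Graph {
  int n;
  std::vector<std::string> token;              // written atom token
  std::vector<std::vector<std::pair<int, int> > > adj; // (neighbor, order)
};

const char *ORGANIC[] = {"B", "C", "N", "O", "P", "S",
                         "F", "Cl", "Br", "I", 0};

bool is_organic_subset(const std::string &el) {
  for (int i = 0; ORGANIC[i]; ++i)
    if (el == ORGANIC[i]) return true;
  return false;
}

// Atom token as written in the output SMILES. Organic-subset neutral atoms
// are written bare (implicit H filled in by the reader); anything else is
// bracketed with its molecule H count and charge.
std::string atom_token(const std::string &el, int charge, int nH) {
  if (charge == 0 && is_organic_subset(el)) return el;
  std::string t = "[" + el;
  if (nH == 1) t += "H";
  else if (nH > 1) t += "H" + std::to_string(nH);
  if (charge > 0) t += (charge == 1 ? "+" : "+" + std::to_string(charge));
  if (charge < 0) t += (charge == -1 ? "-" : "-" + std::to_string(-charge));
  t += "]";
  return t;
}

std::string bond_symbol(int order) {
  switch (order) {
    case 2: return "=";
    case 3: return "#";
    case 4: return ":"; // aromatic bond order if ever present un-kekulized
    default: return "";
  }
}

// Dense re-ranking of arbitrary orderable keys: rank 0 = smallest.
template <typename T>
std::vector<int> dense_rank(const std::vector<T> &keys) {
  std::vector<T> uniq(keys);
  std::sort(uniq.begin(), uniq.end());
  uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
  std::vector<int> r(keys.size());
  for (size_t i = 0; i < keys.size(); ++i)
    r[i] = static_cast<int>(
        std::lower_bound(uniq.begin(), uniq.end(), keys[i]) - uniq.begin());
  return r;
}

// One round of Weisfeiler-Lehman refinement until the partition stabilizes.
void refine(const Graph &g, std::vector<int> &rank) {
  int classes = *std::max_element(rank.begin(), rank.end()) + 1;
  for (int iter = 0; iter < g.n + 2; ++iter) {
    std::vector<std::string> key(g.n);
    for (int v = 0; v < g.n; ++v) {
      std::vector<std::pair<int, int> > nb; // (order, neighbor rank)
      nb.reserve(g.adj[v].size());
      for (size_t e = 0; e < g.adj[v].size(); ++e)
        nb.push_back(std::make_pair(g.adj[v][e].second, rank[g.adj[v][e].first]));
      std::sort(nb.begin(), nb.end());
      std::string k = std::to_string(rank[v]);
      for (size_t e = 0; e < nb.size(); ++e)
        k += "|" + std::to_string(nb[e].first) + "," +
             std::to_string(nb[e].second);
      key[v] = k;
    }
    std::vector<int> nr = dense_rank(key);
    int nclasses = *std::max_element(nr.begin(), nr.end()) + 1;
    rank.swap(nr);
    if (nclasses == classes) break;
    classes = nclasses;
  }
}

// Emit the SMILES for a fully discrete ranking: depth-first traversal from
// the root, children in ascending rank, ring-closure bonds numbered in
// discovery order with the bond symbol written at both ends.
struct Writer {
  const Graph &g;
  const std::vector<int> &rank;
  std::vector<int> parent;
  std::vector<char> visited;
  std::vector<std::vector<int> > children;
  // ring closures per atom: (closure number, bond order)
  std::vector<std::vector<std::pair<int, int> > > closures;
  std::set<std::pair<int, int> > ring_edges;
  int next_ring;

  explicit Writer(const Graph &gg, const std::vector<int> &rk)
      : g(gg), rank(rk), parent(gg.n, -1), visited(gg.n, 0),
        children(gg.n), closures(gg.n), next_ring(1) {}

  std::vector<int> ordered_neighbors(int u) const {
    std::vector<int> nb;
    for (size_t e = 0; e < g.adj[u].size(); ++e) nb.push_back((int)e);
    std::vector<std::pair<int, int> > keyed;
    for (size_t e = 0; e < nb.size(); ++e)
      keyed.push_back(std::make_pair(rank[g.adj[u][nb[e]].first], nb[e]));
    std::sort(keyed.begin(), keyed.end());
    std::vector<int> out;
    for (size_t e = 0; e < keyed.size(); ++e) out.push_back(keyed[e].second);
    return out;
  }

  int bond_order(int u, int v) const {
    for (size_t e = 0; e < g.adj[u].size(); ++e)
      if (g.adj[u][e].first == v) return g.adj[u][e].second;
    return 1;
  }

  void discover(int root) { // pass 1: tree structure + ring closures
    visited[root] = 1;
    dfs(root);
  }

  void dfs(int u) {
    std::vector<int> nb = ordered_neighbors(u);
    for (size_t e = 0; e < nb.size(); ++e) {
      int v = g.adj[u][nb[e]].first;
      int order = g.adj[u][nb[e]].second;
      if (v == parent[u]) continue;
      std::pair<int, int> edge(std::min(u, v), std::max(u, v));
      if (visited[v]) {
        if (!ring_edges.count(edge)) {
          ring_edges.insert(edge);
          closures[v].push_back(std::make_pair(next_ring, order));
          closures[u].push_back(std::make_pair(next_ring, order));
          ++next_ring;
        }
        continue;
      }
      visited[v] = 1;
      parent[v] = u;
      children[u].push_back(v);
      dfs(v);
    }
  }

  std::string ring_digit(int num) const {
    if (num < 10) return std::to_string(num);
    return "%" + std::to_string(num);
  }

  std::string emit(int u) const {
    std::string s = g.token[u];
    for (size_t c = 0; c < closures[u].size(); ++c)
      s += bond_symbol(closures[u][c].second) + ring_digit(closures[u][c].first);
    for (size_t c = 0; c < children[u].size(); ++c) {
      int v = children[u][c];
      std::string branch = bond_symbol(bond_order(u, v)) + emit(v);
      if (c + 1 < children[u].size())
        s += "(" + branch + ")";
      else
        s += branch;
    }
    return s;
  }

  std::string write(int root) {
    discover(root);
    return emit(root);
  }
};

std::string write_smiles(const Graph &g, const std::vector<int> &rank,
                         int root) {
  Writer w(g, rank);
  return w.write(root);
}

// Canonical rooted SMILES: refine, then branch over symmetry cells taking
// the lexicographically smallest completion. `budget` caps the number of
// explored completions.
void canonical_branch(const Graph &g, std::vector<int> rank, int root,
                      std::string &best, int &budget) {
  refine(g, rank);
  // find the smallest-ranked cell with > 1 member (ranks are dense)
  int cell = -1;
  std::vector<int> members;
  const int maxr = *std::max_element(rank.begin(), rank.end());
  for (int r = 0; r <= maxr && cell == -1; ++r) {
    members.clear();
    for (int v = 0; v < g.n; ++v)
      if (rank[v] == r) members.push_back(v);
    if (members.size() > 1) cell = r;
  }
  if (cell == -1) {
    std::string s = write_smiles(g, rank, root);
    if (best.empty() || s < best) best = s;
    --budget;
    return;
  }
  if (budget <= static_cast<int>(members.size())) {
    // budget exhausted: break all remaining ties by subgraph index
    std::vector<std::pair<int, int> > keyed(g.n);
    for (int v = 0; v < g.n; ++v)
      keyed[v] = std::make_pair(rank[v] * (g.n + 1) + v, v);
    std::vector<int> flat(g.n);
    for (int v = 0; v < g.n; ++v) flat[v] = keyed[v].first;
    std::vector<int> dr = dense_rank(flat);
    std::string s = write_smiles(g, dr, root);
    if (best.empty() || s < best) best = s;
    --budget;
    return;
  }
  for (size_t m = 0; m < members.size(); ++m) {
    std::vector<int> r2(g.n);
    // promote members[m] below its cell; shift everything else up
    for (int v = 0; v < g.n; ++v)
      r2[v] = 2 * rank[v] + (v == members[m] ? 0 : 1);
    std::vector<int> dr = dense_rank(r2);
    canonical_branch(g, dr, root, best, budget);
    if (budget <= 0) break;
  }
}

std::string canonical_rooted_smiles(const Graph &g, int root) {
  // initial invariant: the written token (charge and H already inside it)
  std::vector<std::string> keys(g.n);
  for (int v = 0; v < g.n; ++v) keys[v] = g.token[v];
  std::vector<int> rank = dense_rank(keys);
  std::string best;
  int budget = 96;
  canonical_branch(g, rank, root, best, budget);
  return best;
}

// BFS shortest-path bond counts from one source; -1 where unreachable.
void bfs(const std::vector<std::vector<std::pair<int, int> > > &adj, int src,
         std::vector<int> &dist) {
  std::fill(dist.begin(), dist.end(), -1);
  std::queue<int> q;
  dist[src] = 0;
  q.push(src);
  while (!q.empty()) {
    int u = q.front();
    q.pop();
    for (size_t e = 0; e < adj[u].size(); ++e) {
      int v = adj[u][e].first;
      if (dist[v] == -1) {
        dist[v] = dist[u] + 1;
        q.push(v);
      }
    }
  }
}

Graph build_graph(Rcpp::CharacterVector elem, Rcpp::IntegerVector charge,
                  Rcpp::IntegerVector nH, Rcpp::IntegerMatrix bonds) {
  Graph g;
  g.n = elem.size();
  if (charge.size() != g.n || nH.size() != g.n)
    Rcpp::stop("atom attribute vectors differ in length");
  g.token.resize(g.n);
  g.adj.resize(g.n);
  for (int v = 0; v < g.n; ++v)
    g.token[v] =
        atom_token(Rcpp::as<std::string>(elem[v]), charge[v], nH[v]);
  for (int e = 0; e < bonds.nrow(); ++e) {
    int a = bonds(e, 0) - 1, b = bonds(e, 1) - 1, o = bonds(e, 2);
    if (a < 0 || b < 0 || a >= g.n || b >= g.n || a == b)
      Rcpp::stop("bond table refers to invalid atom indices");
    g.adj[a].push_back(std::make_pair(b, o));
    g.adj[b].push_back(std::make_pair(a, o));
  }
  return g;
}

// Induced subgraph of atoms within `radius` bonds of `center`.
Graph ball_subgraph(const Graph &g, const std::vector<int> &dist, int radius,
                    int center, int &new_root) {
  std::vector<int> keep;
  for (int v = 0; v < g.n; ++v)
    if (dist[v] >= 0 && dist[v] <= radius) keep.push_back(v);
  std::vector<int> newid(g.n, -1);
  for (size_t i = 0; i < keep.size(); ++i) newid[keep[i]] = (int)i;
  Graph s;
  s.n = (int)keep.size();
  s.token.resize(s.n);
  s.adj.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    int v = keep[i];
    s.token[i] = g.token[v];
    for (size_t e = 0; e < g.adj[v].size(); ++e) {
      int w = g.adj[v][e].first;
      if (newid[w] >= 0)
        s.adj[i].push_back(std::make_pair(newid[w], g.adj[v][e].second));
    }
  }
  new_root = newid[center];
  return s;
}

std::string env_smiles_one(const Graph &g, int center, int radius) {
  std::vector<int> dist(g.n);
  bfs(g.adj, center, dist);
  int root;
  Graph s = ball_subgraph(g, dist, radius, center, root);
  return canonical_rooted_smiles(s, root);
}

} // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_topo_dist")]]
Rcpp::IntegerMatrix cpp_topo_dist(int n_atoms, Rcpp::IntegerMatrix bonds) {
  std::vector<std::vector<std::pair<int, int> > > adj(n_atoms);
  for (int e = 0; e < bonds.nrow(); ++e) {
    int a = bonds(e, 0) - 1, b = bonds(e, 1) - 1;
    if (a < 0 || b < 0 || a >= n_atoms || b >= n_atoms)
      Rcpp::stop("bond table refers to invalid atom indices");
    adj[a].push_back(std::make_pair(b, bonds(e, 2)));
    adj[b].push_back(std::make_pair(a, bonds(e, 2)));
  }
  Rcpp::IntegerMatrix out(n_atoms, n_atoms);
  std::vector<int> dist(n_atoms);
  for (int v = 0; v < n_atoms; ++v) {
    bfs(adj, v, dist);
    for (int w = 0; w < n_atoms; ++w)
      out(v, w) = (dist[w] == -1 ? NA_INTEGER : dist[w]);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = "cpp_env_smiles")]]
Rcpp::String cpp_env_smiles(Rcpp::CharacterVector elem,
                            Rcpp::IntegerVector charge,
                            Rcpp::IntegerVector nH,
                            Rcpp::IntegerMatrix bonds, int center,
                            int radius) {
  Graph g = build_graph(elem, charge, nH, bonds);
  if (center < 1 || center > g.n)
    Rcpp::stop("atom index out of range");
  if (radius < 1) Rcpp::stop("radius must be >= 1");
  return env_smiles_one(g, center - 1, radius);
}

//' @noRd
// [[Rcpp::export(name = "cpp_shingles")]]
Rcpp::CharacterVector cpp_shingles(Rcpp::CharacterVector elem,
                                   Rcpp::IntegerVector charge,
                                   Rcpp::IntegerVector nH,
                                   Rcpp::IntegerMatrix bonds, int r,
                                   bool include_distance) {
  if (r < 1) Rcpp::stop("radius parameter r must be >= 1");
  Graph g = build_graph(elem, charge, nH, bonds);
  const int n = g.n;
  // all env SMILES: env[rad-1][atom]
  std::vector<std::vector<std::string> > env(
      r, std::vector<std::string>(n));
  for (int v = 0; v < n; ++v) {
    std::vector<int> dist(n);
    bfs(g.adj, v, dist);
    for (int rad = 1; rad <= r; ++rad) {
      int root;
      Graph s = ball_subgraph(g, dist, rad, v, root);
      env[rad - 1][v] = canonical_rooted_smiles(s, root);
    }
  }
  // pairwise distances
  std::set<std::string> shingles;
  std::vector<int> dist(n);
  for (int j = 0; j < n; ++j) {
    bfs(g.adj, j, dist);
    for (int k = j + 1; k < n; ++k) {
      if (dist[k] < 0) continue; // different fragments: no shingle
      for (int rad = 1; rad <= r; ++rad) {
        const std::string &a = env[rad - 1][j];
        const std::string &b = env[rad - 1][k];
        const std::string &lo = (a <= b) ? a : b;
        const std::string &hi = (a <= b) ? b : a;
        if (include_distance)
          shingles.insert(lo + "|" + std::to_string(dist[k]) + "|" + hi);
        else
          shingles.insert(lo + "|" + hi);
      }
    }
  }
  return Rcpp::wrap(shingles); // sorted: std::set iteration order
}
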