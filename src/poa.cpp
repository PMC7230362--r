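#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// Partial order alignment (POA) graph with progressive sequence insertion and
// heaviest-path consensus. Each sequence is aligned to the growing DAG with a
// global (Needleman-Wunsch) dynamic program over the graph's topological
// order: matched positions reuse nodes (or their "aligned ring"
// alternatives), unmatched positions add nodes, and every edge counts the
// sequences traversing it. The sequence aligns globally; graph ends are
// free, since the graph accumulates the union of all reads' ragged ends.
// Score ties prefer the alignment with fewer gaps (a one-base shift that
// trades mismatches for an indel pair must not scramble columns).
//
// The consensus is the path maximising the total re-centred edge weight
// sum((8*w - n)) where n is the number of sequences: transitions carried by
// more than an eighth of the sequences contribute positively. Re-centring
// removes the length bias of a plain heaviest path (a split vote cannot be
// harvested twice via a detour) and weakly supported end branches exclude
// themselves because the maximum-sum subpath stops before them; the 1/8
// pivot deliberately biases drafts long (see consensus_path). Ties prefer
// the larger accumulated node support, then the smaller node id, making the
// result deterministic and, for gap-free equal-length inputs with clear
// majorities, equal to per-column majority voting.

namespace {

const int NEG = std::numeric_limits<int>::min() / 4;

struct PoaGraph {
  std::vector<char> base;
  std::vector<int> support;              // sequences whose path uses the node
  std::vector<std::vector<int>> preds;   // unique in-edge sources
  std::vector<std::vector<int>> succs;   // unique out-edge targets
  std::vector<std::unordered_map<int, int>> w;  // u -> (v -> weight)
  std::vector<std::vector<int>> ring;    // aligned alternatives (other nodes)

  int n() const { return (int) base.size(); }

  int new_node(char c) {
    base.push_back(c);
    support.push_back(0);
    preds.emplace_back();
    succs.emplace_back();
    w.emplace_back();
    ring.emplace_back();
    return n() - 1;
  }

  void add_edge(int u, int v) {
    auto it = w[u].find(v);
    if (it == w[u].end()) {
      w[u][v] = 1;
      preds[v].push_back(u);
      succs[u].push_back(v);
    } else {
      ++(it->second);
    }
  }

  std::vector<int> topo_order() const {
    std::vector<int> indeg(n());
    for (int v = 0; v < n(); ++v) indeg[v] = (int) preds[v].size();
    std::vector<int> order;
    order.reserve(n());
    std::vector<int> stack;
    for (int v = n() - 1; v >= 0; --v)
      if (indeg[v] == 0) stack.push_back(v);  // reversed so smallest id pops first
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      order.push_back(u);
      for (int v : succs[u])
        if (--indeg[v] == 0) stack.push_back(v);
    }
    return order;
  }
};

// Align sequence to graph (global) and merge it in.
void insert_sequence(PoaGraph &g, const std::string &s,
                     int match, int mismatch, int gap) {
  const int L = (int) s.size();
  if (L == 0) return;
  if (g.n() == 0) {
    int prev = -1;
    for (char c : s) {
      int v = g.new_node(c);
      g.support[v] = 1;
      if (prev >= 0) g.add_edge(prev, v);
      prev = v;
    }
    return;
  }

  const int V = g.n();
  std::vector<int> order = g.topo_order();
  std::vector<int> score((size_t) V * (L + 1), NEG);
  std::vector<int> ngap((size_t) V * (L + 1), 0);
  std::vector<unsigned char> move((size_t) V * (L + 1), 0);  // 1 diag, 2 up, 3 left
  std::vector<int> pred((size_t) V * (L + 1), -2);
  auto idx = [&](int v, int j) { return (size_t) v * (L + 1) + j; };

  for (int v : order) {
    for (int j = 0; j <= L; ++j) {
      int best = NEG, bestg = 0;
      unsigned char bm = 0;
      int bp = -2;
      auto consider = [&](int sc, int gp, unsigned char mv, int pp) {
        if (sc > best || (sc == best && gp < bestg)) {
          best = sc; bestg = gp; bm = mv; bp = pp;
        }
      };
      if (j >= 1) {
        // diagonal: v consumed against s[j-1]. The graph prefix before v is
        // free (reads may start anywhere in the graph) but a real
        // predecessor beats a fresh start on ties, so end mismatches stay
        // aligned to existing columns instead of spawning insertions.
        int sub = (g.base[v] == s[j - 1]) ? match : mismatch;
        int b = gap * (j - 1), bg = j - 1;
        int bpp = -1;
        for (int p : g.preds[v]) {
          int sc = score[idx(p, j - 1)], gp = ngap[idx(p, j - 1)];
          if (sc > b || (sc == b && gp <= bg)) { b = sc; bg = gp; bpp = p; }
        }
        consider(b + sub, bg, 1, bpp);
        // left: s[j-1] inserted after current state at v
        consider(score[idx(v, j - 1)] + gap, ngap[idx(v, j - 1)] + 1, 3, -2);
      }
      {
        // up: v consumed against a gap in the sequence
        int b = gap * j, bg = j;
        int bpp = -1;
        for (int p : g.preds[v]) {
          int sc = score[idx(p, j)], gp = ngap[idx(p, j)];
          if (sc > b || (sc == b && gp <= bg)) { b = sc; bg = gp; bpp = p; }
        }
        consider(b + gap, bg + 1, 2, bpp);
      }
      score[idx(v, j)] = best;
      ngap[idx(v, j)] = bestg;
      move[idx(v, j)] = bm;
      pred[idx(v, j)] = bp;
    }
  }

  // alignment end: the graph suffix is free; ties prefer fewer gaps, then
  // the topologically latest node so the final graph column is consumed
  // rather than ending early on a trailing insertion
  std::vector<int> rank(V);
  for (int r = 0; r < V; ++r) rank[order[r]] = r;
  int vb = -1, sb = NEG, gb = 0;
  for (int v = 0; v < V; ++v) {
    int sc = score[idx(v, L)];
    int gp = ngap[idx(v, L)];
    if (vb < 0 || sc > sb || (sc == sb && gp < gb) ||
        (sc == sb && gp == gb && rank[v] > rank[vb])) {
      sb = sc; gb = gp; vb = v;
    }
  }

  // traceback into (graph node, seq pos) event list; -1 marks a gap side
  std::vector<std::pair<int, int>> events;
  int v = vb, j = L;
  bool done = false;
  while (!done) {
    unsigned char mv = move[idx(v, j)];
    int p = pred[idx(v, j)];
    if (mv == 1) {
      events.push_back(std::make_pair(v, j - 1));
      --j;
      if (p == -1) {
        while (j > 0) { events.push_back(std::make_pair(-1, j - 1)); --j; }
        done = true;
      } else v = p;
    } else if (mv == 2) {
      events.push_back(std::make_pair(v, -1));
      if (p == -1) {
        while (j > 0) { events.push_back(std::make_pair(-1, j - 1)); --j; }
        done = true;
      } else v = p;
    } else if (mv == 3) {
      events.push_back(std::make_pair(-1, j - 1));
      --j;
    } else {
      done = true;
    }
  }
  std::reverse(events.begin(), events.end());

  // merge: build the sequence's node chain
  int prev = -1;
  for (size_t k = 0; k < events.size(); ++k) {
    int gv = events[k].first, sj = events[k].second;
    if (sj < 0) continue;  // graph node skipped by the sequence
    char c = s[sj];
    int node;
    if (gv >= 0) {
      if (g.base[gv] == c) {
        node = gv;
      } else {
        node = -1;
        for (int r : g.ring[gv])
          if (g.base[r] == c) { node = r; break; }
        if (node < 0) {
          node = g.new_node(c);
          std::vector<int> members = g.ring[gv];
          members.push_back(gv);
          for (int r : members) {
            g.ring[r].push_back(node);
            g.ring[node].push_back(r);
          }
        }
      }
    } else {
      node = g.new_node(c);
    }
    g.support[node] += 1;
    if (prev >= 0) g.add_edge(prev, node);
    prev = node;
  }
}

// Column-wise majority consensus over the graph. Aligned rings are collapsed
// into columns (so a column's vote is not fragmented across its base
// alternatives), transition weights between columns are aggregated over all
// member edges, and the consensus is the maximum-sum column path under
// re-centred weights (2*W - n_seqs > 0 iff a majority of sequences make the
// transition). A deletion bypass or insertion detour therefore only enters
// the consensus when more than half the sequences take it, weakly supported
// end branches drop out of the maximum-sum subpath on their own, and each
// chosen column emits its best-supported base -- per-column majority voting,
// generalised to the partial order graph.
std::vector<int> consensus_path(const PoaGraph &g, int n_seqs) {
  const int V = g.n();
  std::vector<int> order = g.topo_order();

  // column id = smallest node id in the aligned ring (rings are cliques);
  // votes for "the consensus passes through this column" are pooled across
  // the ring's base alternatives so that substitution variants do not
  // fragment the transition weight a deletion bypass competes against
  std::vector<int> col(V);
  for (int v = 0; v < V; ++v) {
    int c = v;
    for (int r : g.ring[v]) c = std::min(c, r);
    col[v] = c;
  }

  std::vector<long long> cum(V, 0), supp(V, 0);
  std::vector<int> back(V, -1);
  for (int v : order) {
    long long best = 0, bsupp = 0;  // starting fresh at v is always allowed
    int bp = -1;
    // group in-edges by source column, aggregate their weights
    std::vector<int> ps = g.preds[v];
    std::sort(ps.begin(), ps.end());
    std::unordered_map<int, long long> colw;
    for (int p : ps) colw[col[p]] += g.w[p].at(v);
    for (int p : ps) {
      // representative of its column: the member with the best continuation
      bool rep = true;
      for (int q : ps) {
        if (q == p || col[q] != col[p]) continue;
        if (cum[q] > cum[p] || (cum[q] == cum[p] && supp[q] > supp[p]) ||
            (cum[q] == cum[p] && supp[q] == supp[p] && q < p)) {
          rep = false;
          break;
        }
      }
      if (!rep) continue;
      // transitions are re-centred at an eighth of the sequences rather
      // than half: the draft deliberately errs long (a deletion bypass
      // needs >62% support to enter, an insertion detour >37%), because
      // the downstream pileup polishing step removes unsupported bases far
      // more reliably than it can restore missing ones
      long long c = cum[p] + 8LL * colw[col[p]] - n_seqs;
      if (c > best || (c == best && supp[p] > bsupp) ||
          (c == best && supp[p] == bsupp && bp >= 0 && p < bp)) {
        best = c; bsupp = supp[p]; bp = p;
      }
    }
    cum[v] = best;
    supp[v] = bsupp + g.support[v];
    back[v] = bp;
  }
  int end = 0;
  for (int v = 1; v < V; ++v)
    if (cum[v] > cum[end] ||
        (cum[v] == cum[end] && supp[v] > supp[end])) end = v;

  // walk back, emitting each visited column's best-supported base
  std::vector<int> path;
  for (int v = end; v >= 0; v = back[v]) {
    int bestn = v;
    for (int r : g.ring[v]) {
      if (g.support[r] > g.support[bestn] ||
          (g.support[r] == g.support[bestn] && r < bestn)) bestn = r;
    }
    path.push_back(bestn);
  }
  std::reverse(path.begin(), path.end());
  return path;
}

}  // namespace

// graph dump for diagnostics: nodes, edges with weights, consensus path
// [[Rcpp::export]]
List cpp_poa_debug(std::vector<std::string> seqs,
                   int match = 2, int mismatch = -4, int gap = -6) {
  PoaGraph g;
  for (const std::string &s : seqs) insert_sequence(g, s, match, mismatch, gap);
  std::vector<int> from, to, wt;
  for (int u = 0; u < g.n(); ++u)
    for (int v : g.succs[u]) {
      from.push_back(u); to.push_back(v); wt.push_back(g.w[u].at(v));
    }
  std::vector<int> path = consensus_path(g, (int) seqs.size());
  return List::create(_["base"] = std::string(g.base.begin(), g.base.end()),
                      _["support"] = g.support,
                      _["from"] = from, _["to"] = to, _["w"] = wt,
                      _["path"] = path);
}

// [[Rcpp::export]]
List cpp_poa_consensus(std::vector<std::string> seqs,
                       int match = 2, int mismatch = -4, int gap = -6) {
  if (seqs.empty()) stop("at least one sequence is required");
  PoaGraph g;
  for (const std::string &s : seqs) insert_sequence(g, s, match, mismatch, gap);
  if (g.n() == 0) stop("all sequences are empty");

  std::vector<int> path = consensus_path(g, (int) seqs.size());
  std::string out;
  for (int v : path) out.push_back(g.base[v]);
  return List::create(_["consensus"] = out,
                      _["n_nodes"] = g.n(),
                      _["n_seqs"] = (int) seqs.size());
}
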