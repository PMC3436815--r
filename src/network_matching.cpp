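#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Network matching: affine-gap local alignment between a de Bruijn contig
// graph and a linear reference.  Three matrices per contig position:
//   S(i,j,v) best local alignment ending with i_v aligned to t_j
//   I(i,j,v) ... ending with t_j aligned to a gap (insertion in reference)
//   D(i,j,v) ... ending with i_v aligned to a gap (deletion of graph base)
// Contig junctions: an edge l->v means suffix_{k-1}(l) == prefix_{k-1}(v);
// the spelled path carries those k-1 bases once, represented here by v's
// prefix.  Cross-edge moves therefore leave l at position eff(l) = len(l)-(k-1)
// and enter v at position 1, so every spelled base is scored exactly once.
//
// Move codes (stored one byte per cell per matrix; bits 0-2 the move, bits
// 3-4 the source matrix for diagonal moves: 0=S 1=D 2=I):
//   0 none/floor, 1 fresh-start diagonal, 2 within-contig diagonal,
//   3 cross-edge diagonal, 4 gap-open, 5 gap-extend,
//   6 cross gap-open, 7 cross gap-extend
// Predecessor node ids for cross moves are kept in per-(node, j) arrays
// (cross moves only enter at i == 1).

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List nm_align_cpp(CharacterVector seqs_, IntegerVector edge_from,
                  IntegerVector edge_to, int k, std::string ref,
                  int sc_match, int sc_mismatch, int go, int ge) {
  const int n = seqs_.size();
  const int m = (int) ref.size();
  std::vector<std::string> seqs(n);
  std::vector<int> len(n), eff(n), off(n);
  long total = 0;
  for (int v = 0; v < n; ++v) {
    seqs[v] = as<std::string>(seqs_[v]);
    len[v] = (int) seqs[v].size();
    eff[v] = len[v] - (k - 1);
    off[v] = (int) total;
    total += len[v];
  }

  // adjacency (in-edges per node), edges given 0-based
  const int ne = edge_from.size();
  std::vector<std::vector<int>> in_edges(n), out_edges(n);
  for (int e = 0; e < ne; ++e) {
    int u = edge_from[e], v = edge_to[e];
    out_edges[u].push_back(v);
    in_edges[v].push_back(u);
  }
  for (int v = 0; v < n; ++v) {
    std::sort(in_edges[v].begin(), in_edges[v].end());
    std::sort(out_edges[v].begin(), out_edges[v].end());
  }

  // topological order by iterative DFS from in-degree-0 roots (smallest id
  // first), then any unvisited node; back edges (to a gray node) are noted
  // and excluded from same-column propagation.
  std::vector<int> color(n, 0); // 0 white 1 gray 2 black
  std::vector<int> topo; topo.reserve(n);
  std::vector<std::pair<int,int>> back_edges;
  std::vector<int> roots;
  for (int v = 0; v < n; ++v) if (in_edges[v].empty()) roots.push_back(v);
  for (int v = 0; v < n; ++v) roots.push_back(v); // fallback for cycles
  for (int r : roots) {
    if (color[r] != 0) continue;
    std::vector<std::pair<int,int>> st; // (node, next out index)
    st.push_back({r, 0});
    color[r] = 1;
    while (!st.empty()) {
      int u = st.back().first;
      int &ix = st.back().second;
      if (ix < (int) out_edges[u].size()) {
        int w = out_edges[u][ix++];
        if (color[w] == 0) { color[w] = 1; st.push_back({w, 0}); }
        else if (color[w] == 1) back_edges.push_back({u, w});
      } else {
        color[u] = 2;
        topo.push_back(u);
        st.pop_back();
      }
    }
  }
  std::reverse(topo.begin(), topo.end());

  auto is_back = [&](int u, int v) {
    for (auto &p : back_edges) if (p.first == u && p.second == v) return true;
    return false;
  };

  const long ncell = total * (long)(m + 1);
  std::vector<int> S(ncell, 0), I(ncell, 0), D(ncell, 0);
  std::vector<unsigned char> SM(ncell, 0), IM(ncell, 0), DM(ncell, 0);
  const long nbound = (long) n * (m + 1);
  std::vector<int> SP(nbound, -1), DP(nbound, -1); // cross-move predecessors
  // column 0 is all zero (paper initialisation); I/D column 0 = 0 as well —
  // harmless since S's floor dominates any gap-led prefix.

  int best = 0, best_v = -1, best_i = -1, best_j = -1;

  for (int j = 1; j <= m; ++j) {
    const char tj = ref[j - 1];
    for (int t = 0; t < n; ++t) {
      const int v = topo[t];
      const char *sv = seqs[v].c_str();
      const long base = (long) off[v] * (m + 1);
      const long bnd = (long) v * (m + 1) + j;
      // --- i == 1 boundary cell
      {
        const long c = base + j;          // (v, i=1, j)
        const long cL = c - 1;            // (v, i=1, j-1)
        // I: consume t_j at fixed graph position
        {
          int open_v = S[cL] + go, ext_v = I[cL] + ge;
          if (open_v >= ext_v) { I[c] = open_v; IM[c] = 4; }
          else                 { I[c] = ext_v;  IM[c] = 5; }
        }
        // D: enter v's first base as a gap, from a predecessor junction
        {
          int bestd = NEG; unsigned char bm = 0; int bp = -1;
          for (int l : in_edges[v]) {
            if (eff[l] < 1) continue;
            if (is_back(l, v)) continue; // back edges feed S's diagonal only
            const long p = ((long) off[l] + eff[l] - 1) * (m + 1) + j;
            int open_v = S[p] + go, ext_v = D[p] + ge;
            if (open_v > bestd) { bestd = open_v; bm = 6; bp = l; }
            if (ext_v  > bestd) { bestd = ext_v;  bm = 7; bp = l; }
          }
          D[c] = bestd; DM[c] = bm; DP[bnd] = bp;
        }
        // S: fresh start or cross-edge diagonal
        const char a = sv[0];
        const int gg = (a == tj && a != 'N') ? sc_match : sc_mismatch;
        int bests = 0; unsigned char sm = 0; int sp = -1;
        if (gg > bests) { bests = gg; sm = 1; }
        for (int l : in_edges[v]) { // smallest id first (sorted)
          if (eff[l] < 1) continue;
          const long p = ((long) off[l] + eff[l] - 1) * (m + 1) + (j - 1);
          int cand = S[p] + gg;
          if (cand > bests) { bests = cand; sm = 3; sp = l; }
          cand = D[p] + gg;
          if (cand > bests) { bests = cand; sm = (unsigned char)(3 | (1 << 3)); sp = l; }
          cand = I[p] + gg;
          if (cand > bests) { bests = cand; sm = (unsigned char)(3 | (2 << 3)); sp = l; }
        }
        S[c] = bests; SM[c] = sm; SP[bnd] = sp;
        if (bests > best) { best = bests; best_v = v; best_i = 1; best_j = j; }
      }
      // --- i > 1: ordinary Smith-Waterman recurrences within the contig
      for (int i = 2; i <= len[v]; ++i) {
        const long c = base + (long)(i - 1) * (m + 1) + j;
        const long cL = c - 1;                 // (i, j-1)
        const long cU = c - (m + 1);           // (i-1, j)
        const long cD = cU - 1;                // (i-1, j-1)
        {
          int open_v = S[cL] + go, ext_v = I[cL] + ge;
          if (open_v >= ext_v) { I[c] = open_v; IM[c] = 4; }
          else                 { I[c] = ext_v;  IM[c] = 5; }
        }
        {
          int open_v = S[cU] + go, ext_v = D[cU] + ge;
          if (open_v >= ext_v) { D[c] = open_v; DM[c] = 4; }
          else                 { D[c] = ext_v;  DM[c] = 5; }
        }
        const char a = sv[i - 1];
        const int gg = (a == tj && a != 'N') ? sc_match : sc_mismatch;
        int bests = 0; unsigned char sm = 0;
        int cand = S[cD] + gg;                 // tie preference S > D > I
        if (cand > bests) { bests = cand; sm = 2; }
        cand = D[cD] + gg;
        if (cand > bests) { bests = cand; sm = (unsigned char)(2 | (1 << 3)); }
        cand = I[cD] + gg;
        if (cand > bests) { bests = cand; sm = (unsigned char)(2 | (2 << 3)); }
        S[c] = bests; SM[c] = sm;
        if (bests > best) { best = bests; best_v = v; best_i = i; best_j = j; }
      }
    }
  }

  if (best < 1) {
    return List::create(_["score"] = 0);
  }

  // ---- traceback from the best S cell until score 0
  std::string ops;            // per-column, reversed at the end: = X I D
  std::vector<int> chain;     // node ids visited, reversed at the end
  std::vector<int> visits(n, 0);
  int cv = best_v, ci = best_i, cj = best_j;
  int mat = 0; // 0=S 1=D 2=I
  chain.push_back(cv); visits[cv] = 1;
  int first_i = best_i;  // contig position of the earliest graph-consuming column
  int first_j = best_j;  // reference position of the earliest ref-consuming column
  bool truncated = false, done = false;

  auto cell = [&](int v, int i, int j) -> long {
    return ((long) off[v] + i - 1) * (m + 1) + j;
  };
  auto bound = [&](int v, int j) -> long { return (long) v * (m + 1) + j; };

  while (!done) {
    const long c = cell(cv, ci, cj);
    if (mat == 0) {
      if (S[c] <= 0) break;               // reached a score of 0
      const unsigned char code = SM[c] & 7, src = SM[c] >> 3;
      const char a = seqs[cv][ci - 1];
      ops.push_back((a == ref[cj - 1] && a != 'N') ? '=' : 'X');
      first_i = ci; first_j = cj;
      if (code == 1) { done = true; }     // fresh start: alignment begins here
      else if (code == 2) { ci -= 1; cj -= 1; mat = src; }
      else if (code == 3) {               // cross diagonal into predecessor
        const int l = SP[bound(cv, cj)];
        if (++visits[l] > 2) { truncated = true; done = true; }
        else { chain.push_back(l); cv = l; ci = eff[l]; cj -= 1; mat = src; }
      } else done = true;                 // floor (defensive)
    } else if (mat == 1) { // D: consumed graph base, gap in reference
      const unsigned char code = DM[c] & 7;
      ops.push_back('D');
      first_i = ci;
      if (code == 4)      { ci -= 1; mat = 0; }
      else if (code == 5) { ci -= 1; mat = 1; }
      else if (code == 6 || code == 7) {
        const int l = DP[bound(cv, cj)];
        if (++visits[l] > 2) { truncated = true; break; }
        chain.push_back(l);
        cv = l; ci = eff[l]; mat = (code == 6) ? 0 : 1;
      } else stop("inconsistent DP state in traceback");
    } else { // I: consumed reference base, gap in graph
      const unsigned char code = IM[c] & 7;
      ops.push_back('I');
      first_j = cj;
      cj -= 1; mat = (code == 4) ? 0 : 2;
    }
  }

  std::reverse(ops.begin(), ops.end());
  std::reverse(chain.begin(), chain.end());

  int nmatch = 0;
  for (char o : ops) if (o == '=') ++nmatch;

  return List::create(
    _["score"] = best,
    _["chain"] = IntegerVector(chain.begin(), chain.end()),
    _["ops"] = ops,
    _["i_start"] = first_i,
    _["i_end"] = best_i,
    _["j_start"] = first_j,
    _["j_end"] = best_j,
    _["n_match"] = nmatch,
    _["truncated"] = truncated,
    _["n_back_edges"] = (int) back_edges.size());
}
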