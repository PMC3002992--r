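#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Successor table for a residual network of m free genes, one rule per gene.
// Rules are given as bitmasks over the free-gene bits (bit g = gene g, LSB
// first): next(g) = (act_const[g] || (s & act_mask[g])) && !(s & inh_mask[g]).
// Clamped/fixed genes must already have been folded into the masks.
// [[Rcpp::export]]
IntegerVector bn_succ_table(int m, IntegerVector act_mask, IntegerVector inh_mask,
                            LogicalVector act_const) {
  if (m < 0 || m > 28)
    stop("successor table supports at most 28 free genes (got %d)", m);
  if (act_mask.size() != m || inh_mask.size() != m || act_const.size() != m)
    stop("rule vectors must have length m");
  R_xlen_t N = (R_xlen_t)1 << m;
  IntegerVector succ(N);
  for (R_xlen_t s = 0; s < N; ++s) {
    int ns = 0;
    for (int g = 0; g < m; ++g) {
      bool on = (act_const[g] || ((int)s & act_mask[g])) && !((int)s & inh_mask[g]);
      if (on) ns |= (1 << g);
    }
    succ[s] = ns;
  }
  return succ;
}

// All limit cycles of a deterministic successor map, found by pointer-chasing
// with colouring: every state is visited at most twice, each walk is tagged
// with a fresh colour, and a walk that re-enters its own colour has closed a
// new cycle. Returns a list of integer state-vectors, each rotated so the
// numerically smallest state comes first.
// [[Rcpp::export]]
List bn_cycles_chase(IntegerVector succ) {
  R_xlen_t N = succ.size();
  std::vector<int> color(N, 0);
  std::vector<int> path;
  std::vector< std::vector<int> > cycles;
  int comp = 0;
  for (R_xlen_t s0 = 0; s0 < N; ++s0) {
    if (color[s0]) continue;
    ++comp;
    path.clear();
    int s = (int)s0;
    while (color[s] == 0) {
      color[s] = comp;
      path.push_back(s);
      s = succ[s];
      if (s < 0 || s >= N) stop("successor out of range");
    }
    if (color[s] == comp) {
      size_t j = 0;
      while (path[j] != s) ++j;
      cycles.push_back(std::vector<int>(path.begin() + j, path.end()));
    }
  }
  List out(cycles.size());
  for (size_t i = 0; i < cycles.size(); ++i) {
    std::vector<int> &c = cycles[i];
    size_t mi = std::min_element(c.begin(), c.end()) - c.begin();
    std::rotate(c.begin(), c.begin() + mi, c.end());
    out[i] = IntegerVector(c.begin(), c.end());
  }
  return out;
}

// Same cycles by a set-based route: iterate the image operator on the full
// state set. Starting from S0 = all states, F(S) = {succ(s) : s in S} is a
// decreasing sequence whose fixpoint is exactly the union of all limit
// cycles; the restriction of succ to that set is a permutation, which is
// then decomposed into its disjoint cycles.
// [[Rcpp::export]]
List bn_cycles_image(IntegerVector succ) {
  R_xlen_t N = succ.size();
  std::vector<char> cur(N, 1), nxt(N, 0);
  R_xlen_t size = N;
  for (;;) {
    std::fill(nxt.begin(), nxt.end(), 0);
    R_xlen_t ns = 0;
    for (R_xlen_t s = 0; s < N; ++s)
      if (cur[s]) {
        int t = succ[s];
        if (!nxt[t]) { nxt[t] = 1; ++ns; }
      }
    cur.swap(nxt);
    if (ns == size) break;  // decreasing sequence: equal size => fixpoint
    size = ns;
  }
  std::vector<char> seen(N, 0);
  std::vector< std::vector<int> > cycles;
  for (R_xlen_t s0 = 0; s0 < N; ++s0) {
    if (!cur[s0] || seen[s0]) continue;
    std::vector<int> c;
    int s = (int)s0;
    while (!seen[s]) {
      seen[s] = 1;
      c.push_back(s);
      s = succ[s];
    }
    cycles.push_back(c);
  }
  List out(cycles.size());
  for (size_t i = 0; i < cycles.size(); ++i) {
    std::vector<int> &c = cycles[i];
    size_t mi = std::min_element(c.begin(), c.end()) - c.begin();
    std::rotate(c.begin(), c.begin() + mi, c.end());
    out[i] = IntegerVector(c.begin(), c.end());
  }
  return out;
}
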