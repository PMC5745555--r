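// Cograph (P4-free) utilities and a global-alignment identity kernel.
//
// Orthology relations correspond to cographs, i.e. graphs with no induced
// path on four vertices (P4).  Similarity graphs built from thresholded
// sequence identity can violate this; they are repaired by a minimum number
// of edge insertions/deletions.  Minimum cograph editing is NP-hard, but the
// candidate graphs here are small, so an exact bounded search is practical.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <climits>
#include <cstdint>
using namespace Rcpp;

typedef std::vector<uint64_t> BitAdj; // one 64-bit neighbourhood mask per vertex

static BitAdj to_bits(const LogicalMatrix &adj) {
  int n = adj.nrow();
  BitAdj nb(n, 0u);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && adj(i, j)) nb[i] |= (1ull << j);
  return nb;
}

// Find one induced P4 a-b-c-d; returns true and fills out[4] (0-based).
// {b,c} is the middle edge; a attaches to b only, d to c only, ad absent.
static bool find_p4(const BitAdj &nb, int n, int out[4]) {
  for (int b = 0; b < n; ++b) {
    for (int c = b + 1; c < n; ++c) {
      if (!(nb[b] & (1ull << c))) continue;
      uint64_t A = nb[b] & ~nb[c] & ~(1ull << c);
      uint64_t D = nb[c] & ~nb[b] & ~(1ull << b);
      if (!A || !D) continue;
      for (int a = 0; a < n; ++a) {
        if (!(A & (1ull << a))) continue;
        uint64_t Dok = D & ~nb[a] & ~(1ull << a);
        if (Dok) {
          int d = 0; while (!(Dok & (1ull << d))) ++d;
          out[0] = a; out[1] = b; out[2] = c; out[3] = d;
          return true;
        }
      }
    }
  }
  return false;
}

// [[Rcpp::export]]
bool cpp_is_cograph(LogicalMatrix adj) {
  int n = adj.nrow();
  if (n > 63) stop("cpp_is_cograph supports at most 63 vertices");
  BitAdj nb = to_bits(adj);
  int p4[4];
  return !find_p4(nb, n, p4);
}

// [[Rcpp::export]]
IntegerVector cpp_find_p4(LogicalMatrix adj) {
  int n = adj.nrow();
  if (n > 63) stop("cpp_find_p4 supports at most 63 vertices");
  BitAdj nb = to_bits(adj);
  int p4[4];
  if (!find_p4(nb, n, p4))
    return IntegerVector(0);
  return IntegerVector::create(p4[0] + 1, p4[1] + 1, p4[2] + 1, p4[3] + 1);
}

static int count_p4(const BitAdj &nb, int n) {
  int cnt = 0;
  for (int b = 0; b < n; ++b)
    for (int c = b + 1; c < n; ++c) {
      if (!(nb[b] & (1ull << c))) continue;
      uint64_t A = nb[b] & ~nb[c] & ~(1ull << c);
      uint64_t D = nb[c] & ~nb[b] & ~(1ull << b);
      if (!A || !D) continue;
      for (int a = 0; a < n; ++a) {
        if (!(A & (1ull << a))) continue;
        uint64_t Dok = D & ~nb[a] & ~(1ull << a);
        cnt += __builtin_popcountll(Dok);
      }
    }
  return cnt;
}

// [[Rcpp::export]]
int cpp_count_p4(LogicalMatrix adj) {
  int n = adj.nrow();
  if (n > 63) stop("cpp_count_p4 supports at most 63 vertices");
  BitAdj nb = to_bits(adj);
  return count_p4(nb, n);
}

// ---------------------------------------------------------------------------
// Exact editing: iterative deepening over edit budgets.  Branch on an induced
// P4: any repair must flip at least one of its six vertex pairs.  Flipped
// pairs are locked along a search path so each edit set is explored once.
// Among all minimum-size solutions the reported one prefers insertions over
// deletions, then the lexicographically smallest sorted pair list.

struct EditSearch {
  int n;
  BitAdj nb;
  std::vector<uint64_t> locked; // per-vertex mask of pairs fixed on this path
  std::vector<std::array<int, 3>> cur;       // (i, j, +1 insert / -1 delete)
  std::vector<std::vector<std::array<int, 3>>> sols;

  void flip(int i, int j) {
    nb[i] ^= (1ull << j);
    nb[j] ^= (1ull << i);
  }

  void dfs(int k) {
    int p4[4];
    if (!find_p4(nb, n, p4)) {
      if (k == 0) sols.push_back(cur); // only collect exact-size solutions
      return;
    }
    if (k == 0) return;
    // the six vertex pairs of the P4, in deterministic order
    for (int x = 0; x < 4; ++x)
      for (int y = x + 1; y < 4; ++y) {
        int i = p4[x], j = p4[y];
        if (i > j) std::swap(i, j);
        if (locked[i] & (1ull << j)) continue;
        bool had = ((nb[i] >> j) & 1ull) != 0;
        locked[i] |= (1ull << j);
        flip(i, j);
        cur.push_back({i, j, had ? -1 : +1});
        dfs(k - 1);
        cur.pop_back();
        flip(i, j);
        locked[i] &= ~(1ull << j);
      }
  }
};

static bool solution_less(const std::vector<std::array<int, 3>> &a,
                          const std::vector<std::array<int, 3>> &b) {
  int da = 0, db = 0;
  for (auto &e : a) if (e[2] < 0) ++da;
  for (auto &e : b) if (e[2] < 0) ++db;
  if (da != db) return da < db; // prefer insertions
  auto sa = a, sb = b;
  std::sort(sa.begin(), sa.end());
  std::sort(sb.begin(), sb.end());
  return sa < sb;
}

// [[Rcpp::export]]
List cpp_cograph_edit_exact(LogicalMatrix adj, int max_k) {
  int n = adj.nrow();
  if (n > 63) stop("exact cograph editing supports at most 63 vertices");
  EditSearch s;
  s.n = n;
  s.nb = to_bits(adj);
  s.locked.assign(n, 0u);
  for (int k = 0; k <= max_k; ++k) {
    s.sols.clear();
    s.dfs(k);
    if (!s.sols.empty()) {
      auto best = *std::min_element(s.sols.begin(), s.sols.end(), solution_less);
      std::sort(best.begin(), best.end());
      IntegerMatrix ed(best.size(), 3);
      for (size_t r = 0; r < best.size(); ++r) {
        ed(r, 0) = best[r][0] + 1;
        ed(r, 1) = best[r][1] + 1;
        ed(r, 2) = best[r][2];
      }
      return List::create(_["count"] = k, _["edits"] = ed);
    }
  }
  return List::create(_["count"] = NA_INTEGER,
                      _["edits"] = IntegerMatrix(0, 3));
}

// ---------------------------------------------------------------------------
// Exhaustive minimum (reference implementation used by the tests): enumerate
// all k-subsets of vertex pairs for k = 0, 1, ... until a flip set yields a
// P4-free graph.  Algorithmically independent of the branching search above.

// [[Rcpp::export]]
int cpp_cograph_edit_exhaustive(LogicalMatrix adj) {
  int n = adj.nrow();
  if (n > 8) stop("exhaustive cograph editing is limited to 8 vertices");
  BitAdj base = to_bits(adj);
  std::vector<std::pair<int, int>> pairs;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) pairs.push_back({i, j});
  int P = pairs.size();
  int p4[4];
  for (int k = 0; k <= P; ++k) {
    std::vector<int> idx(k);
    for (int i = 0; i < k; ++i) idx[i] = i;
    while (true) {
      BitAdj nb = base;
      for (int i = 0; i < k; ++i) {
        int a = pairs[idx[i]].first, b = pairs[idx[i]].second;
        nb[a] ^= (1ull << b);
        nb[b] ^= (1ull << a);
      }
      if (!find_p4(nb, n, p4)) return k;
      // next combination
      int pos = k - 1;
      while (pos >= 0 && idx[pos] == P - k + pos) --pos;
      if (pos < 0) break;
      ++idx[pos];
      for (int i = pos + 1; i < k; ++i) idx[i] = idx[i - 1] + 1;
    }
  }
  return P; // unreachable: the complete graph is a cograph
}

// ---------------------------------------------------------------------------
// Greedy editing for graphs above the exact-search size limit: repeatedly
// apply the single flip that lowers the induced-P4 count the most; ties
// prefer insertion over deletion, then the lexicographically smallest pair.

// [[Rcpp::export]]
List cpp_cograph_edit_greedy(LogicalMatrix adj, int max_edits) {
  int n = adj.nrow();
  if (n > 63) stop("greedy cograph editing supports at most 63 vertices");
  BitAdj nb = to_bits(adj);
  std::vector<std::array<int, 3>> edits;
  int cur = count_p4(nb, n);
  while (cur > 0 && (int)edits.size() < max_edits) {
    int best_i = -1, best_j = -1, best_cnt = INT_MAX, best_ins = -1;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        bool had = ((nb[i] >> j) & 1ull) != 0;
        nb[i] ^= (1ull << j); nb[j] ^= (1ull << i);
        int c = count_p4(nb, n);
        nb[i] ^= (1ull << j); nb[j] ^= (1ull << i);
        int ins = had ? 0 : 1;
        // first encountered wins ties beyond (count, insertion-preferred),
        // giving the lexicographically smallest pair
        if (c < best_cnt || (c == best_cnt && ins > best_ins)) {
          best_cnt = c; best_i = i; best_j = j; best_ins = ins;
        }
      }
    if (best_cnt >= cur) break; // no single flip reduces the count
    bool had = (nb[best_i] >> best_j) & 1u;
    nb[best_i] ^= (1ull << best_j); nb[best_j] ^= (1ull << best_i);
    edits.push_back({best_i, best_j, had ? -1 : +1});
    cur = best_cnt;
  }
  IntegerMatrix ed(edits.size(), 3);
  for (size_t r = 0; r < edits.size(); ++r) {
    ed(r, 0) = edits[r][0] + 1;
    ed(r, 1) = edits[r][1] + 1;
    ed(r, 2) = edits[r][2];
  }
  LogicalMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) out(i, j) = (i != j) && ((nb[i] >> j) & 1ull);
  return List::create(_["count"] = (int)edits.size(), _["edits"] = ed,
                      _["adj"] = out, _["p4_left"] = cur);
}

// ---------------------------------------------------------------------------
// Global alignment identity: optimal Needleman-Wunsch score with match +1,
// mismatch -1, gap -1.  Among optimal-score alignments the one with the most
// identical columns is taken, then the shortest; identity = matches / length.
// The lexicographic objective is additive, so a tuple DP is exact.

// [[Rcpp::export]]
double cpp_nw_identity(std::string s1, std::string s2) {
  int n = s1.size(), m = s2.size();
  if (n == 0 || m == 0) stop("sequences must be nonempty");
  std::vector<int> S_prev(m + 1), M_prev(m + 1), L_prev(m + 1);
  std::vector<int> S(m + 1), M(m + 1), L(m + 1);
  for (int j = 0; j <= m; ++j) { S_prev[j] = -j; M_prev[j] = 0; L_prev[j] = j; }
  for (int i = 1; i <= n; ++i) {
    S[0] = -i; M[0] = 0; L[0] = i;
    for (int j = 1; j <= m; ++j) {
      bool eq = s1[i - 1] == s2[j - 1];
      // diagonal
      int s = S_prev[j - 1] + (eq ? 1 : -1);
      int mm = M_prev[j - 1] + (eq ? 1 : 0);
      int l = L_prev[j - 1] + 1;
      // up (gap in s2)
      int s2c = S_prev[j] - 1, m2 = M_prev[j], l2 = L_prev[j] + 1;
      if (s2c > s || (s2c == s && (m2 > mm || (m2 == mm && l2 < l)))) {
        s = s2c; mm = m2; l = l2;
      }
      // left (gap in s1)
      int s3 = S[j - 1] - 1, m3 = M[j - 1], l3 = L[j - 1] + 1;
      if (s3 > s || (s3 == s && (m3 > mm || (m3 == mm && l3 < l)))) {
        s = s3; mm = m3; l = l3;
      }
      S[j] = s; M[j] = mm; L[j] = l;
    }
    std::swap(S, S_prev); std::swap(M, M_prev); std::swap(L, L_prev);
  }
  return (double)M_prev[m] / (double)L_prev[m];
}
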