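#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

// Watson-Crick plus G.U wobble pairing on DNA alphabet (T stands for U).
static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'T';
  case 'T': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'T';
  case 'C': return b == 'G';
  default: return false;
  }
}

// Maximum-scoring nested structure by Nussinov-style dynamic programming
// with a minimum hairpin loop of `min_loop` unpaired bases. The score is
// pair_score per base pair minus helix_penalty for every helix opening
// (each maximal run of stacked pairs is charged once, so bulges and
// interior loops re-charge the penalty). This loop-penalized pairing model
// rewards the long arm-to-arm duplex of a pre-miRNA over the scattered
// short helices random sequence can always form; with helix_penalty = 0 it
// reduces to plain maximum base pairing. Ties resolve to the most distal
// admissible partner.
// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop = 3, int pair_score = 2,
                   int helix_penalty = 5) {
  const int n = seq.size();
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T')
      stop("fold_hairpin: non-ACGU character '%s' at position %d",
           std::string(1, c), i + 1);
  }
  if (n == 0)
    return List::create(_["n_pairs"] = 0, _["structure"] = "",
                        _["partner"] = IntegerVector(0));
  const int M = pair_score;
  const int P = helix_penalty;
  const int NEG = INT_MIN / 4;
  std::vector<int> Wm((size_t)n * n, 0), Vm((size_t)n * n, NEG);
  auto W = [&](int i, int j) -> int& { return Wm[(size_t)i * n + j]; };
  auto V = [&](int i, int j) -> int& { return Vm[(size_t)i * n + j]; };
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      if (can_pair(seq[i], seq[j])) {
        int inner = 0;
        if (j - 1 - (i + 1) >= min_loop + 1) {
          inner = W(i + 1, j - 1); // non-stacked continuation (re-charged)
          if (V(i + 1, j - 1) > NEG && V(i + 1, j - 1) > inner)
            inner = V(i + 1, j - 1); // stacked on (i+1, j-1), no charge
        }
        V(i, j) = M + inner;
      }
      int best = W(i + 1, j);
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (V(i, k) <= NEG) continue;
        int v = V(i, k) - P + (k + 1 <= j ? W(k + 1, j) : 0);
        if (v > best) best = v;
      }
      W(i, j) = best;
    }
  }
  // traceback (prefer distal partners on ties)
  std::string db(n, '.');
  std::vector<int> partner(n, -1);
  struct Frame { int i, j; bool paired; };
  std::vector<Frame> stack;
  stack.push_back({0, n - 1, false});
  while (!stack.empty()) {
    Frame f = stack.back();
    stack.pop_back();
    int i = f.i, j = f.j;
    if (j - i < min_loop + 1) continue;
    if (!f.paired) {
      if (W(i, j) == 0) continue;
      if (W(i, j) == W(i + 1, j)) { stack.push_back({i + 1, j, false}); continue; }
      for (int k = j; k >= i + min_loop + 1; --k) {
        if (V(i, k) <= NEG) continue;
        int v = V(i, k) - P + (k + 1 <= j ? W(k + 1, j) : 0);
        if (v == W(i, j)) {
          stack.push_back({i, k, true});
          if (k + 1 <= j) stack.push_back({k + 1, j, false});
          break;
        }
      }
    } else {
      db[i] = '('; db[j] = ')';
      partner[i] = j; partner[j] = i;
      if (j - 1 - (i + 1) >= min_loop + 1) {
        int inner = V(i, j) - M;
        if (V(i + 1, j - 1) > NEG && V(i + 1, j - 1) == inner)
          stack.push_back({i + 1, j - 1, true});
        else
          stack.push_back({i + 1, j - 1, false});
      }
    }
  }
  IntegerVector part(n);
  int npairs = 0;
  for (int i = 0; i < n; ++i) if (partner[i] > i) ++npairs;
  for (int i = 0; i < n; ++i) part[i] = partner[i] + 1; // 1-based, 0 = none
  return List::create(_["n_pairs"] = npairs,
                      _["structure"] = db,
                      _["partner"] = part,
                      _["score"] = W(0, n - 1));
}

// Best ungapped overlap alignment between each read and each reference:
// slide the read across the reference over all offsets whose overlap is at
// least min(len_read, len_ref) - slack, and report the minimum mismatch
// count over the overlap. Entries with no admissible offset get NA.
// [[Rcpp::export(name = ".overlap_mismatches")]]
IntegerMatrix overlap_mismatches(CharacterVector reads, CharacterVector refs,
                                 int slack = 2) {
  int nr = reads.size(), nf = refs.size();
  IntegerMatrix out(nr, nf);
  for (int a = 0; a < nr; ++a) {
    std::string r = as<std::string>(reads[a]);
    int lr = r.size();
    for (int b = 0; b < nf; ++b) {
      std::string f = as<std::string>(refs[b]);
      int lf = f.size();
      int min_ov = std::min(lr, lf) - slack;
      if (min_ov < 1) min_ov = 1;
      int best = NA_INTEGER;
      // offset = position of read start relative to ref start
      for (int off = -(lr - min_ov); off <= lf - min_ov; ++off) {
        int lo = std::max(0, -off);        // read index where overlap starts
        int hi = std::min(lr, lf - off);   // read index past overlap end
        int ov = hi - lo;
        if (ov < min_ov) continue;
        int mm = 0;
        for (int i = lo; i < hi; ++i) if (r[i] != f[i + off]) ++mm;
        if (best == NA_INTEGER || mm < best) best = mm;
      }
      out(a, b) = best;
    }
  }
  return out;
}
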