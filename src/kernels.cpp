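#include <Rcpp.h>
using namespace Rcpp;

// Bases are encoded 1=A, 2=C, 3=G, 4=U; 0 = N (never pairs, always mismatches).

static inline bool wc_or_wobble(int a, int b) {
  return (a == 1 && b == 4) || (a == 4 && b == 1) ||
         (a == 2 && b == 3) || (a == 3 && b == 2) ||
         (a == 3 && b == 4) || (a == 4 && b == 3);
}

// Maximum base-pair (Nussinov-style) fold over nested structures with a
// minimum hairpin loop of `min_loop` unpaired nucleotides. Returns the
// 0-based pairing partner per position, -1 for unpaired. Traceback is
// deterministic: the leftmost position is left unpaired whenever that
// attains the optimum, otherwise paired with the largest admissible k
// (which keeps helices stacked against the enclosing pair instead of
// introducing spurious bulges among co-optimal structures).
// [[Rcpp::export]]
IntegerVector nussinov_partner(IntegerVector seq, int min_loop) {
  int n = seq.size();
  IntegerVector partner(n, -1);
  if (n < 2) return partner;
  std::vector< std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i + 1][j];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!wc_or_wobble(seq[i], seq[k])) continue;
        int v = 1 + (k > i + 1 ? M[i + 1][k - 1] : 0) + (k < j ? M[k + 1][j] : 0);
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  std::vector< std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    if (M[i][j] == M[i + 1][j]) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = j; k >= i + min_loop + 1; --k) {
      if (!wc_or_wobble(seq[i], seq[k])) continue;
      int v = 1 + (k > i + 1 ? M[i + 1][k - 1] : 0) + (k < j ? M[k + 1][j] : 0);
      if (v == M[i][j]) {
        partner[i] = k;
        partner[k] = i;
        if (k > i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  return partner;
}

// [[Rcpp::export]]
int nussinov_max_pairs(IntegerVector seq, int min_loop) {
  IntegerVector p = nussinov_partner(seq, min_loop);
  int cnt = 0;
  for (int i = 0; i < p.size(); ++i) if (p[i] >= 0) ++cnt;
  return cnt / 2;
}

// Ungapped identity scan: substitution count of `query` against `subject`
// at every offset 0..(S-L). N never matches.
// [[Rcpp::export]]
IntegerVector mismatch_scan_cpp(IntegerVector subject, IntegerVector query) {
  int S = subject.size(), L = query.size();
  if (L == 0 || S < L) return IntegerVector(0);
  IntegerVector out(S - L + 1);
  for (int o = 0; o <= S - L; ++o) {
    int mm = 0;
    for (int i = 0; i < L; ++i) {
      int a = subject[o + i], b = query[i];
      if (a == 0 || b == 0 || a != b) ++mm;
    }
    out[o] = mm;
  }
  return out;
}

// Complementary-site scan: the small RNA (query, 5'->3') is paired
// antiparallel against the transcript (subject), query position i (1-based)
// opposite subject position o + L - i (0-based). Column 0: non-WC,
// non-wobble oppositions; column 1: G:U wobbles.
// [[Rcpp::export]]
IntegerMatrix site_scan_cpp(IntegerVector subject, IntegerVector query) {
  int S = subject.size(), L = query.size();
  if (L == 0 || S < L) return IntegerMatrix(0, 2);
  IntegerMatrix out(S - L + 1, 2);
  for (int o = 0; o <= S - L; ++o) {
    int mm = 0, gu = 0;
    for (int i = 0; i < L; ++i) {
      int q = query[i], s = subject[o + L - 1 - i];
      bool wc = (q == 1 && s == 4) || (q == 4 && s == 1) ||
                (q == 2 && s == 3) || (q == 3 && s == 2);
      if (wc) continue;
      bool wob = (q == 3 && s == 4) || (q == 4 && s == 3);
      if (wob) ++gu; else ++mm;
    }
    out(o, 0) = mm;
    out(o, 1) = gu;
  }
  return out;
}
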