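#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Stacking-aware base-pair maximization (Nussinov-style) for hairpin
// candidate evaluation. Pair scores GC=3, AU=2, GU=1; +1 bonus when a
// pair stacks directly on another; minimum hairpin loop 3 nt. The score
// is converted to a kcal/mol-like energy proxy by the R wrapper.

static const int NEG = -1000000;

static inline int pairScore(char a, char b) {
  if (a == 'U') a = 'T';
  if (b == 'U') b = 'T';
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return NEG;
}

struct Fold {
  int n;
  std::string s;
  std::vector<std::vector<int> > M, P;
  std::string db;

  Fold(const std::string& seq) : n(seq.size()), s(seq),
      M(n, std::vector<int>(n, 0)), P(n, std::vector<int>(n, NEG)),
      db(n, '.') {}

  inline bool canPair(int i, int j) const {
    return j - i - 1 >= 3 && pairScore(s[i], s[j]) > 0;
  }

  void run() {
    for (int len = 5; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        if (canPair(i, j)) {
          int inner = (j - 1) - (i + 1) >= 0 ? M[i + 1][j - 1] : 0;
          int best = inner;
          if (canPair(i + 1, j - 1) && P[i + 1][j - 1] + 1 > best)
            best = P[i + 1][j - 1] + 1;
          P[i][j] = pairScore(s[i], s[j]) + best;
        }
        int best = M[i][j - 1];
        for (int k = i; k <= j - 4; ++k) {
          if (P[k][j] == NEG) continue;
          int cand = (k > i ? M[i][k - 1] : 0) + P[k][j];
          if (cand > best) best = cand;
        }
        M[i][j] = best;
      }
    }
  }

  void traceP(int i, int j) {
    db[i] = '(';
    db[j] = ')';
    int inner = (j - 1) - (i + 1) >= 0 ? M[i + 1][j - 1] : 0;
    int sc = pairScore(s[i], s[j]);
    if (canPair(i + 1, j - 1) && P[i][j] == sc + P[i + 1][j - 1] + 1)
      traceP(i + 1, j - 1);
    else if (P[i][j] == sc + inner)
      traceM(i + 1, j - 1);
    else
      traceP(i + 1, j - 1); // unreachable; defensive
  }

  void traceM(int i, int j) {
    if (j - i + 1 < 5) return;
    if (M[i][j] == M[i][j - 1]) { traceM(i, j - 1); return; }
    for (int k = i; k <= j - 4; ++k) {
      if (P[k][j] == NEG) continue;
      int cand = (k > i ? M[i][k - 1] : 0) + P[k][j];
      if (cand == M[i][j]) {
        if (k > i) traceM(i, k - 1);
        traceP(k, j);
        return;
      }
    }
  }
};

// [[Rcpp::export(name = ".foldDp")]]
List foldDp(std::string seq) {
  int n = seq.size();
  if (n < 5)
    return List::create(_["structure"] = std::string(n, '.'),
                        _["score"] = 0);
  Fold f(seq);
  f.run();
  int score = f.M[0][n - 1];
  if (score > 0) f.traceM(0, n - 1);
  return List::create(_["structure"] = f.db, _["score"] = score);
}
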