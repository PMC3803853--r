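#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). Gap of length L costs open + L * ext,
// matching the BLAST convention (gapopen 11, gapextend 1 => a 1-gap costs 12).
// Tie-breaks: among equal-score optima, smallest subject start, then smallest
// query start, then smallest subject end, then query end.

static inline int gapcost(int L, int open, int ext) {
  return L > 0 ? open + L * ext : 0;
}

// [[Rcpp::export(name = ".sw_local")]]
List sw_local(IntegerVector qa, IntegerVector sa, IntegerMatrix sub,
              int open, int ext) {
  const int n = qa.size(), m = sa.size();
  const int NEG = -1000000000;
  // H/E/F as (n+1) x (m+1); E = gap in subject (consumes query row),
  // F = gap in query (consumes subject column)
  std::vector<std::vector<int> > H(n + 1, std::vector<int>(m + 1, 0));
  std::vector<std::vector<int> > E(n + 1, std::vector<int>(m + 1, NEG));
  std::vector<std::vector<int> > F(n + 1, std::vector<int>(m + 1, NEG));
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int e = std::max(H[i - 1][j] - (open + ext), E[i - 1][j] - ext);
      int f = std::max(H[i][j - 1] - (open + ext), F[i][j - 1] - ext);
      int d = H[i - 1][j - 1] + sub(qa[i - 1], sa[j - 1]);
      int h = std::max(0, std::max(d, std::max(e, f)));
      E[i][j] = e; F[i][j] = f; H[i][j] = h;
      if (h > best) best = h;
    }
  }
  if (best == 0)
    return List::create(_["score"] = 0, _["qstart"] = NA_INTEGER,
                        _["qend"] = NA_INTEGER, _["sstart"] = NA_INTEGER,
                        _["send"] = NA_INTEGER, _["identity"] = NA_REAL,
                        _["ncol"] = 0L);
  // enumerate optimum end cells, trace each back, keep the tie-break winner
  int bqs = 0, bqe = 0, bss = 0, bse = 0, bmatch = 0, bcols = 0;
  bool have = false;
  for (int j = 1; j <= m; ++j) {
    for (int i = 1; i <= n; ++i) {
      if (H[i][j] != best) continue;
      int ci = i, cj = j, state = 0; // 0=H, 1=E, 2=F
      int matches = 0, cols = 0;
      while (true) {
        if (state == 0) {
          if (H[ci][cj] == 0) break;
          int d = H[ci - 1][cj - 1] + sub(qa[ci - 1], sa[cj - 1]);
          if (H[ci][cj] == d) {
            if (qa[ci - 1] == sa[cj - 1]) ++matches;
            ++cols; --ci; --cj;
          } else if (H[ci][cj] == E[ci][cj]) {
            state = 1;
          } else {
            state = 2;
          }
        } else if (state == 1) {
          ++cols;
          if (E[ci][cj] == H[ci - 1][cj] - (open + ext)) { --ci; state = 0; }
          else { --ci; }
        } else {
          ++cols;
          if (F[ci][cj] == H[ci][cj - 1] - (open + ext)) { --cj; state = 0; }
          else { --cj; }
        }
      }
      int qs = ci + 1, ss = cj + 1;
      bool take = !have;
      if (have) {
        if (ss < bss) take = true;
        else if (ss == bss && qs < bqs) take = true;
        else if (ss == bss && qs == bqs && j < bse) take = true;
        else if (ss == bss && qs == bqs && j == bse && i < bqe) take = true;
      }
      if (take) {
        bqs = qs; bqe = i; bss = ss; bse = j;
        bmatch = matches; bcols = cols; have = true;
      }
    }
  }
  return List::create(_["score"] = best, _["qstart"] = bqs, _["qend"] = bqe,
                      _["sstart"] = bss, _["send"] = bse,
                      _["identity"] = (double)bmatch / (double)bcols,
                      _["ncol"] = bcols);
}

// Brute-force local alignment score: exhaustive depth-first enumeration over
// every increasing matching of query/subject positions, charging each gap run
// between consecutive matched pairs open + L * ext. Independent of the DP
// above; exponential, intended only for short sequences.
static void brute_dfs(const IntegerVector& qa, const IntegerVector& sa,
                      const IntegerMatrix& sub, int open, int ext,
                      int i, int j, int acc, int& best) {
  if (acc > best) best = acc;
  const int n = qa.size(), m = sa.size();
  for (int i2 = i + 1; i2 < n; ++i2) {
    for (int j2 = j + 1; j2 < m; ++j2) {
      int g = gapcost(i2 - i - 1, open, ext) + gapcost(j2 - j - 1, open, ext);
      brute_dfs(qa, sa, sub, open, ext, i2, j2,
                acc - g + sub(qa[i2], sa[j2]), best);
    }
  }
}

// [[Rcpp::export(name = ".sw_brute_score")]]
int sw_brute_score(IntegerVector qa, IntegerVector sa, IntegerMatrix sub,
                   int open, int ext) {
  int best = 0;
  const int n = qa.size(), m = sa.size();
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      brute_dfs(qa, sa, sub, open, ext, i, j, sub(qa[i], sa[j]), best);
  return best;
}
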