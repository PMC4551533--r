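#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

namespace {

// Global (end-to-end) alignment by Needleman-Wunsch over additive tuples
// (score, matches, -gap_columns), maximized lexicographically. Lexicographic
// max over additive tuples is a valid DP objective, so the traceback-free
// recurrence below yields, among all optimal-score alignments, the one with
// the most matched columns and, among those, the fewest gap columns.
struct Cell {
  double score;
  int matches;
  int gaps;   // gap columns
  int pairs;  // aligned (match or mismatch) columns
};

inline bool lex_better(double s1, int m1, int g1,
                       double s2, int m2, int g2) {
  if (s1 != s2) return s1 > s2;
  if (m1 != m2) return m1 > m2;
  return g1 < g2;
}

Cell align_pair(const std::string& a, const std::string& b,
                double match, double mismatch, double gap) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<Cell> prev(m + 1), cur(m + 1);
  prev[0] = {0.0, 0, 0, 0};
  for (int j = 1; j <= m; ++j) prev[j] = {j * gap, 0, j, 0};
  for (int i = 1; i <= n; ++i) {
    cur[0] = {i * gap, 0, i, 0};
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char bj = b[j - 1];
      // N is never a match, even against another N
      const bool is_match = (ai == bj) && ai != 'N' && ai != 'n';
      // diagonal
      Cell best = prev[j - 1];
      best.score += is_match ? match : mismatch;
      best.matches += is_match ? 1 : 0;
      best.pairs += 1;
      // gap in b (consume a[i-1])
      {
        const Cell& up = prev[j];
        double s = up.score + gap;
        if (lex_better(s, up.matches, up.gaps + 1,
                       best.score, best.matches, best.gaps)) {
          best = {s, up.matches, up.gaps + 1, up.pairs};
        }
      }
      // gap in a (consume b[j-1])
      {
        const Cell& left = cur[j - 1];
        double s = left.score + gap;
        if (lex_better(s, left.matches, left.gaps + 1,
                       best.score, best.matches, best.gaps)) {
          best = {s, left.matches, left.gaps + 1, left.pairs};
        }
      }
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

}  // namespace

// [[Rcpp::export]]
List align_global_cpp(std::string a, std::string b,
                      double match, double mismatch, double gap) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  Cell c = align_pair(a, b, match, mismatch, gap);
  int columns = c.pairs + c.gaps;
  return List::create(
      _["score"] = c.score, _["matches"] = c.matches,
      _["mismatches"] = c.pairs - c.matches, _["gaps"] = c.gaps,
      _["columns"] = columns,
      _["identity"] = (double)c.matches / (double)columns);
}

// [[Rcpp::export]]
NumericVector identity_many_cpp(std::string a, CharacterVector bs,
                                double match, double mismatch, double gap) {
  if (a.empty()) stop("sequences must be non-empty");
  const int n = bs.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string b = as<std::string>(bs[k]);
    if (b.empty()) stop("sequences must be non-empty");
    Cell c = align_pair(a, b, match, mismatch, gap);
    out[k] = (double)c.matches / (double)(c.pairs + c.gaps);
  }
  return out;
}
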