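#include <Rcpp.h>
#include <cmath>
#include <string>
using namespace Rcpp;

namespace {

// Substitution-only comparison of primer against read starting at offset.
// Any position involving N counts as a mismatch. Returns the mismatch count,
// or budget + 1 early as soon as the budget is exceeded.
inline int count_mismatches(const std::string& read, std::size_t offset,
                            const std::string& primer, int budget) {
  int mm = 0;
  for (std::size_t k = 0; k < primer.size(); ++k) {
    const char r = read[offset + k];
    const char p = primer[k];
    if (r != p || r == 'N') {
      if (++mm > budget) return mm;
    }
  }
  return mm;
}

}  // namespace

// Status codes: 0 = ok, 1 = no_forward_primer, 2 = no_reverse_primer,
// 3 = bad_length. Forward primer is anchored at position 0; the reverse
// primer region is scanned left to right starting immediately after the
// forward primer, and the leftmost window within the substitution budget
// wins. Everything from the reverse primer onward (adaptors included) is
// discarded.
// [[Rcpp::export]]
List trim_reads_cpp(CharacterVector reads, std::string fwd, std::string rev,
                    double mismatch_frac, int len_target, int len_tol) {
  const int n = reads.size();
  const int budget_f = (int)std::floor(mismatch_frac * fwd.size());
  const int budget_r = (int)std::floor(mismatch_frac * rev.size());
  IntegerVector status(n);
  CharacterVector region(n);
  for (int i = 0; i < n; ++i) {
    std::string read = as<std::string>(reads[i]);
    if (read.size() < fwd.size() ||
        count_mismatches(read, 0, fwd, budget_f) > budget_f) {
      status[i] = 1;
      region[i] = NA_STRING;
      continue;
    }
    long hit = -1;
    if (read.size() >= fwd.size() + rev.size()) {
      const std::size_t last = read.size() - rev.size();
      for (std::size_t j = fwd.size(); j <= last; ++j) {
        if (count_mismatches(read, j, rev, budget_r) <= budget_r) {
          hit = (long)j;
          break;
        }
      }
    }
    if (hit < 0) {
      status[i] = 2;
      region[i] = NA_STRING;
      continue;
    }
    const int len = (int)(hit - (long)fwd.size());
    if (len < len_target - len_tol || len > len_target + len_tol) {
      status[i] = 3;
      region[i] = NA_STRING;
      continue;
    }
    status[i] = 0;
    region[i] = read.substr(fwd.size(), len);
  }
  return List::create(_["status"] = status, _["region"] = region);
}
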