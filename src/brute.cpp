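#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive enumeration of all non-crossing permitted matchings, by
// recursion on "leftmost site unmatched, or matched to each feasible j".
// Deliberately independent of the dynamic-programming solvers: no memoisation,
// no shared recurrence code. Exponential; callers cap n.
namespace {

struct Problem {
  std::vector<int> codes;           // 0..3, 1-based via codes[i-1]
  const IntegerMatrix *scores;      // 4x4 pair scores
  int d;
};

int permitted_score(const Problem &p, int i, int j) {
  if (j - i <= p.d) return -1;
  int s = (*p.scores)(p.codes[i - 1], p.codes[j - 1]);
  return s > 0 ? s : -1;
}

int enumerate_best(const Problem &p, int lo, int hi) {
  if (lo >= hi) return 0;
  // option 1: site lo stays unmatched
  int best = enumerate_best(p, lo + 1, hi);
  // option 2: site lo matched to some feasible j; non-crossing splits the
  // interval into (lo, j) interior and (j, hi] remainder
  for (int j = lo + 1; j <= hi; ++j) {
    int s = permitted_score(p, lo, j);
    if (s < 0) continue;
    int total = s + enumerate_best(p, lo + 1, j - 1) + enumerate_best(p, j + 1, hi);
    if (total > best) best = total;
  }
  return best;
}

} // namespace

// [[Rcpp::export]]
int cpp_brute_force(IntegerVector codes_, IntegerMatrix bmat, int d) {
  Problem p;
  p.codes.assign(codes_.begin(), codes_.end());
  p.scores = &bmat;
  p.d = d;
  return enumerate_best(p, 1, (int)p.codes.size());
}
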