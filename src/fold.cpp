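#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Nucleotide codes are 0..3 (A,C,G,U); `bmat` is the 4x4 symmetric pair-score
// matrix; a pair (i,j) contributes bmat only when j - i > d.
static inline int pair_b(const std::vector<int> &codes, const IntegerMatrix &bmat,
                         int d, int i, int j) {
  if (j - i <= d) return 0;
  return bmat(codes[i - 1], codes[j - 1]);
}

// Classic evaluation by increasing interval length (rules a-d; rule d in the
// original S(i,k) + S(k+1,j) form).
// [[Rcpp::export]]
IntegerMatrix cpp_fold_diagonal(IntegerVector codes_, IntegerMatrix bmat, int d) {
  const int n = codes_.size();
  std::vector<int> codes(codes_.begin(), codes_.end());
  IntegerMatrix S(n, n); // zero-initialised; cell (i,j) at S(i-1,j-1)
  for (int len = 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      const int j = i + len - 1;
      int best = (i + 1 <= j - 1 ? S(i, j - 2) : 0) + pair_b(codes, bmat, d, i, j); // rule a
      int rb = S(i - 1, j - 2); // rule b: S(i, j-1)
      if (rb > best) best = rb;
      int rc = S(i, j - 1);     // rule c: S(i+1, j)
      if (rc > best) best = rc;
      for (int k = i + 1; k < j; ++k) { // rule d: S(i,k) + S(k+1,j)
        int cand = S(i - 1, k - 1) + S(k, j - 1);
        if (cand > best) best = cand;
      }
      S(i - 1, j - 1) = best;
    }
  }
  return S;
}

// Column-order evaluation: per column j, an independent ascending-i pass
// (rules a,b) then a dependent descending-i pass (rules c,d with the
// S(i,k-1) + S(k,j) indexing).
// [[Rcpp::export]]
IntegerMatrix cpp_fold_column(IntegerVector codes_, IntegerMatrix bmat, int d) {
  const int n = codes_.size();
  std::vector<int> codes(codes_.begin(), codes_.end());
  IntegerMatrix S(n, n);
  for (int j = 2; j <= n; ++j) {
    for (int i = 1; i <= j - 1; ++i) { // independent: rules a, b
      int a = (i + 1 <= j - 1 ? S(i, j - 2) : 0) + pair_b(codes, bmat, d, i, j);
      int b = S(i - 1, j - 2);
      S(i - 1, j - 1) = a > b ? a : b;
    }
    for (int i = j - 1; i >= 1; --i) { // dependent: rules c, d
      int s = S(i - 1, j - 1);
      int rc = S(i, j - 1); // S(i+1, j); S(j,j) = 0
      if (rc > s) s = rc;
      for (int k = j - 1; k >= i + 1; --k) {
        int cand = S(i - 1, k - 2) + S(k - 1, j - 1); // S(i,k-1) + S(k,j); S(i,i)=0
        if (cand > s) s = cand;
      }
      S(i - 1, j - 1) = s;
    }
  }
  return S;
}

// Four-Russians accelerated column DP.
//
// Fixed alignment (never re-aligned per column):
//   Rgroup g = rows g*q+1 .. (g+1)*q   (group of row k is (k-1)/q)
//   Cgroup g = columns g*q .. (g+1)*q-1 (Cgroup 0 = 1..q-1)
// v_g digits run from the group's highest row z = (g+1)*q downward:
//   digit t = S(z-t-1, j) - S(z-t, j)  in {0, .., C-1};
// packed key is the base-C value, digit 0 most significant.
// R-table entries are uint8 offsets k* - (g*q+1); 0xFF marks "not yet
// computed" (used by the lazy mode, which fills entries on first lookup).
// [[Rcpp::export]]
List cpp_fold_four_russians(IntegerVector codes_, IntegerMatrix bmat, int d,
                            int q, int C, bool lazy) {
  const int n = codes_.size();
  std::vector<int> codes(codes_.begin(), codes_.end());
  if (q < 2) stop("q must be >= 2");
  if (C < 2) stop("C must be >= 2");
  // table width C^(q-1), guarded
  double wd = 1.0;
  for (int t = 0; t < q - 1; ++t) {
    wd *= C;
    if (wd > 1048576.0) stop("R-table width C^(q-1) exceeds the memory guard; lower q");
  }
  const long long W = (long long)wd;

  IntegerMatrix S(n, n);
  int *p = S.begin(); // column-major: S(i, j) is p[(j-1)*n + (i-1)]
  const int G = (n + q - 1) / q + 1;            // groups that can ever occur
  std::vector<long long> vkey(G, -1);           // per-column v_g keys
  std::vector<std::vector<uint8_t>> rtab(G);    // rtab[g]: W keys x (g*q) rows, key-major
  std::vector<const uint8_t *> rslice(G, nullptr); // per-column slice rtab[g] + vkey[g]*ni
  std::vector<char> built(G, 0);

  // instrumentation
  double n_lookups = 0, n_direct = 0, n_cells = 0, n_entries = 0;
  int max_direct_cell = 0;

  std::vector<int> Vp(q), digits(q - 1);

  for (int j = 2; j <= n; ++j) {
    int *colj = p + (size_t)(j - 1) * n;        // S(., j)
    const int *coljm1 = p + (size_t)(j - 2) * n; // S(., j-1)
    // [Independent] rules a, b
    for (int i = 1; i <= j - 1; ++i) {
      int a = (i + 1 <= j - 1 ? coljm1[i] : 0) + pair_b(codes, bmat, d, i, j);
      int b = coljm1[i - 1];
      colj[i - 1] = a > b ? a : b;
    }
    std::fill(vkey.begin(), vkey.end(), -1LL);
    std::fill(rslice.begin(), rslice.end(), nullptr);
    // [Dependent] rules c, d
    for (int i = j - 1; i >= 1; --i) {
      int s = colj[i - 1];
      int rc = colj[i]; // S(i+1, j); the diagonal cell stays 0
      if (rc > s) s = rc;
      if (j - i >= 2) {
        ++n_cells;
        int cell_direct = 0;
        const int klo = i + 1, khi = j - 1;
        const int glo = (i + q - 1) / q;   // first group fully above row i
        const int ghi = (j - 1) / q - 1;   // last group fully below row j-1
        const int *rowi = p + (i - 1);     // S(i, c) at rowi[(c-1)*n]
        if (ghi >= glo) {
          // i-side partial group: k in [klo, glo*q] (empty when i is on a boundary)
          for (int k = klo; k <= glo * q; ++k) {
            int cand = rowi[(size_t)(k - 2) * n] + colj[k - 1];
            if (cand > s) s = cand;
            ++cell_direct;
          }
          // complete interior groups: one R-table lookup each
          for (int g = glo; g <= ghi; ++g) {
            uint8_t off = rslice[g][i - 1];
            if (off == 0xFF) { // lazy fill: scan group against decoded offsets
              const int a = g * q + 1, b = (g + 1) * q;
              long long key = vkey[g];
              for (int t = q - 2; t >= 0; --t) { digits[t] = (int)(key % C); key /= C; }
              Vp[0] = 0;
              for (int t = 1; t < q; ++t) Vp[t] = Vp[t - 1] + digits[t - 1];
              int best = -1, bestk = a;
              for (int k = a; k <= b; ++k) {
                int val = rowi[(size_t)(k - 2) * n] + Vp[b - k];
                if (val > best) { best = val; bestk = k; }
              }
              off = (uint8_t)(bestk - a);
              const_cast<uint8_t *>(rslice[g])[i - 1] = off;
              ++n_entries;
            }
            const int k = g * q + 1 + off;
            const int cand = rowi[(size_t)(k - 2) * n] + colj[k - 1];
            if (cand > s) s = cand;
          }
          n_lookups += ghi - glo + 1;
          // j-side partial group: k in [(ghi+1)*q + 1, khi]
          for (int k = (ghi + 1) * q + 1; k <= khi; ++k) {
            int cand = rowi[(size_t)(k - 2) * n] + colj[k - 1];
            if (cand > s) s = cand;
            ++cell_direct;
          }
        } else {
          // no complete interior group: plain Rule-d scan
          for (int k = khi; k >= klo; --k) {
            int cand = rowi[(size_t)(k - 2) * n] + colj[k - 1];
            if (cand > s) s = cand;
            ++cell_direct;
          }
        }
        n_direct += cell_direct;
        if (cell_direct > max_direct_cell) max_direct_cell = cell_direct;
      }
      colj[i - 1] = s;
      // store v_g once the group's last (lowest-row) cell in column j is done
      if ((i - 1) % q == 0) {
        const int g = (i - 1) / q, z = (g + 1) * q;
        if (z <= j - 1) {
          long long key = 0;
          for (int t = 0; t < q - 1; ++t) {
            int diff = colj[z - t - 2] - colj[z - t - 1];
            if (diff < 0 || diff >= C)
              stop("column marginal outside {0,..,C-1}; scoring scheme violates the bounded-difference premise");
            key = key * C + diff;
          }
          vkey[g] = key;
          if (g >= 1 && built[g]) rslice[g] = rtab[g].data() + (size_t)key * (g * q);
        }
      }
    }
    // [Table] once Cgroup g = columns g*q..(g+1)*q-1 is complete
    if ((j + 1) % q == 0) {
      const int g = (j + 1) / q - 1;
      if (g >= 1 && g < G) {
        const int a = g * q + 1, b = (g + 1) * q, ni = g * q;
        rtab[g].assign((size_t)W * ni, 0xFF);
        built[g] = 1;
        if (!lazy) {
          std::vector<int> bestv(ni);
          std::vector<uint8_t> bestk(ni);
          for (long long v = 0; v < W; ++v) {
            long long key = v;
            for (int t = q - 2; t >= 0; --t) { digits[t] = (int)(key % C); key /= C; }
            Vp[0] = 0;
            for (int t = 1; t < q; ++t) Vp[t] = Vp[t - 1] + digits[t - 1];
            { // k = a initialises; remaining k sweep columnwise (contiguous in i)
              const int *pc = p + (size_t)(a - 2) * n;
              const int vp = Vp[b - a];
              for (int ii = 0; ii < ni; ++ii) { bestv[ii] = pc[ii] + vp; bestk[ii] = 0; }
            }
            for (int k = a + 1; k <= b; ++k) {
              const int *pc = p + (size_t)(k - 2) * n;
              const int vp = Vp[b - k];
              const uint8_t off = (uint8_t)(k - a);
              for (int ii = 0; ii < ni; ++ii) {
                int val = pc[ii] + vp;
                if (val > bestv[ii]) { bestv[ii] = val; bestk[ii] = off; }
              }
            }
            std::copy(bestk.begin(), bestk.end(), rtab[g].begin() + (size_t)v * ni);
            n_entries += ni;
          }
        }
      }
    }
  }

  return List::create(
      _["S"] = S,
      _["counters"] = NumericVector::create(
          _["lookups"] = n_lookups, _["direct_evals"] = n_direct,
          _["rule_d_cells"] = n_cells, _["max_direct_per_cell"] = (double)max_direct_cell,
          _["table_entries"] = n_entries),
      _["q"] = q);
}
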