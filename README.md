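# rnafour

Exact solvers for the **basic RNA-folding problem**: given an RNA sequence
over `{A, C, G, U}`, find a maximum-score **non-crossing matching** of
complementary nucleotides (A:U, C:G, optionally G:U wobble), subject to a
minimum separation `j - i > d` between paired sites. This maximum-pairing
model is the combinatorial core inside most RNA secondary-structure
software — it is solved repeatedly in the inner loops of richer
thermodynamic and comparative methods, and on very long sequences such as
RNA virus genomes — which makes its cubic cost worth attacking. The package
is for people who need that core fast, verifiable, and scriptable from R.

Three interchangeable solvers fill the same dynamic-programming table

```
S(i,j) = max( S(i+1,j-1) + B(i,j),          # rule a: pair (i,j)
              S(i,j-1),                      # rule b: j unmatched
              S(i+1,j),                      # rule c: i unmatched
              max_{i<k<j} S(i,k) + S(k+1,j)) # rule d: bipartition
```

* `fold_diagonal()` — the classic O(n³) evaluation by increasing `j - i`;
* `fold_column()` — the same recurrences column-by-column (independent
  rules a–b pass, then dependent rules c–d pass);
* `fold_four_russians()` — the column DP with a **Four-Russians speedup**:
  rows are cut into groups of size `q`, each group's column values are
  encoded as bounded difference digits, and the rule-d split inside every
  complete group is answered by one lookup in a table `R(i, g, v)` built
  group-by-group *interleaved* with the fill — O(n³ / log n) total with
  `q = ⌊log_{C+1} n⌋`, where `C - 1` is the maximum pair score.

The speedup changes the work, never the answers: all three solvers are
cell-for-cell identical on every input (tested exhaustively, plus against
an independent brute-force enumeration oracle on small sequences).
Traceback, matching validation, dot-bracket and CT output, a benchmark /
comparison harness and a small CLI round out the tool.

## A worked example

```r
library(rnafour)

fit <- rna_fold("GGGAAAUCCCAGCUUCGGCU")
fit
#> <rna_fold> seq  (n = 20, four-russians solver)
#>   score: 7   pairs: 7
#>   GGGAAAUCCCAGCUUCGGCU
#>   ((((..))))(((....)))
```

Seven base pairs is the optimum: two stems, `(1..4)×(7..10)` and
`(11..13)×(18..20)`, with hairpin loops respecting `d = 1`. `tidy()`
lists the pairs, `glance()` the one-row summary:

```r
tidy(fit)
#> # A tibble: 7 × 5
#>       i     j base_i base_j pair_score
#> 1     1    10 G      C               1
#> 2     2     9 G      C               1
#> 3     3     8 G      C               1
#> 4     4     7 A      U               1
#> 5    11    20 A      U               1
#> 6    12    19 G      C               1
#> 7    13    18 C      G               1
```

Batch folding is pipe-friendly, and the Four-Russians solver exposes its
work counters:

```r
read_fasta("my.fasta") |> fold_table(algorithm = "four-russians")

sm <- fold_four_russians(random_rna(300, seed = 4), q = 3)
sm$counters
#>  lookups  direct_evals  rule_d_cells  max_direct_per_cell  table_entries
#>  1455300         89200         44551                    4          59400
```

`max_direct_per_cell = 4 ≤ 2q`: only the two partial boundary groups of
each cell are ever scanned directly; everything else is table lookups.
Scoring is configurable (`scoring_scheme("pairwise", au = 2, cg = 3)` gives
a C = 4 difference alphabet; pair-score files are supported), structures
serialize with `to_dot_bracket()` / `write_ct()`, and
`run_compare()` / `run_bench()` drive solver cross-checks and timing
tables. A CLI wraps it all: `exec/rnafour fold --input my.fasta`,
`... compare`, `... bench`, `... gen`.

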