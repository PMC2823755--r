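---
title: "Maximum-score RNA folding and the Four-Russians speedup"
author: "rnafour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-score RNA folding and the Four-Russians speedup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnafour)
```

## The problem

The basic RNA-folding problem asks for a *maximum-score, non-crossing
matching* of complementary nucleotides in a sequence \(K\) of length
\(n\) over \(\{A, C, G, U\}\). A pair \((i, j)\) is *permitted* when the
two residues form a scored pair (A:U or C:G under the default scheme;
G:U wobble optionally) and the sites are separated by more than the
minimum-separation parameter \(d\) (strictly \(j - i > d\); default
\(d = 1\)). A matching is *non-crossing* (nested) when it contains no
four sites \(i < i' < j < j'\) with both \((i, j)\) and \((i', j')\)
matched — equivalently, the chords drawn on a circle never intersect.
Maximizing the number (or total score) of such pairs is the combinatorial
core of RNA secondary-structure prediction, and is solved repeatedly in
the inner loops of richer thermodynamic and comparative methods, and on
very long sequences when folding RNA virus genomes.

This model deliberately ignores stacking energies, loop penalties and
pseudoknots; it is the counting/scoring skeleton on which those
refinements are built, and the package's scope is exactly this skeleton.

## The dynamic program

Let \(S(i, j)\) be the optimal score over sites \(i..j\). With
\(B(i, j)\) the score of the pair at \((i, j)\) (zero if not permitted),

\[
S(i,j) = \max \begin{cases}
S(i+1, j-1) + B(i, j) & \text{(a: pair } i,j\text{)}\\
S(i, j-1) & \text{(b: } j \text{ unmatched)}\\
S(i+1, j) & \text{(c: } i \text{ unmatched)}\\
\max_{i<k<j}\, S(i, k) + S(k+1, j) & \text{(d: bipartition)}
\end{cases}
\]

with \(S(i, j) = 0\) whenever \(j - i \le d\) (no permitted pair fits) and
empty/inverted intervals read as 0, which also settles rule a at
\(i + 1 = j\). `fold_diagonal()` evaluates by increasing \(j - i\) — the
textbook order. `fold_column()` evaluates per column \(j\): an
*independent* ascending-\(i\) pass applies rules a–b (which never read
column \(j\)), then a *dependent* descending-\(i\) pass applies rules c–d
in the equivalent indexing \(S(i, k-1) + S(k, j)\), \(k = j-1..i+1\). The
two rule-d forms are the same family under a shift of \(k\); the package
standardizes internally on the column form. Rule d is the cubic
bottleneck, and the column order is the one the speedup needs.

## The Four-Russians speedup

Rows of each column are cut into fixed groups of size \(q\):
Rgroup \(g\) holds rows \(gq+1..(g+1)q\); columns are cut identically
(Cgroup 0 is columns \(1..q-1\), Cgroup \(g\) is \(gq..(g+1)q-1\)). The
alignment is fixed once — never re-aligned per column.

Two observations make constant work per group possible:

1. **Bounded marginals.** Growing an interval by one site can raise the
   optimum by at most the maximum pair score, so consecutive values down a
   column differ by a value in \(\{0, \dots, C-1\}\), where
   \(C = \max B + 1\) (\(C = 2\) for the unit scheme). A group's column
   values \(V_g\) — taken from its highest row \(z\) downward, the
   direction in which values never decrease — are therefore captured, up to
   the additive constant \(V_g[1]\), by \(q - 1\) bounded digits
   \(v_g\) (`encode_group()`); `decode_vector()` rebuilds the offsets as
   prefix sums anchored at 0, so `decode(encode(V)) + V[1] == V` exactly.

2. **Additive constants never change an argmax** (the package tests this
   directly). So the best split index \(k^*\) within a group, for a fixed
   lower row \(i\), depends only on \((i, g, v_g)\) — not on the column —
   and can be precomputed in a table \(R(i, g, v)\) over all \(C^{q-1}\)
   digit vectors.

The fill then proceeds per column as before, except that the rule-d loop
walks groups instead of cells: each group lying *strictly inside*
\((i, j)\) is resolved by one table lookup; the at-most-one group cut by
\(i\) and the group cut by \(j-1\) are scanned directly (at most \(2q\)
direct evaluations per cell — an instrumentation counter asserts the
bound). \(v_g\) is encoded the moment the group's lowest cell of the
column is written, and the table for Cgroup \(g\) is built as soon as its
columns are complete — the precomputation is *interleaved* with the fill,
which is what distinguishes this use of the Four-Russians technique, and
the table is ready exactly when the first column that could query it
arrives. Total time is \(O(n^3/q)\) for the rule-d work plus
\(O(n^2 C^{q-1} q)\) for table building; with \(q = \log_b n\) for any
base \(b > C\) this is \(O(n^3/\log n)\).

The evaluation order keeps both boundary partial groups as direct scans.
Reversing the \(i\)/\(k\) order could remove that overhead; we keep the
straightforward order and absorb the \(O(n^2 q)\) term, which simplifies
the interleave invariant and is invisible at the sizes we target.

### Choosing q

`choose_q(n, C, q_max)` returns
\(\mathrm{clamp}(\lfloor \log_{C+1} n \rfloor,\, 2,\, q_{\max})\): base
strictly greater than \(C\) as the time bound requires, clamped below by
the smallest useful group and above by `q_max = 8`. The cap matters
because eager table memory is \(\Theta(n^2 C^{q-1}/q)\) — super-quadratic
at the asymptotic \(q\) — while any constant \(q \ge 2\) preserves
exactness; only the speedup factor changes. Entries are stored as one
byte (an offset within the group), key-major so that consecutive rows of
one slice are adjacent in memory, and a guard refuses \(C^{q-1} > 2^{20}\).

### Conventions fixed once

* **Digit orientation.** Differences are taken in the direction of
  decreasing row index, where they are non-negative; position \(t\) of a
  digit/offset vector corresponds to row \(z - t\) of the group
  (0-based \(t\), \(z\) the group's highest row). Encode, decode, build
  and lookup all share this mapping.
* **Tie-breaks.** \(k^*\) ties resolve to the smallest \(k\) in the
  group, and traceback tries rules in the fixed order a, b, c, d (smallest
  split first), so all outputs are deterministic. Any optimum is equally
  valid; fixing the rule makes tables and structures testable.
* **Degenerate sizes.** When \(n < 2q\) no group is ever strictly
  interior, so the algorithm degrades gracefully to the plain column DP
  through its partial-group path; length-1 sequences yield the single
  zero cell.
* **Eager vs lazy tables.** The default builds every digit vector of a
  group eagerly, as the time analysis assumes. A `lazy` flag computes an
  entry on first lookup instead (same array, sentinel-filled); the score
  matrices are identical and a test asserts it — the flag trades the
  predictable build cost for input-dependent work.

## Traceback and structure output

`traceback_pairs()` re-derives, cell by cell, which rule attains each
value and descends through it — \(O(n^2)\) worst case, no stored
pointers. Keeping back-pointers during the fill would make traceback
\(O(n)\), but the fill dominates total time at every size we touch and
pointer-free matrices keep the three solvers' outputs directly
comparable, which the whole test architecture leans on. Rule a is taken
only when \((i, j)\) is genuinely permitted, so a zero-score tie can
never fabricate a pair. The result validates against the definition
(`validate_matching()`: disjoint, non-crossing, permitted) and serializes
to dot-bracket (`to_dot_bracket()`) or the common 6-column CT dialect
(`write_ct()`/`read_ct()`), chosen for downstream-tool compatibility.

## The synthetic-data generator

`random_rna(n, seed)` draws residues i.i.d. uniformly over the four
nucleotides. This emulates the random test sequences used for
benchmarking this family of algorithms; since the fill's control flow is
sequence-independent, composition does not affect runtime comparisons.
What uniform sequences do *not* emulate: real RNA base composition, GC
skew, or any evolved secondary structure — so passing tests demonstrate
*algorithmic exactness and the claimed work bounds*, not biological
accuracy of predicted structures (which this score model does not aim
for). Correctness evidence does not rest on the generator's realism: the
solvers are checked cell-for-cell against each other on random inputs and
against an exhaustive enumeration oracle (an independent recursion that
shares no code with the DP) on every sequence short enough to enumerate.

## Problem sizes and test design

The suite cross-checks all three solvers on hundreds of random instances
with \(n\) up to 300 across \(q \in \{2,3,4,5\}\), \(d \in \{1,2,3\}\)
and both the unit and an AU=2/CG=3 (\(C = 4\)) scheme — the latter
exercises the generalized \(C\)-ary difference alphabet end-to-end;
oracle agreement is checked on 500+ instances with \(n \le 14\). These
sizes give full code-path coverage (many group alignments, both partial
ends, interleave timing) while keeping the suite fast; exactness at
larger \(n\) follows from the same code paths, and the benchmark harness
(`run_bench()`) runs \(n\) in the thousands. Timing ratios are reported
as indicative only: they are hardware-dependent, and the package treats
the direction of the trend — not any absolute number — as the soft,
non-gating expectation.

## Limitations

* No thermodynamic model: scores are per-pair constants, so predicted
  structures are maximum-score matchings, not minimum-free-energy folds.
* No pseudoknots (by definition of non-crossing), no ambiguity codes.
* Scores must be non-negative integers with at least one positive pair,
  so the difference alphabet is finite — the premise of the encoding.
* The parallel \(O(n^2)\) variant of the speedup is out of scope.

## Package shape

Tabular inputs and outputs (sequence tables, fold summaries, comparison
and benchmark reports) are tibbles and compose with the pipe; fitted
results (`score_matrix`, `rna_fold`) are light S3 objects with
`tidy()`/`glance()`/`autoplot()` methods, since a DP triangle is a matrix,
not a data frame. The command-line layer (`fold`, `compare`, `bench`,
`gen` via `cli_main()` and the installed `exec/rnafour` script) is a thin
veneer over the same functions.
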