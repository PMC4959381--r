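---
title: "Methods: lane-parallel Smith-Waterman scanning and identity distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lane-parallel Smith-Waterman scanning and identity distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swlanes)
```

## What the package computes

swlanes implements two alignment workloads that share one dynamic-programming
core:

1. **Protein database scanning.** A query is compared against every sequence
   of a database with the Smith-Waterman algorithm under affine gap
   penalties, score-only, and subjects are ranked by optimal local score.
   Full alignments are recovered by traceback only for the top-ranked hits,
   where their cost is negligible.
2. **Identity-based distance matrices** (the first stage of the classic
   ClustalW progressive-alignment pipeline). For every sequence pair the
   distance is

   $$d(S_i, S_j) = 1 - \frac{nid(S_i, S_j)}{\min(l_i, l_j)},$$

   where $nid$ is the number of exactly matching residue pairs in an optimal
   local alignment. Stages 2 and 3 of that pipeline (neighbor-joining guide
   tree, progressive alignment) are out of scope; the PHYLIP output feeds
   directly into standard tools for them (e.g. `ape::nj()`).

## The recurrences

For query $Q$ (length $q$) and subject $S$ (length $s$), with substitution
table $sbt$, gap-open penalty $\alpha$ and gap-extend penalty $\beta$ (a gap
of length $g$ costs $\alpha + (g-1)\beta$):

$$
\begin{aligned}
H(i,j) &= \max\{0,\; E(i,j),\; F(i,j),\; H(i-1,j-1) + sbt(Q[i], S[j])\}\\
E(i,j) &= \max\{H(i,j-1) - \alpha,\; E(i,j-1) - \beta\}\\
F(i,j) &= \max\{H(i-1,j) - \alpha,\; F(i-1,j) - \beta\}
\end{aligned}
$$

with $H(i,0) = H(0,j) = E(i,0) = F(0,j) = 0$. The optimal score is the
matrix maximum. $E$ and $F$ are *not* clamped at zero — the recurrences are
used exactly as written; with the zero initial values they are bounded below
by $-\alpha$ in practice, so 32-bit integer arithmetic is ample at any
realistic sequence length.

### Identity counts without traceback

Counting identities normally requires the full matrix plus a traceback,
which is quadratic space. Instead, companion matrices are co-computed in the
same linear-space sweep:

* $N_A(i,j)$ — identities on the path into an $H$ cell: $0$ where
  $H(i,j) = 0$; $N_A(i-1,j-1) + m(i,j)$ on a diagonal step (where
  $m(i,j) = 1$ iff $Q[i] = S[j]$); otherwise inherited from $N_E$ or $N_F$;
* $N_E$, $N_F$ — the same quantity for the gap states, inheriting from
  $N_A(i,j-1)$ / $N_A(i-1,j)$ on gap-open and from themselves on gap-extend,
  and $0$ at $j=1$ / $i=1$ respectively.

Then $nid = N_A(i_{max}, j_{max})$ at the cell carrying the matrix maximum.

**Tie-breaking is the load-bearing design decision here.** Where co-optimal
paths exist the identity count is only well defined once a canonical path is
fixed. The package uses one precedence everywhere: zero-stop, then diagonal,
then horizontal gap, then vertical gap; within a gap state, open before
extend. The traceback routine follows the *same* precedence, which is what
makes the two routes to `nid` comparable exactly, pair for pair — the test
suite exercises exactly this equivalence. Two caveats follow: `nid(Q,S)`
and `nid(S,Q)` may legitimately differ on co-optimal ties (only score
symmetry is guaranteed), and a different-but-equally-valid precedence would
produce a different, equally defensible `nid` on tied paths.

The matrix argmax is the *first* maximum in row-major order, implemented as
a strict-improvement update so the result does not depend on scan
implementation details. A score of zero reports the conventional empty
alignment: cell $(0,0)$, $nid = 0$, distance $1$.

## Lane-parallel execution

Both applications are dominated by many independent pairwise DPs, so the
engine vectorises *across* subject sequences: up to 16 subjects are packed
column-wise into a channel buffer (lanes), and each DP step advances the
same cell of all lanes at once. Subjects are length-sorted first and sliced
into consecutive groups, which minimises the length spread — and hence the
wasted padding — inside each batch. This is the inter-sequence scheme used
by vector-unit database-search implementations; no intra-sequence
(anti-diagonal or striped) mode is provided, and the portable kernel with a
configurable lane count (1–16, default 16, the natural width for 32-bit
integer lanes on 512-bit vector units) replaces hardware-specific variants.
Batches are fixed at packing time; lanes are not refilled as shorter
sequences finish, which costs some padded cells but keeps results trivially
independent of execution order.

Per packed column the engine builds two gather tables before the sweep: the
*sprofile* (`sbt(r, column[k])` for every residue `r` and lane `k`) and the
*mprofile* (the match indicator). Every DP step then reads one 16-wide row
of each instead of doing 16 scalar table lookups. The same structure is
exposed at the R level as `build_column_profiles()` so tests can compare it
entry-by-entry against scalar lookups.

**Padding.** Short lanes are padded with a 25th internal sentinel code whose
substitution score against everything is $-128$ and which never matches.
Padded cells therefore decay to zero under the local-alignment clamp, can
never seed a best-score update (any padded cell's value is strictly below a
real cell already scanned), and never flow back into live columns. Padding
neutrality is asserted directly in the tests by extending batches with extra
sentinel columns.

## Long queries: multi-pass scanning

Very long queries would otherwise force the whole query row set through the
cache at once, so the scanner can process the query in consecutive chunks of
`query_chunk` rows. Between passes it carries, per subject column: the last
$H$ row, the last $F$ row (and the $N_A$/$N_F$ rows when identities are
requested), plus the per-lane running best. $E$ needs no carry because,
when chunking along query rows, $E(i,j)$ depends only on cells of row $i$.
This is the minimal exact state: multi-pass results equal the single pass
bit for bit, which the tests check for chunk sizes from 1 upward.

## Scheduling and the worker pool

Worker processes stand in for cluster nodes; the dispatcher / worker /
collector split mirrors the master–worker layout of distributed aligners so
a network transport could replace the local pool without touching the
engines. Two schemes:

* **Static** (the database-search scheme): the length-sorted database is cut
  into one contiguous chunk per worker, residue totals proportional to
  per-worker *compute-power factors*, cutting only at sequence boundaries
  (scores are per-sequence, so splitting one would change results). Factors
  come from `sample_test()`: each worker times the identical sample scan and
  its factor is cells/second. Only ratios matter. The sample must provide at
  least `min_cells` (default $10^7$) DP cells so the timing is not noise;
  calibration runs once per invocation, not per query.
* **Dynamic** (the distance-matrix scheme): tasks go into an exactly-once
  pool; idle workers pull as they finish. A task whose evaluation fails is
  re-queued once, then the run aborts. The completion ledger (task id,
  worker, attempt) is returned for inspection.

Distance-matrix tasks follow the pivot scheme: the task for pivot $i$ (in
length-sorted order) aligns it against a batch of at most `batch_size`
sequences drawn from $\{i+1..n\}$. The default `batch_size` of 16 makes one
task exactly one lane batch — the finest granularity the engine offers,
which is what a dynamic scheduler wants. The per-dataset workload is
$W = \sum_i L_i \sum_{j>i} L_j$, the exact number of DP cells, and the
per-task cell counts always sum to $W$.

Either scheme, any worker count and any batch size produce bit-identical
hit lists and matrices; merging validates that partials cover the expected
ids exactly once and errors on gaps or overlaps.

## Scoring conventions

* Alphabet: the canonical 24-symbol NCBI order `ARNDCQEGHILKMFPSTWYVBZX*`,
  so BLOSUM flat files load without remapping. BLOSUM62 is bundled;
  arbitrary NCBI-format files are read keyed by symbol, not position.
* Defaults: BLOSUM62 with $\alpha = 10$, $\beta = 2$ — the standard
  protein-search setting. $\alpha = \beta$ gives linear gap costs (the
  +3/−1, gap 1 scheme used in several tests is built with
  `match_mismatch_matrix()`, which is a test device, not a recommended
  search scoring).
* Unknown residues map to `X` by default (real FASTA contains ambiguity
  codes); `unknown = "strict"` rejects them. Coordinates in alignment
  reports are 1-based inclusive.

## The synthetic-sequence generator

All fixtures are generated in code; nothing is downloaded. Plain databases
are i.i.d. uniform draws over the 20 standard residues with fixed, uniform
or (truncated, rounded) normal length models; the default normal model
(mean 465, sd 80) mimics the length structure of curated-protein extracts
used in large-scale benchmarking. Families are built from a random root by
per-site forced substitution at rate $r$ and optional indels (deletion or
insertion with equal probability, geometric(1/2) length) at a per-site rate.
Generation uses integer-based sampling under a caller-supplied seed, so
output is byte-identical across platforms.

What this emulates — and does not: i.i.d. composition has no positional or
compositional bias, no domain structure, no repeats or low-complexity
regions, and the mutation model is uniform rather than a realistic
substitution process (no WAG/LG-style rates). Passing tests therefore
demonstrate algorithmic correctness (exact kernel equivalences, scheduling
invariance, monotone distance behaviour), not retrieval sensitivity on real
protein families.

## Problem sizes and numerical checks

The verification suite uses: 1,000 random pairs of length ≤ 200 for the
kernel equivalences (under both the affine BLOSUM62 scheme and the linear
+3/−1 scheme); a 5,000-sequence database (normal lengths, mean 465) against
10 queries for lane/scalar agreement; a 1,000-sequence database with a
500-residue query for multi-pass exactness at chunk sizes 1, 7, 16 and 64;
datasets of 20 fixed-length sequences spanning a 100× range in $W$ for the
runtime-linearity check (Pearson $r > 0.95$); and 15-member families at
substitution rates 0.05 and 0.25 for the distance ordering. All equivalence
checks are exact integer comparisons — there are no tolerances in the DP
itself. `scripts/acceptance.R` recomputes the same quantities at slightly
smaller sizes from a single `--seed`.

## Known limitations

* 32-bit integer scores; no saturating 8/16-bit fast paths with overflow
  rescan, as hardware-tuned scanners use.
* No E-value or other score statistics, and no heuristic prefilter — every
  subject is scored exactly.
* `nid` on tied co-optimal paths is convention-dependent (see above).
* The worker pool is process-based on one host; it emulates heterogeneous
  nodes (see `throttle` in `sample_test()`) but not network transport.
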