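# swlanes

Lane-parallel Smith-Waterman database scanning and identity-based distance
matrices for protein sequences.

## What it is for

Two everyday workloads in sequence analysis reduce to very many independent
pairwise local alignments:

* **Database search** — score a query against every sequence of a protein
  database with the Smith-Waterman algorithm (affine gaps, score-only,
  exact: no seeding heuristics), rank subjects by optimal local score, and
  produce full alignments only for the top hits.
* **Distance matrices for multiple alignment** — the first (and typically
  dominant) stage of the ClustalW progressive-alignment pipeline:
  for every pair *S<sub>i</sub>*, *S<sub>j</sub>* compute

  *d*(*S<sub>i</sub>*, *S<sub>j</sub>*) = 1 − *nid* / min(*l<sub>i</sub>*, *l<sub>j</sub>*),

  where *nid* is the number of exactly matching residue pairs in an optimal
  local alignment.

The package's core is a set of linear-space DP kernels built around the
affine-gap recurrences (H, E, F with a zero clamp on H) plus companion
recurrences (N<sub>A</sub>, N<sub>E</sub>, N<sub>F</sub>) that deliver *nid*
at the maximum-score cell **without traceback**, so distances need neither
the quadratic-space matrix nor a path reconstruction. Subjects are packed
16 to a batch into a channel buffer and all 16 DP cells advance per step
(inter-sequence vectorization), with per-column score/match gather profiles;
long queries are handled in exact multi-pass chunks; and work is spread over
a local worker pool with either static (sample-test calibrated,
compute-power proportional) or dynamic (exactly-once task pool) scheduling.

Intended users: anyone needing exact protein database scanning or
ClustalW-style stage-1 distances at desk scale, and anyone who wants a
readable, fully tested reference for the traceback-free identity-count
recurrence and for inter-sequence lane vectorization.

## Worked example

```r
library(swlanes)
sch <- scoring_scheme()                     # BLOSUM62, gap open 10, extend 2

db  <- synth_sequences(200, "normal", mean = 465, sd = 80, seed = 42)
fam <- synth_family(5, root_length = 300, sub_rate = 0.1,
                    indel_rate = 0.01, seed = 42, prefix = "fam")
db  <- c(db, fam)                           # hide the family in the database

res <- scan_database(fam[[1]]$residues, db, sch, top_k = 5)
res
#> Smith-Waterman scan: query query (300 aa) vs 206 subjects
#>   28309500 DP cells in 0.20s (0.142 GCUPS)
#> Top hits:
#>  rank subject_id length score
#>     1    famroot    300  1757
#>     2       fam5    300  1555
#>     3       fam3    305  1546
#>     4       fam1    295  1509
#>     5       fam4    305  1469
```

The family root ranks first (it *is* the query, score 1757 = self-score);
its five mutated descendants follow, far above the unrelated background.
The cell count is exact (query length × database residues); GCUPS is
informational. Aligning a top hit:

```r
aln <- align_top_hits(encode_sequence("famroot", fam[[1]]$residues),
                      db, res$hits, sch, k = 2)[[2]]
aln
#> Local alignment famroot[1-300] vs fam5[1-300]  score 1555  nid 272
#>   TCAIDWTPEDCFVWPNHDCMCVRGNAILPGDDWMCDRWNTWQQRVNRQIGCATEDMIHKV
#>   ||||||| ||||||||| |||| ||| || ||||||||| ||||||||||||||| ||||
#>   TCAIDWTMEDCFVWPNHPCMCVWGNAELPEDDWMCDRWNEWQQRVNRQIGCATEDYIHKV
#>   ...
```

272 of 300 positions identical — consistent with the 10% substitution rate.
The distance matrix over the family, computed without any traceback:

```r
dm <- compute_distance_matrix(fam, sch)
round(dm$d, 3)
#>         famroot  fam1  fam2  fam3  fam4  fam5
#> famroot   0.000 0.075 0.110 0.087 0.120 0.093
#> fam1      0.075 0.000 0.183 0.159 0.193 0.159
#> fam2      0.110 0.183 0.000 0.203 0.220 0.197
#> fam3      0.087 0.159 0.203 0.000 0.200 0.173
#> fam4      0.120 0.193 0.220 0.200 0.000 0.190
#> fam5      0.093 0.159 0.197 0.173 0.190 0.000
```

Root–copy distances sit near the substitution rate (0.075–0.120 around
0.1); copy–copy distances are roughly twice that, as two independent
mutation draws should be. `write_phylip_distmat(dm$d, dm$ids, "d.phy")`
emits the square PHYLIP matrix consumed by guide-tree builders
(e.g. `ape::nj()`), and `write_pairs_tsv()` the long-form pair table.

Both applications accept `workers` and `scheduler` arguments; results are
bit-identical for any worker count and either scheduler.

## Command line

A thin wrapper over the same functions is installed at `exec/swlanes`:

```sh
swlanes synth  --n 200 --len-mean 465 --len-sd 80 --seed 1 --out db.fasta
swlanes search --query q.fasta --db db.fasta --matrix BLOSUM62 \
               --gap-open 10 --gap-extend 2 --top 20 --out hits.tsv --align 3
swlanes distmat --in seqs.fasta --workers 4 --scheduler dynamic \
               --out dist.phylip --tsv pairs.tsv
swlanes workload --in seqs.fasta
```

## Documentation

The methods vignette (`vignettes/swlanes-methods.Rmd`) describes the
recurrences, the tie-breaking convention that makes the identity count well
defined, the lane engine and its padding contract, multi-pass state
carrying, the two scheduling schemes, and what the synthetic generator does
and does not emulate.
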