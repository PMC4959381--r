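Package: swlanes
Title: Lane-Parallel Smith-Waterman Database Search and Identity-Based
    Distance Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Score-only Smith-Waterman protein database scanning with
    inter-sequence lane vectorization, multi-pass handling of long queries
    and ranked hit reporting, together with ClustalW stage-1 distance
    matrices computed from a traceback-free exact-match-count dynamic
    programme.  Includes static (sample-test calibrated) and dynamic
    (task-pool) load balancing over a local worker pool, FASTA and NCBI
    substitution-matrix input, PHYLIP distance-matrix output, and a
    deterministic synthetic-sequence generator used by the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    optparse,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
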