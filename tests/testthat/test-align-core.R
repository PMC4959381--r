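test_that("single-cell and clamped scores follow the recurrences", {
  expect_identical(sw_full("A", "A", blosum)$score, 4L)
  expect_identical(sw_full("A", "R", blosum)$score, 0L)
  expect_identical(sw_score_linear("A", "A", blosum),
                   list(score = 4L, best_cell = c(1L, 1L)))
  # perfect 4-residue match under +3/-1, linear gap 1
  expect_identical(sw_full("ACGT", "ACGT", mm31)$score, 12L)
  # zero-score pair reports the conventional empty-alignment cell
  r0 <- sw_score_linear("AAA", "CCC", mm31)
  expect_identical(r0$score, 0L)
  expect_identical(r0$best_cell, c(0L, 0L))
})

test_that("gap costs are affine: alpha for the first residue, beta after", {
  # Q aligns with a gap of length g in the subject: score = matches - gap
  sch <- scoring_scheme(match_mismatch_matrix(5L, -4L), 3L, 1L)
  # AAAA vs AA--AA style: 8 matches minus alpha + beta for the 2-gap
  expect_identical(sw_full("AAAACCAAAA", "AAAAAAAA", sch)$score,
                   8L * 5L - (3L + 1L))
})

test_that("linear-space score equals the full-matrix oracle exactly", {
  set.seed(101)
  for (t in 1:200) {
    p <- rand_pair(120L)
    sch <- if (t %% 2L) blosum else mm31
    f <- sw_full(p$q, p$s, sch)
    l <- sw_score_linear(p$q, p$s, sch)
    expect_identical(l$score, f$score)
    expect_identical(l$best_cell, f$best_cell)
  }
})

test_that("traceback alignments are valid and score-consistent", {
  set.seed(102)
  for (t in 1:50) {
    p <- rand_pair(80L)
    sch <- if (t %% 2L) blosum else mm31
    aln <- sw_traceback(p$q, p$s, sch)
    if (aln$score == 0L) {
      expect_identical(aln$nid, 0L)
      expect_identical(aln$query_aln, "")
      next
    }
    expect_identical(nchar(aln$query_aln), nchar(aln$subject_aln))
    qa <- strsplit(aln$query_aln, "")[[1L]]
    sa <- strsplit(aln$subject_aln, "")[[1L]]
    expect_false(any(qa == "-" & sa == "-"))
    # aligned segments reproduce the claimed coordinates
    expect_identical(paste(qa[qa != "-"], collapse = ""),
                     substr(p$q, aln$q_start, aln$q_end))
    expect_identical(paste(sa[sa != "-"], collapse = ""),
                     substr(p$s, aln$s_start, aln$s_end))
    # column-wise rescoring equals the DP score
    expect_identical(swlanes:::alignment_score(aln, sch), aln$score)
    expect_identical(aln$nid, sum(qa == sa & qa != "-"))
  }
})

test_that("traceback handles the worked deletion example", {
  aln <- sw_traceback("ACGTA", "ACTA", mm31)
  expect_identical(aln$nid, 4L)
  expect_identical(sw_traceback("AAA", "CCC", mm31)$score, 0L)
  full <- sw_traceback("AAAA", "AAAA", blosum)
  expect_identical(full$nid, 4L)
  expect_identical(full$query_aln, "AAAA")
})

test_that("traceback-free identity count equals the traceback count", {
  set.seed(103)
  for (t in 1:200) {
    p <- rand_pair(120L)
    sch <- if (t %% 2L) blosum else mm31
    lin <- sw_nid_linear(p$q, p$s, sch)
    tb <- sw_traceback(p$q, p$s, sch)
    expect_identical(lin$nid, tb$nid)
    expect_identical(lin$score, tb$score)
    expect_lte(lin$nid, min(nchar(p$q), nchar(p$s)))
    expect_gte(lin$nid, 0L)
  }
  # self-alignment matches everywhere
  s <- rand_protein(75L)
  expect_identical(sw_nid_linear(s, s, blosum)$nid, 75L)
  expect_identical(sw_nid_linear("AAA", "CCC", mm31),
                   list(score = 0L, nid = 0L, best_cell = c(0L, 0L)))
})

test_that("scores agree with an independent aligner on random pairs", {
  # Biostrings charges open+extend for the first gap position, so its
  # opening penalty is alpha - beta under this package's convention.
  ref62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  set.seed(104)
  for (t in 1:40) {
    p <- rand_pair(80L)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(p$q), Biostrings::AAString(p$s), type = "local",
      substitutionMatrix = ref62, gapOpening = 8, gapExtension = 2,
      scoreOnly = TRUE)
    expect_identical(sw_score_linear(p$q, p$s, blosum)$score, as.integer(ref))
  }
})

test_that("score is symmetric and monotone under appending residues", {
  set.seed(105)
  for (t in 1:40) {
    p <- rand_pair(100L)
    expect_identical(sw_score_linear(p$q, p$s, blosum)$score,
                     sw_score_linear(p$s, p$q, blosum)$score)
    ext <- paste0(p$q, rand_protein(10L))
    expect_gte(sw_score_linear(ext, p$s, blosum)$score,
               sw_score_linear(p$q, p$s, blosum)$score)
  }
})
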