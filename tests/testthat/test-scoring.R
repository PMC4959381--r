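test_that("bundled BLOSUM62 has the canonical values and shape", {
  m <- load_substitution_matrix("BLOSUM62")
  expect_identical(dim(m), c(24L, 24L))
  expect_identical(m, t(m))
  expect_identical(m["A", "A"], 4L)
  expect_identical(m["A", "R"], -1L)
  expect_identical(m["W", "W"], 11L)
  # strictly positive self-scores for the 20 standard residues
  expect_true(all(diag(m)[1:20] > 0L))
})

test_that("bundled BLOSUM62 matches the independent reference table", {
  ref <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  m <- load_substitution_matrix("BLOSUM62")
  expect_identical(unname(m), unname(ref[rownames(m), colnames(m)]))
})

test_that("matrix files are keyed by symbol, not position", {
  aa <- aa_alphabet()
  ident <- matrix(-1L, 24L, 24L, dimnames = list(aa, aa))
  diag(ident) <- 1L
  write_flat <- function(m, order, path) {
    con <- file(path, "w")
    writeLines("# test matrix", con)
    writeLines(paste(" ", paste(order, collapse = "  ")), con)
    for (r in order) {
      writeLines(paste(r, paste(m[r, order], collapse = " ")), con)
    }
    close(con)
  }
  f1 <- withr::local_tempfile(fileext = ".txt")
  write_flat(ident, aa, f1)
  expect_identical(load_substitution_matrix(f1), ident)
  # permuted row/column order must read back to the same keyed table
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_flat(ident, rev(aa), f2)
  expect_identical(load_substitution_matrix(f2), ident)
})

test_that("asymmetric or incomplete matrix files are rejected", {
  f <- withr::local_tempfile(fileext = ".txt")
  aa <- aa_alphabet()
  m <- matrix(0L, 24L, 24L, dimnames = list(aa, aa))
  m["A", "R"] <- 5L   # not mirrored
  con <- file(f, "w")
  writeLines(paste(" ", paste(aa, collapse = " ")), con)
  for (r in aa) writeLines(paste(r, paste(m[r, ], collapse = " ")), con)
  close(con)
  expect_error(load_substitution_matrix(f), "symmetric")
  expect_error(load_substitution_matrix("no-such-matrix-xyz"), "not found")
})

test_that("sequence encoding is a bijection with case folding and X policy", {
  enc <- encode_sequence("t", "ARN")
  expect_identical(enc$codes, c(0L, 1L, 2L))
  expect_identical(encode_sequence("t", "arn")$codes, enc$codes)
  expect_identical(decode_sequence(enc), "ARN")
  # every alphabet symbol round-trips
  all_sym <- paste(aa_alphabet(), collapse = "")
  expect_identical(decode_sequence(encode_sequence("t", all_sym)), all_sym)
  # unknown residues: default maps to X, strict rejects
  x_code <- which(aa_alphabet() == "X") - 1L
  expect_identical(encode_sequence("t", "AJA")$codes[2L], x_code)
  expect_error(encode_sequence("t", "AJA", unknown = "strict"), "unknown")
  expect_error(encode_sequence("t", "  "), "empty")
})

test_that("gap penalties are validated", {
  expect_error(scoring_scheme(gap_open = 1, gap_extend = 2), "gap_open")
  expect_error(scoring_scheme(gap_open = -1), "gap_open")
  sch <- scoring_scheme(gap_open = 3, gap_extend = 3)  # linear gaps allowed
  expect_identical(sch$alpha, 3L)
})

test_that("column profiles equal independent scalar lookups", {
  sch <- blosum
  # worked example: 16 lanes of 'A' against residue 'A'
  colA <- rep(0L, 16L)
  pr <- build_column_profiles(colA, sch)
  expect_identical(unname(pr$sprofile["A", ]), rep(4L, 16L))
  expect_identical(unname(pr$mprofile["A", ]), rep(1L, 16L))
  pr2 <- build_column_profiles(c(0L, 1L), sch)
  expect_identical(unname(pr2$mprofile["A", ]), c(1L, 0L))
  # exhaustive: random 16-lane columns, all 24 residues
  set.seed(11)
  for (rep in 1:10) {
    column <- sample(0:23, 16L, replace = TRUE)
    pr <- build_column_profiles(column, sch)
    for (r in 0:23) {
      expect_identical(unname(pr$sprofile[r + 1L, ]),
                       unname(sch$sbt[r + 1L, column + 1L]))
      expect_identical(unname(pr$mprofile[r + 1L, ]),
                       as.integer(column == r))
    }
    # non-padding lanes: exactly one match indicator per column
    expect_identical(unname(colSums(pr$mprofile)), rep(1, 16))
  }
  # sentinel column: never matches, always scores the floor
  prs <- build_column_profiles(c(0L, 24L), sch)
  expect_identical(unname(prs$sprofile[, 2L]), rep(-128L, 24L))
  expect_identical(sum(prs$mprofile[, 2L]), 0L)
  expect_error(build_column_profiles(c(0L, 25L), sch), "invalid")
  expect_error(build_column_profiles(integer(0L), sch), "lane count")
})
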