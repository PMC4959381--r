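# Scalar Smith-Waterman kernels.  sw_full() keeps the whole DP matrix and is
# the package's brute-force oracle; sw_score_linear() and sw_nid_linear() are
# the linear-space production kernels; sw_traceback() recovers one optimal
# local alignment under the same fixed branch precedence the identity-count
# recurrence uses, so the two routes to nid are comparable cell for cell.

as_encoded <- function(x, id = "seq") {
  if (inherits(x, "encoded_seq")) return(x)
  if (is.character(x) && length(x) == 1L) return(encode_sequence(id, x))
  stop("expected an encoded_seq or a residue string")
}

#' Full-matrix Smith-Waterman (oracle)
#'
#' Computes the complete affine-gap local-alignment DP matrices `H`, `E`,
#' `F` with zero initial borders and clamped `H`.  Quadratic space; meant
#' for verification and traceback, not for database scanning.
#'
#' @param query,subject `encoded_seq` objects or residue strings.
#' @param scheme An [scoring_scheme()].
#' @return List with `score`, `best_cell` (first row-major argmax, `c(0, 0)`
#'   for an all-zero matrix), and matrices `H`, `E`, `F` of dimension
#'   `(q+1) x (s+1)`.
#' @export
sw_full <- function(query, subject, scheme) {
  q <- as_encoded(query, "query"); s <- as_encoded(subject, "subject")
  r <- cpp_sw_full(q$codes, s$codes, scheme$sbt_ext, scheme$alpha, scheme$beta)
  list(score = r$score, best_cell = c(r$best_i, r$best_j),
       H = r$H, E = r$E, F = r$F)
}

#' Linear-space score-only Smith-Waterman
#'
#' Same recurrences as [sw_full()] but holding only rolling rows, so memory
#' is proportional to the subject length.  Returns the identical optimal
#' score and argmax cell.
#'
#' @inheritParams sw_full
#' @return List with `score` and `best_cell`.
#' @export
sw_score_linear <- function(query, subject, scheme) {
  q <- as_encoded(query, "query"); s <- as_encoded(subject, "subject")
  r <- cpp_sw_linear(q$codes, s$codes, scheme$sbt_ext, scheme$alpha,
                     scheme$beta, FALSE)
  list(score = r$score, best_cell = c(r$best_i, r$best_j))
}

#' Linear-space score plus identity count
#'
#' Runs the companion recurrences for the number of exactly matching
#' residue pairs (`N_A`, with `N_E`/`N_F` for the gap states) alongside the
#' score DP, and reports the count at the maximum-score cell.  This equals
#' the identity count obtained by tracing back one optimal local alignment
#' under the package's branch precedence, without storing the matrix.
#'
#' @inheritParams sw_full
#' @return List with `score`, `nid`, `best_cell`.
#' @export
sw_nid_linear <- function(query, subject, scheme) {
  q <- as_encoded(query, "query"); s <- as_encoded(subject, "subject")
  r <- cpp_sw_linear(q$codes, s$codes, scheme$sbt_ext, scheme$alpha,
                     scheme$beta, TRUE)
  list(score = r$score, nid = r$nid, best_cell = c(r$best_i, r$best_j))
}

#' Optimal local alignment with traceback
#'
#' Recovers one optimal local alignment from the full DP matrices, starting
#' at the first row-major maximum cell and stopping at the first zero `H`
#' cell.  Branch precedence is fixed: diagonal, then horizontal gap (open
#' before extend), then vertical gap (open before extend), matching the
#' case order of the traceback-free identity-count recurrence so both
#' routes follow the same co-optimal path.
#'
#' @inheritParams sw_full
#' @return A `local_alignment`: aligned segments (with `-` gaps), 1-based
#'   inclusive start/end coordinates on both sequences, `score`, and `nid`
#'   (count of identical aligned pairs).  A zero score yields the empty
#'   alignment with `nid = 0`.
#' @export
sw_traceback <- function(query, subject, scheme) {
  q <- as_encoded(query, "query"); s <- as_encoded(subject, "subject")
  full <- sw_full(q, s, scheme)
  H <- full$H; E <- full$E; F <- full$F
  alpha <- scheme$alpha; beta <- scheme$beta
  qc <- q$codes; sc <- s$codes
  i <- full$best_cell[[1L]]; j <- full$best_cell[[2L]]
  qa <- character(0L); sa <- character(0L)
  qi_end <- i; sj_end <- j
  state <- "H"
  while (i > 0L && j > 0L) {
    hij <- H[i + 1L, j + 1L]
    if (state == "H") {
      if (hij == 0L) break
      d <- H[i, j] + scheme$sbt_ext[qc[i] + 1L, sc[j] + 1L]
      if (hij == d) {
        qa <- c(AA_ORDER[qc[i] + 1L], qa); sa <- c(AA_ORDER[sc[j] + 1L], sa)
        i <- i - 1L; j <- j - 1L
      } else if (hij == E[i + 1L, j + 1L]) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      e <- E[i + 1L, j + 1L]
      qa <- c("-", qa); sa <- c(AA_ORDER[sc[j] + 1L], sa)
      if (e == H[i + 1L, j] - alpha) state <- "H"
      j <- j - 1L
    } else {
      f <- F[i + 1L, j + 1L]
      qa <- c(AA_ORDER[qc[i] + 1L], qa); sa <- c("-", sa)
      if (f == H[i, j + 1L] - alpha) state <- "H"
      i <- i - 1L
    }
  }
  empty <- full$score == 0L
  nid <- if (empty) 0L else sum(qa == sa & qa != "-")
  structure(list(
    query_id = q$id, subject_id = s$id,
    query_aln = if (empty) "" else paste(qa, collapse = ""),
    subject_aln = if (empty) "" else paste(sa, collapse = ""),
    q_start = if (empty) 0L else i + 1L,
    q_end = if (empty) 0L else qi_end,
    s_start = if (empty) 0L else j + 1L,
    s_end = if (empty) 0L else sj_end,
    score = full$score, nid = as.integer(nid)
  ), class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, width = 60L, ...) {
  cat(sprintf("Local alignment %s[%d-%d] vs %s[%d-%d]  score %d  nid %d\n",
              x$query_id, x$q_start, x$q_end,
              x$subject_id, x$s_start, x$s_end, x$score, x$nid))
  if (!nzchar(x$query_aln)) {
    cat("  (empty alignment)\n")
    return(invisible(x))
  }
  qa <- strsplit(x$query_aln, "")[[1L]]
  sa <- strsplit(x$subject_aln, "")[[1L]]
  bar <- ifelse(qa == sa & qa != "-", "|", " ")
  n <- length(qa)
  for (off in seq(1L, n, by = width)) {
    idx <- off:min(off + width - 1L, n)
    cat("  ", paste(qa[idx], collapse = ""), "\n", sep = "")
    cat("  ", paste(bar[idx], collapse = ""), "\n", sep = "")
    cat("  ", paste(sa[idx], collapse = ""), "\n", sep = "")
  }
  invisible(x)
}

# Recompute an alignment's score from its columns; used by tests and by
# align_top_hits() consistency checks.
alignment_score <- function(aln, scheme) {
  if (!nzchar(aln$query_aln)) return(0L)
  qa <- strsplit(aln$query_aln, "")[[1L]]
  sa <- strsplit(aln$subject_aln, "")[[1L]]
  stopifnot(length(qa) == length(sa), !any(qa == "-" & sa == "-"))
  score <- 0L
  gap_state <- "none"   # which sequence the current gap run sits in
  for (k in seq_along(qa)) {
    if (qa[k] == "-") {
      score <- score - (if (gap_state == "q") scheme$beta else scheme$alpha)
      gap_state <- "q"
    } else if (sa[k] == "-") {
      score <- score - (if (gap_state == "s") scheme$beta else scheme$alpha)
      gap_state <- "s"
    } else {
      a <- match(qa[k], AA_ORDER); b <- match(sa[k], AA_ORDER)
      score <- score + scheme$sbt[a, b]
      gap_state <- "none"
    }
  }
  score
}
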