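# Inter-sequence lane parallelism: subjects are length-sorted, packed 16 to
# a batch into a column-wise residue buffer, and every DP step advances the
# same cell of all lanes.  This mirrors vector-unit channel buffers while
# staying portable; the scalar kernel is the one-lane degenerate case.

#' Pack sequences into lane batches
#'
#' Sorts sequences by length (descending, ties by input order) and slices
#' the sorted list into consecutive groups of at most `lane_count`, so the
#' length spread inside each batch -- and with it the wasted padding -- is
#' minimal.  The last batch may be partially filled.
#'
#' @param sequences List of `encoded_seq`.
#' @param lane_count Lanes per batch, 1..16 (default 16).
#' @return List of `lane_batch` objects: `seq_ids`, `lane_lengths`,
#'   `columns` (max length x lane_count residue-code matrix, sentinel
#'   padded), `input_index` (positions in the original list).
#' @export
sort_and_batch <- function(sequences, lane_count = 16L) {
  stopifnot(length(sequences) >= 1L)
  lane_count <- as.integer(lane_count)
  if (is.na(lane_count) || lane_count < 1L || lane_count > 16L) {
    stop("lane_count must be between 1 and 16")
  }
  lens <- vapply(sequences, function(s) s$length, integer(1L))
  ord <- order(-lens, seq_along(sequences))
  idx_groups <- unname(split(ord, ceiling(seq_along(ord) / lane_count)))
  lapply(idx_groups, function(idx) make_lane_batch(sequences[idx], idx))
}

# Build one packed batch from <= 16 sequences (already grouped).
make_lane_batch <- function(seqs, input_index = seq_along(seqs)) {
  L <- length(seqs)
  stopifnot(L >= 1L, L <= 16L)
  lens <- vapply(seqs, function(s) s$length, integer(1L))
  maxlen <- max(lens)
  cols <- matrix(SENTINEL_CODE, nrow = maxlen, ncol = L)
  for (k in seq_len(L)) cols[seq_len(lens[k]), k] <- seqs[[k]]$codes
  structure(list(
    seq_ids = vapply(seqs, function(s) s$id, character(1L)),
    lane_lengths = lens,
    columns = cols,
    input_index = as.integer(input_index)
  ), class = "lane_batch")
}

#' @export
print.lane_batch <- function(x, ...) {
  cat("<lane_batch> ", length(x$lane_lengths), " lanes, lengths ",
      min(x$lane_lengths), "-", max(x$lane_lengths), "\n", sep = "")
  invisible(x)
}

# Fresh carry state for a batch: zero boundary rows and zero running best.
new_pass_state <- function(batch) {
  L <- ncol(batch$columns); maxlen <- nrow(batch$columns)
  zero <- matrix(0L, L, maxlen + 1L)
  list(Hrow = zero, Frow = zero, NArow = zero, NFrow = zero,
       best_score = integer(L), best_i = integer(L), best_j = integer(L),
       best_nid = integer(L), rows_done = 0L)
}

# Advance the lane DP over one chunk of query rows, carrying boundary state.
run_lane_pass <- function(query_codes_chunk, batch, scheme, state,
                          with_nid = FALSE) {
  out <- cpp_lane_pass(query_codes_chunk, state$rows_done, batch$columns,
                       scheme$sbt_ext, scheme$alpha, scheme$beta, with_nid,
                       state$Hrow, state$Frow, state$NArow, state$NFrow,
                       state$best_score, state$best_i, state$best_j,
                       state$best_nid)
  out$rows_done <- state$rows_done + length(query_codes_chunk)
  out
}

#' Lane-parallel score-only Smith-Waterman
#'
#' Aligns one query against every live lane of a packed batch in a single
#' row-by-row sweep, gathering substitution scores through per-column
#' profiles.  Each lane's result is exactly the scalar
#' [sw_score_linear()] value for that pair; padding lanes report 0.
#'
#' @param query An `encoded_seq` or residue string.
#' @param batch A `lane_batch`.
#' @param scheme An [scoring_scheme()].
#' @return Integer vector of per-lane scores, named by `seq_ids`.
#' @export
lane_sw_scores <- function(query, batch, scheme) {
  q <- as_encoded(query, "query")
  st <- run_lane_pass(q$codes, batch, scheme, new_pass_state(batch), FALSE)
  stats::setNames(st$best_score, batch$seq_ids)
}

#' Lane-parallel score and identity count
#'
#' As [lane_sw_scores()] but co-running the exact-match-count recurrences,
#' reading both the score profile and the match-indicator profile at each
#' step.  Per lane the result equals the scalar [sw_nid_linear()] output.
#'
#' @inheritParams lane_sw_scores
#' @return Data frame with columns `seq_id`, `score`, `nid`.
#' @export
lane_sw_nid <- function(query, batch, scheme) {
  q <- as_encoded(query, "query")
  st <- run_lane_pass(q$codes, batch, scheme, new_pass_state(batch), TRUE)
  data.frame(seq_id = batch$seq_ids, score = st$best_score,
             nid = st$best_nid, stringsAsFactors = FALSE)
}
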