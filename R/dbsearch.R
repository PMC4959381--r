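# Database scanning: chunked, multi-pass, lane-parallel score-only search of
# a protein FASTA database with a single query, ranked top-k reporting and
# traceback alignment of the top hits only (the alignments take negligible
# time next to the score-only scan).

#' Scan a protein database with a query
#'
#' Scores every database sequence against the query with score-only
#' affine-gap Smith-Waterman, using 16-lane inter-sequence parallel DP over
#' a length-sorted packing of the database.  Long queries can be processed
#' in multiple passes of at most `query_chunk` rows with boundary state
#' carried between passes; results are identical to a single pass.  Hits
#' are ranked by score, ties broken by database input order, and the ranked
#' list is identical for any worker count and either scheduler.
#'
#' @param query `encoded_seq`, residue string, or single-record FASTA path.
#' @param db FASTA path or list of records / `encoded_seq`.
#' @param scheme An [scoring_scheme()].
#' @param top_k Number of hits to report (default 20).
#' @param lane_count Lanes per batch, 1..16.
#' @param query_chunk Maximum query rows per pass; 0 (default) scans in a
#'   single pass.
#' @param workers Worker processes (default 1).
#' @param scheduler `"static"` (proportional contiguous chunks, the
#'   database-search scheme) or `"dynamic"` (task pool).
#' @param powers Optional compute-power factors for the static scheduler
#'   (defaults to equal shares); see [sample_test()].
#' @param max_query_len Hard cap on query length (reject longer queries).
#' @return An `sw_search` object: `hits` (rank, subject_id, length, score),
#'   `scores` (all subjects), `cells` (exact DP cell count), `elapsed`,
#'   `ledger` (dynamic scheduler only).
#' @examples
#' db <- synth_sequences(30, length_model = "fixed", length = 60, seed = 2)
#' sch <- scoring_scheme()
#' res <- scan_database(db[[1]]$residues, db, sch, top_k = 5)
#' res$hits
#' @export
scan_database <- function(query, db, scheme, top_k = 20L, lane_count = 16L,
                          query_chunk = 0L, workers = 1L,
                          scheduler = c("static", "dynamic"), powers = NULL,
                          max_query_len = 100000L) {
  scheduler <- match.arg(scheduler)
  force(scheme)   # forced before closures are shipped to worker processes
  stopifnot(top_k >= 1L, query_chunk >= 0L, workers >= 1L)
  t0 <- proc.time()[["elapsed"]]
  if (is.character(db) && length(db) == 1L) db <- read_fasta(db)
  if (length(db) == 0L) stop("empty database")
  if (is.character(query) && length(query) == 1L && file.exists(query)) {
    query <- read_fasta(query)[[1L]]
  }
  if (is.list(query) && !inherits(query, "encoded_seq")) {
    query <- encode_sequence(query$id, query$residues)
  }
  q <- as_encoded(query, "query")
  if (q$length > max_query_len) {
    stop("query length ", q$length, " exceeds the configured cap of ",
         max_query_len, " residues")
  }
  db_enc <- encode_records(db)
  db_ids <- vapply(db_enc, function(s) s$id, character(1L))
  db_lens <- vapply(db_enc, function(s) s$length, integer(1L))

  scan_batch <- function(batch) {
    scores <- if (query_chunk > 0L) {
      multipass_scan(q, batch, scheme, query_chunk)
    } else {
      lane_sw_scores(q, batch, scheme)
    }
    data.frame(subject_id = batch$seq_ids,
               length = batch$lane_lengths,
               score = as.integer(scores),
               db_order = batch$input_index,
               stringsAsFactors = FALSE)
  }

  ledger <- NULL
  if (scheduler == "dynamic") {
    batches <- sort_and_batch(db_enc, lane_count)
    tasks <- lapply(seq_along(batches), function(i) {
      list(id = paste0("b", i), batch = batches[[i]])
    })
    run <- dynamic_pool_run(tasks, function(t) scan_batch(t$batch), workers)
    partials <- run$results
    ledger <- run$ledger
  } else {
    if (is.null(powers)) powers <- rep(1, workers)
    # re-organized (length-sorted) order, cut into per-worker chunks
    ord <- order(-db_lens, seq_along(db_enc))
    chunks <- static_partition(db_enc[ord], powers)
    chunk_fn <- function(idx_local) {
      idx <- ord[idx_local]
      sub <- db_enc[idx]
      batches <- sort_and_batch(sub, lane_count)
      do.call(rbind, lapply(batches, function(b) {
        b$input_index <- idx[b$input_index]   # map back to db positions
        scan_batch(b)
      }))
    }
    live <- which(vapply(chunks, length, integer(1L)) > 0L)
    partials <- if (workers == 1L) {
      lapply(chunks[live], chunk_fn)
    } else {
      static_pool_run(chunks, chunk_fn, workers)
    }
  }

  all_scores <- do.call(rbind, partials)
  hits <- merge_results(partials, "search", expected = db_ids, top_k = top_k)
  elapsed <- proc.time()[["elapsed"]] - t0
  structure(list(
    query_id = q$id, query_length = q$length,
    hits = hits,
    scores = all_scores[order(all_scores$db_order),
                        c("subject_id", "length", "score"), drop = FALSE],
    cells = as.numeric(q$length) * sum(as.numeric(db_lens)),
    elapsed = elapsed,
    ledger = ledger,
    params = list(top_k = top_k, lane_count = lane_count,
                  query_chunk = query_chunk, workers = workers,
                  scheduler = scheduler, alpha = scheme$alpha,
                  beta = scheme$beta)
  ), class = "sw_search")
}

#' @export
print.sw_search <- function(x, ...) {
  st <- cell_stats(x)
  cat(sprintf("Smith-Waterman scan: query %s (%d aa) vs %d subjects\n",
              x$query_id, x$query_length, nrow(x$scores)))
  cat(sprintf("  %.0f DP cells in %.2fs (%.3f GCUPS)\n",
              st$total_cells, st$elapsed, st$gcups))
  cat("Top hits:\n")
  print(head(x$hits, 10L), row.names = FALSE)
  invisible(x)
}

#' Multi-pass lane scan of one batch
#'
#' Processes the query in consecutive chunks of at most `query_chunk` rows,
#' carrying the boundary DP state (last H row, last F row, running best) per
#' subject column between passes.  The horizontal-gap state E needs no
#' carry: when chunking along query rows it only depends on cells within
#' the current row.  Scores are exactly those of a single pass.
#'
#' @inheritParams lane_sw_scores
#' @param query_chunk Maximum query rows per pass (>= 1).
#' @return Integer vector of per-lane scores, named by `seq_ids`.
#' @export
multipass_scan <- function(query, batch, scheme, query_chunk) {
  q <- as_encoded(query, "query")
  stopifnot(query_chunk >= 1L)
  state <- new_pass_state(batch)
  starts <- seq(1L, q$length, by = query_chunk)
  for (st in starts) {
    chunk <- q$codes[st:min(st + query_chunk - 1L, q$length)]
    state <- run_lane_pass(chunk, batch, scheme, state, FALSE)
  }
  stats::setNames(state$best_score, batch$seq_ids)
}

#' Traceback alignments for the top hits
#'
#' Computes full local alignments for the `k` best-ranked hits only.  Each
#' alignment's score is checked against the scanned score; a mismatch would
#' indicate kernel disagreement and raises an error.
#'
#' @param query `encoded_seq` or residue string.
#' @param db The database used for the scan (list of records or
#'   `encoded_seq`).
#' @param hits Ranked hit data frame (from `sw_search$hits`).
#' @param scheme The scheme used for the scan.
#' @param k Number of top hits to align (truncated to the hits available).
#' @return List of `local_alignment` objects.
#' @export
align_top_hits <- function(query, db, hits, scheme, k = 5L) {
  q <- as_encoded(query, "query")
  if (is.character(db) && length(db) == 1L) db <- read_fasta(db)
  db_enc <- encode_records(db)
  ids <- vapply(db_enc, function(s) s$id, character(1L))
  k <- min(k, nrow(hits))
  lapply(seq_len(k), function(r) {
    sid <- hits$subject_id[r]
    subj <- db_enc[[match(sid, ids)]]
    aln <- sw_traceback(q, subj, scheme)
    if (aln$score != hits$score[r]) {
      stop("traceback score ", aln$score, " != scanned score ",
           hits$score[r], " for subject ", sid)
    }
    aln
  })
}

#' DP-cell accounting for a finished scan
#'
#' The cell count is exact and hardware-independent: query length times
#' total database residues.  GCUPS (giga cell updates per second) is the
#' count divided by wall time and is informational only.
#'
#' @param report An `sw_search` object.
#' @return List with `total_cells`, `elapsed` (seconds), `gcups`.
#' @export
cell_stats <- function(report) {
  stopifnot(inherits(report, "sw_search"))
  list(total_cells = report$cells, elapsed = report$elapsed,
       gcups = report$cells / max(report$elapsed, 1e-9) / 1e9)
}
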