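# ClustalW stage-1: the all-pairs distance matrix.  The distance between two
# sequences is d = 1 - nid/min(l_i, l_j), where nid is the number of exact
# matches in an optimal local alignment -- computed here without traceback by
# the companion recurrences, so the whole matrix runs in linear space per
# pair.  Pairs are organised into pivot-vs-trailing-batch tasks over the
# length-sorted set, the granularity both schedulers work with.

#' Identity-based distance between two sequences
#'
#' `d = 1 - nid / min(l_i, l_j)`: 0 for identical sequences, 1 when no
#' positive-scoring local alignment exists.
#'
#' @param s_i,s_j `encoded_seq` objects or residue strings.
#' @param scheme An [scoring_scheme()].
#' @return Distance in \[0, 1\].
#' @export
pair_distance <- function(s_i, s_j, scheme) {
  a <- as_encoded(s_i, "s_i"); b <- as_encoded(s_j, "s_j")
  r <- sw_nid_linear(a, b, scheme)
  1 - r$nid / min(a$length, b$length)
}

#' Partition all sequence pairs into alignment tasks
#'
#' Sequences are length-sorted (descending, ties by input order); the task
#' for pivot `i` aligns it against the trailing set `{i+1..n}`, sliced into
#' subject batches of at most `batch_size` (each then lane-packed).  The
#' union of all tasks' (pivot, subject) pairs is the strict upper triangle
#' of the sorted order, each pair exactly once.
#'
#' @param sequences List of `encoded_seq` (>= 2).
#' @param batch_size Subjects per task (default 16, one lane batch).
#' @return List with `tasks` (each: `id`, `pivot`, `subjects` -- positions
#'   in the sorted order), `order` (sorted positions into the input), and
#'   `lengths` (sorted).
#' @export
make_tasks <- function(sequences, batch_size = 16L) {
  n <- length(sequences)
  if (n < 2L) stop("need at least 2 sequences")
  stopifnot(batch_size >= 1L)
  lens <- vapply(sequences, function(s) s$length, integer(1L))
  ord <- order(-lens, seq_len(n))
  sorted_lens <- lens[ord]
  tasks <- list()
  for (i in seq_len(n - 1L)) {
    trailing <- (i + 1L):n
    groups <- split(trailing, ceiling(seq_along(trailing) / batch_size))
    for (g in seq_along(groups)) {
      tasks[[length(tasks) + 1L]] <- list(
        id = paste0("t", i, ".", g),
        pivot = i,
        subjects = groups[[g]],
        cells = as.numeric(sorted_lens[i]) *
          sum(as.numeric(sorted_lens[groups[[g]]]))
      )
    }
  }
  list(tasks = tasks, order = ord, lengths = sorted_lens)
}

#' Total DP workload of a dataset
#'
#' `W = sum_i L_i * sum_{j>i} L_j` -- the total number of DP matrix cells
#' needed for the all-pairs distance computation.  With per-cell work
#' constant, runtime grows linearly in `W`.  When `batch_size` is given the
#' per-task cell counts of the corresponding task partition (over the
#' length-sorted order) are included; they always sum to `W`.
#'
#' @param lengths Integer vector of sequence lengths (n >= 1).
#' @param batch_size Optional; subjects per task for the per-task breakdown.
#' @return List with `W` and, if requested, `per_task` (named by task id).
#' @examples
#' workload(c(2, 3, 4))$W  # 26
#' @export
workload <- function(lengths, batch_size = NULL) {
  lengths <- as.numeric(lengths)
  stopifnot(length(lengths) >= 1L, all(lengths >= 1))
  W <- (sum(lengths)^2 - sum(lengths^2)) / 2
  out <- list(W = W)
  if (!is.null(batch_size) && length(lengths) >= 2L) {
    fake <- lapply(seq_along(lengths), function(i) {
      structure(list(id = paste0("s", i), codes = integer(0L),
                     length = as.integer(lengths[i])), class = "encoded_seq")
    })
    tp <- make_tasks(fake, batch_size)
    out$per_task <- stats::setNames(
      vapply(tp$tasks, `[[`, numeric(1L), "cells"),
      vapply(tp$tasks, `[[`, character(1L), "id"))
  }
  out
}

#' Compute the all-pairs distance matrix
#'
#' Every upper-triangle pair is aligned exactly once with the lane-parallel
#' score+identity kernel; the matrix is mirrored, zero on the diagonal, and
#' identical across scheduler types, worker counts and batch sizes.
#' Distances are computed over the length-sorted order and reported in the
#' original input order.
#'
#' @param sequences FASTA path or list of records / `encoded_seq` (n >= 2).
#' @param scheme An [scoring_scheme()].
#' @param scheduler `"dynamic"` (task pool, the distance-matrix scheme) or
#'   `"static"` (contiguous task ranges proportional to `powers`).
#' @param workers Worker processes.
#' @param batch_size Subjects per task (default 16).
#' @param powers Optional compute-power factors for the static scheduler.
#' @return An `sw_distmat`: `d` (n x n, input order, ids as dimnames),
#'   `nid` (match counts), `ids`, `workload` (total cells `W`),
#'   `per_task_cells`, `ledger` (dynamic scheduler only).
#' @examples
#' fam <- synth_family(4, root_length = 80, sub_rate = 0.1, seed = 3)
#' dm <- compute_distance_matrix(fam, scoring_scheme())
#' round(dm$d, 3)
#' @export
compute_distance_matrix <- function(sequences, scheme = scoring_scheme(),
                                    scheduler = c("dynamic", "static"),
                                    workers = 1L, batch_size = 16L,
                                    powers = NULL) {
  scheduler <- match.arg(scheduler)
  force(scheme)   # forced before closures are shipped to worker processes
  if (is.character(sequences) && length(sequences) == 1L) {
    sequences <- read_fasta(sequences)
  }
  seqs <- encode_records(sequences)
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  ids <- vapply(seqs, function(s) s$id, character(1L))
  tp <- make_tasks(seqs, batch_size)
  sorted <- seqs[tp$order]

  task_fn <- function(task) {
    pivot <- sorted[[task$pivot]]
    batch <- make_lane_batch(sorted[task$subjects], task$subjects)
    res <- lane_sw_nid(pivot, batch, scheme)
    lmin <- pmin(pivot$length, batch$lane_lengths)
    data.frame(i = task$pivot, j = task$subjects, nid = res$nid,
               d = 1 - res$nid / lmin)
  }

  ledger <- NULL
  if (scheduler == "dynamic") {
    run <- dynamic_pool_run(tp$tasks, task_fn, workers)
    partials <- run$results
    ledger <- run$ledger
  } else {
    if (is.null(powers)) powers <- rep(1, workers)
    cells <- vapply(tp$tasks, `[[`, numeric(1L), "cells")
    chunks <- partition_by_size(cells, powers)
    chunk_fn <- function(idx) do.call(rbind, lapply(tp$tasks[idx], task_fn))
    partials <- static_pool_run(chunks, chunk_fn, workers)
  }

  merged <- merge_results(partials, "distmat", expected = n)
  # back to input order
  inv <- order(tp$order)
  d <- merged$d[inv, inv, drop = FALSE]
  nid <- merged$nid[inv, inv, drop = FALSE]
  dimnames(d) <- list(ids, ids)
  dimnames(nid) <- list(ids, ids)
  structure(list(
    d = d, nid = nid, ids = ids,
    workload = workload(vapply(seqs, function(s) s$length, integer(1L)))$W,
    per_task_cells = stats::setNames(
      vapply(tp$tasks, `[[`, numeric(1L), "cells"),
      vapply(tp$tasks, `[[`, character(1L), "id")),
    ledger = ledger,
    params = list(scheduler = scheduler, workers = workers,
                  batch_size = batch_size)
  ), class = "sw_distmat")
}

#' @export
print.sw_distmat <- function(x, ...) {
  n <- length(x$ids)
  off <- x$d[upper.tri(x$d)]
  cat(sprintf("Identity-based distance matrix: %d sequences, W = %.0f cells\n",
              n, x$workload))
  cat(sprintf("  off-diagonal distances: min %.3f, mean %.3f, max %.3f\n",
              min(off), mean(off), max(off)))
  invisible(x)
}

#' @export
as.matrix.sw_distmat <- function(x, ...) x$d

#' @export
as.dist.sw_distmat <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' Write the pairwise table of a distance matrix
#'
#' Long-form TSV with one row per unordered pair: `id_i`, `id_j`, `nid`,
#' `d`.
#'
#' @param x An `sw_distmat`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(x, path) {
  stopifnot(inherits(x, "sw_distmat"))
  n <- length(x$ids)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(id_i = x$ids[idx[, 1L]], id_j = x$ids[idx[, 2L]],
                   nid = x$nid[idx], d = x$d[idx])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
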