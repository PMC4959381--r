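# Load balancing over a local pool of worker processes.  The three-module
# split (dispatcher, single-node worker, result collector) matches the usual
# master/worker layout of cluster aligners, so a network transport could be
# slotted in without touching the alignment engines.  Two schemes are
# provided: static proportional partitioning calibrated by a timed sample
# scan, and a dynamic exactly-once task pool.

# Spin up a PSOCK pool with the package namespace loaded.  Library paths of
# the master are forwarded so workers resolve the same installation.
make_worker_pool <- function(workers) {
  cl <- parallel::makePSOCKcluster(workers)
  setpaths <- function(paths) .libPaths(paths)
  environment(setpaths) <- globalenv()
  parallel::clusterCall(cl, setpaths, .libPaths())
  parallel::clusterEvalQ(cl, loadNamespace("swlanes"))
  cl
}

#' Measure per-worker compute power with a sample test
#'
#' Every worker times the identical sample scan (a lane-parallel score-only
#' pass of the longest sample sequence against the whole sample) and its
#' compute-power factor is cells per second.  Factors are relative: only
#' their ratios are used downstream when sizing static partitions.
#'
#' @param workers Number of worker processes (1 runs in-process).
#' @param sample List of records or `encoded_seq` -- the calibration set.
#' @param scheme An [scoring_scheme()].
#' @param min_cells Minimum DP-cell workload the sample must provide
#'   (default 1e7); smaller samples are rejected as too noisy to time.
#' @param reps Repetitions of the scan per worker (timed together).
#' @param throttle Optional numeric slowdown factor per worker (>= 1), used
#'   by tests to emulate heterogeneous nodes: a worker with factor f sleeps
#'   (f-1) times its scan time, so its measured power is ~1/f of nominal.
#' @return Data frame with columns `worker`, `power` (cells/second).
#' @export
sample_test <- function(workers, sample, scheme, min_cells = 1e7,
                        reps = 1L, throttle = NULL) {
  force(scheme)
  stopifnot(workers >= 1L, length(sample) >= 1L)
  seqs <- encode_records(sample)
  lens <- vapply(seqs, function(s) s$length, integer(1L))
  qidx <- which.max(lens)
  q <- seqs[[qidx]]
  cells <- as.numeric(q$length) * sum(as.numeric(lens)) * reps
  if (cells < min_cells) {
    stop("sample workload (", format(cells, big.mark = ","),
         " cells) is below min_cells = ", format(min_cells, big.mark = ","))
  }
  if (!is.null(throttle)) {
    stopifnot(length(throttle) == workers, all(throttle >= 1))
  }
  batches <- sort_and_batch(seqs)
  job <- function(w) {
    t0 <- proc.time()[["elapsed"]]
    for (r in seq_len(reps)) {
      for (b in batches) lane_sw_scores(q, b, scheme)
    }
    dt <- proc.time()[["elapsed"]] - t0
    if (!is.null(throttle) && throttle[w] > 1) {
      Sys.sleep((throttle[w] - 1) * dt)
    }
    proc.time()[["elapsed"]] - t0
  }
  elapsed <- if (workers == 1L) {
    list(job(1L))
  } else {
    cl <- make_worker_pool(workers)
    on.exit(parallel::stopCluster(cl), add = TRUE)
    parallel::clusterApply(cl, seq_len(workers), function(w) {
      tryCatch(job(w), error = function(e) conditionMessage(e))
    })
  }
  failed <- !vapply(elapsed, is.numeric, logical(1L))
  if (any(failed)) {
    warning("excluding failed worker(s): ",
            paste(which(failed), collapse = ", "))
    if (all(failed)) stop("sample test failed on every worker")
  }
  data.frame(worker = which(!failed),
             power = cells / pmax(unlist(elapsed[!failed]), 1e-9))
}

# Cut items with given sizes into length(powers) contiguous chunks whose
# size totals are proportional to powers, cutting only at item boundaries.
# Each cut lands on the boundary closest to the ideal cumulative target, so
# no chunk deviates from its target by more than the largest single item.
partition_by_size <- function(sizes, powers) {
  n <- length(sizes)
  w <- length(powers)
  stopifnot(w >= 1L, all(powers > 0))
  if (w == 1L) return(list(seq_len(n)))
  cum <- cumsum(as.numeric(sizes))
  total <- cum[n]
  targets <- total * cumsum(powers)[-w] / sum(powers)
  cuts <- integer(w - 1L)
  prev <- 0L
  for (i in seq_len(w - 1L)) {
    k <- findInterval(targets[i], cum)   # last boundary with cum <= target
    # include the crossing item iff that lands nearer the target
    if (k < n) {
      below <- if (k == 0L) 0 else cum[k]
      if (abs(cum[k + 1L] - targets[i]) < abs(below - targets[i])) k <- k + 1L
    }
    cuts[i] <- max(k, prev)
    prev <- cuts[i]
  }
  bounds <- c(0L, cuts, n)
  lapply(seq_len(w), function(i) {
    if (bounds[i] >= bounds[i + 1L]) integer(0L)
    else (bounds[i] + 1L):bounds[i + 1L]
  })
}

#' Static proportional database partition
#'
#' Splits a sequence list into one contiguous chunk per worker, with chunk
#' residue totals proportional to the workers' compute-power factors up to
#' one-sequence granularity.  Sequences are never split: scores are
#' per-sequence, so cutting inside one would change results.
#'
#' @param db List of records or `encoded_seq`.
#' @param profiles Data frame from [sample_test()] or a bare numeric vector
#'   of power factors.
#' @return List of integer index vectors into `db`, one per worker, whose
#'   concatenation is `seq_along(db)` exactly.
#' @export
static_partition <- function(db, profiles) {
  stopifnot(length(db) >= 1L)
  powers <- if (is.data.frame(profiles)) profiles$power else as.numeric(profiles)
  lens <- vapply(db, function(s) {
    if (inherits(s, "encoded_seq")) s$length else nchar(s$residues)
  }, numeric(1L))
  partition_by_size(lens, powers)
}

#' Run tasks through a dynamic exactly-once pool
#'
#' Hands tasks out to idle workers as they finish (mutual exclusion is the
#' pool's contract: no task runs twice, none is skipped) and returns the
#' results in task order together with a completion ledger.  A task whose
#' evaluation fails is re-queued once; a second failure aborts the run.
#'
#' @param tasks List of tasks; each element may carry an `id` field,
#'   otherwise list names or positions are used as ids.
#' @param task_fn Function applied to each task.
#' @param workers Number of worker processes (1 runs in-process).
#' @return List with `results` (in task order) and `ledger` (data frame of
#'   `task_id`, `worker` process id, `attempt`).
#' @export
dynamic_pool_run <- function(tasks, task_fn, workers = 1L) {
  force(task_fn)
  stopifnot(workers >= 1L)
  ids <- task_ids(tasks)
  if (length(tasks) == 0L) {
    return(list(results = list(),
                ledger = data.frame(task_id = character(0L),
                                    worker = integer(0L),
                                    attempt = integer(0L))))
  }
  wrapped <- function(task) {
    r <- tryCatch(list(ok = TRUE, value = task_fn(task)),
                  error = function(e) list(ok = FALSE,
                                           msg = conditionMessage(e)))
    r$pid <- Sys.getpid()
    r
  }
  if (workers == 1L) {
    raw <- lapply(tasks, wrapped)
  } else {
    cl <- make_worker_pool(workers)
    on.exit(parallel::stopCluster(cl), add = TRUE)
    raw <- parallel::clusterApplyLB(cl, tasks, wrapped)
  }
  attempt <- rep(1L, length(tasks))
  failed <- which(!vapply(raw, `[[`, logical(1L), "ok"))
  if (length(failed)) {
    # one re-queue pass for failed tasks, then hard error
    retry <- if (workers == 1L) {
      lapply(tasks[failed], wrapped)
    } else {
      cl2 <- make_worker_pool(min(workers, length(failed)))
      on.exit(parallel::stopCluster(cl2), add = TRUE)
      parallel::clusterApplyLB(cl2, tasks[failed], wrapped)
    }
    still <- !vapply(retry, `[[`, logical(1L), "ok")
    if (any(still)) {
      stop("task(s) failed after re-queue: ",
           paste(ids[failed[still]], collapse = ", "), " -- first error: ",
           retry[[which(still)[1L]]]$msg)
    }
    raw[failed] <- retry
    attempt[failed] <- 2L
  }
  list(results = lapply(raw, `[[`, "value"),
       ledger = data.frame(task_id = ids,
                           worker = vapply(raw, `[[`, integer(1L), "pid"),
                           attempt = attempt))
}

task_ids <- function(tasks) {
  if (length(tasks) == 0L) return(character(0L))
  ids <- vapply(seq_along(tasks), function(i) {
    t <- tasks[[i]]
    if (is.list(t) && !is.null(t$id)) as.character(t$id)
    else if (!is.null(names(tasks)) && nzchar(names(tasks)[i])) names(tasks)[i]
    else as.character(i)
  }, character(1L))
  if (anyDuplicated(ids)) stop("duplicate task ids")
  ids
}

# Run one function per worker over pre-assigned chunks (static scheme).
static_pool_run <- function(chunks, chunk_fn, workers) {
  live <- which(vapply(chunks, length, integer(1L)) > 0L)
  if (workers == 1L || length(live) <= 1L) {
    return(lapply(chunks[live], chunk_fn))
  }
  cl <- make_worker_pool(min(workers, length(live)))
  on.exit(parallel::stopCluster(cl), add = TRUE)
  parallel::clusterApply(cl, chunks[live], chunk_fn)
}

#' Merge partial results from workers
#'
#' Collector step: validates that the partials cover disjoint id sets whose
#' union is complete, then assembles the global result -- a re-ranked hit
#' list for database search, or the mirrored distance matrix for distance
#' computation.  Coverage gaps or overlaps are hard errors naming the
#' offending ids.
#'
#' @param partials List of partial result data frames.
#' @param type `"search"` (columns `subject_id`, `length`, `score`,
#'   `db_order`) or `"distmat"` (columns `i`, `j`, `nid`, `d`).
#' @param expected For `"search"`, the complete vector of database ids; for
#'   `"distmat"`, the number of sequences `n`.
#' @param top_k For `"search"`, hits to keep after re-ranking.
#' @return For `"search"`, a ranked hit data frame; for `"distmat"`, a list
#'   with matrices `d` and `nid` (indices in the order used by the pairs).
#' @export
merge_results <- function(partials, type = c("search", "distmat"),
                          expected, top_k = Inf) {
  type <- match.arg(type)
  all_df <- do.call(rbind, partials)
  if (type == "search") {
    ids <- all_df$subject_id
    check_coverage(ids, expected)
    ord <- order(-all_df$score, all_df$db_order)
    out <- all_df[ord, c("subject_id", "length", "score"), drop = FALSE]
    out <- out[seq_len(min(top_k, nrow(out))), , drop = FALSE]
    rownames(out) <- NULL
    cbind(rank = seq_len(nrow(out)), out)
  } else {
    n <- expected
    keys <- paste(pmin(all_df$i, all_df$j), pmax(all_df$i, all_df$j))
    want <- outer(seq_len(n), seq_len(n), function(i, j) ifelse(i < j,
                  paste(i, j), NA))
    check_coverage(keys, want[!is.na(want)])
    d <- matrix(0, n, n); nid <- matrix(0L, n, n)
    d[cbind(all_df$i, all_df$j)] <- all_df$d
    d[cbind(all_df$j, all_df$i)] <- all_df$d
    nid[cbind(all_df$i, all_df$j)] <- all_df$nid
    nid[cbind(all_df$j, all_df$i)] <- all_df$nid
    diag(nid) <- 0L
    list(d = d, nid = nid)
  }
}

check_coverage <- function(got, want) {
  dup <- unique(got[duplicated(got)])
  if (length(dup)) {
    stop("overlapping partial results for id(s): ",
         paste(head(dup, 5L), collapse = ", "))
  }
  miss <- setdiff(want, got)
  extra <- setdiff(got, want)
  if (length(miss) || length(extra)) {
    stop("partial results do not cover the input exactly; missing: ",
         paste(head(miss, 5L), collapse = ", "), "; unexpected: ",
         paste(head(extra, 5L), collapse = ", "))
  }
  invisible(TRUE)
}
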