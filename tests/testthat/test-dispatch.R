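test_that("static partition is proportional up to one sequence", {
  # equal powers, equal-length sequences: clean 50/50 residue split
  db <- synth_sequences(10, "fixed", length = 10, seed = 51)
  ch <- static_partition(db, c(1, 1))
  expect_identical(unlist(ch, use.names = FALSE), 1:10)
  expect_identical(lengths(ch), c(5L, 5L))

  # 2:1 powers over 90 residues: 60/30 give or take one sequence
  db2 <- synth_sequences(9, "fixed", length = 10, seed = 52)
  ch2 <- static_partition(db2, c(2, 1))
  expect_identical(sort(unlist(ch2)), 1:9)
  expect_identical(lengths(ch2), c(6L, 3L))

  # single worker gets everything
  expect_identical(static_partition(db2, 1), list(1:9))

  # property: deviation from the ideal share bounded by the longest sequence
  set.seed(53)
  for (t in 1:20) {
    n <- sample(5:60, 1L)
    db3 <- synth_sequences(n, "uniform", min = 10, max = 200,
                           seed = 1000L + t)
    powers <- runif(sample(2:5, 1L), 0.5, 4)
    ch3 <- static_partition(db3, powers)
    expect_identical(sort(unlist(ch3)), seq_len(n))
    lens <- vapply(db3, function(r) nchar(r$residues), numeric(1L))
    total <- sum(lens)
    got <- vapply(ch3, function(idx) sum(lens[idx]), numeric(1L))
    ideal <- total * powers / sum(powers)
    expect_true(all(abs(got - ideal) <= max(lens) + 1e-9))
  }
})

test_that("dynamic pool hands every task out exactly once", {
  tasks <- lapply(1:25, function(i) list(id = paste0("t", i), x = i))
  run <- dynamic_pool_run(tasks, function(t) t$x^2, workers = 1L)
  expect_identical(unlist(run$results), (1:25)^2)
  expect_identical(sort(run$ledger$task_id), sort(paste0("t", 1:25)))
  expect_identical(anyDuplicated(run$ledger$task_id), 0L)
  # empty pool
  empty <- dynamic_pool_run(list(), function(t) t, workers = 1L)
  expect_length(empty$results, 0L)
})

test_that("pool results are identical across worker counts", {
  tasks <- lapply(1:30, function(i) list(id = paste0("t", i), x = i))
  fn <- function(t) t$x * 3L
  r1 <- dynamic_pool_run(tasks, fn, workers = 1L)
  r2 <- dynamic_pool_run(tasks, fn, workers = 2L)
  expect_identical(r1$results, r2$results)
  expect_identical(sort(r2$ledger$task_id), sort(r1$ledger$task_id))
  expect_identical(anyDuplicated(r2$ledger$task_id), 0L)
})

test_that("failing tasks are re-queued once and then abort the run", {
  flaky_dir <- withr::local_tempdir()
  tasks <- lapply(1:4, function(i) list(id = paste0("t", i), x = i))
  # t3 fails on its first attempt only (a marker file records the attempt)
  fn <- function(t) {
    if (t$x == 3L) {
      marker <- file.path(flaky_dir, "seen")
      if (!file.exists(marker)) {
        file.create(marker)
        stop("transient failure")
      }
    }
    t$x
  }
  run <- dynamic_pool_run(tasks, fn, workers = 1L)
  expect_identical(unlist(run$results), 1:4)
  expect_identical(run$ledger$attempt, c(1L, 1L, 2L, 1L))
  # permanent failure is a hard error naming the task
  expect_error(
    dynamic_pool_run(tasks, function(t) if (t$x == 2L) stop("boom") else t$x,
                     workers = 1L),
    "t2")
})

test_that("sample test measures relative compute power", {
  sample_set <- synth_sequences(30, "fixed", length = 200, seed = 54)
  # workload below the floor is rejected
  expect_error(sample_test(1L, sample_set, blosum, min_cells = 1e12),
               "below min_cells")
  p1 <- sample_test(1L, sample_set, blosum, min_cells = 1e5)
  expect_identical(nrow(p1), 1L)
  expect_gt(p1$power, 0)
})

test_that("merged partials equal a one-worker run and validate coverage", {
  db <- synth_sequences(20, "uniform", min = 30, max = 60, seed = 55)
  q <- db[[4L]]$residues
  whole <- scan_database(q, db, blosum, top_k = 20L)
  # hand-split partial hit lists re-rank to the same global result
  scores <- whole$scores
  scores$db_order <- seq_len(nrow(scores))
  parts <- list(scores[1:7, ], scores[8:20, ])
  merged <- merge_results(parts, "search",
                          expected = scores$subject_id, top_k = 20L)
  expect_identical(merged, whole$hits)
  # overlap and gap are hard errors
  expect_error(merge_results(list(scores[1:7, ], scores[7:20, ]), "search",
                             expected = scores$subject_id), "overlap")
  expect_error(merge_results(list(scores[1:7, ]), "search",
                             expected = scores$subject_id), "missing")
})
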