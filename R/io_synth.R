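# FASTA and PHYLIP I/O (FASTA via Biostrings) plus a deterministic
# synthetic-protein generator so the whole test suite runs from code alone.

#' Read a multi-FASTA file
#'
#' @param path Readable FASTA file.  Multi-line records are joined, CR/LF
#'   endings tolerated, record order preserved.  The id is the first
#'   whitespace-delimited token of the header; the remainder is kept as the
#'   description.
#' @return List of records: `id`, `description`, `residues`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("no sequences in ", path)
  headers <- names(set)
  seqs <- gsub("\\s", "", as.character(set))
  if (any(!nzchar(seqs))) {
    stop("record with empty sequence in ", path, ": ",
         headers[!nzchar(seqs)][1L])
  }
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("record with empty id in ", path)
  mapply(function(i, d, r) list(id = i, description = d, residues = r),
         ids, desc, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records List of records as returned by [read_fasta()] (or with at
#'   least `id` and `residues`).
#' @param path Output path.
#' @param wrap Line width for sequence wrapping (default 60); `0` writes
#'   each sequence on a single line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  if (length(records) == 0L) stop("no records to write")
  seqs <- vapply(records, function(r) r$residues, character(1L))
  hdr <- vapply(records, function(r) {
    d <- r$description
    if (!is.null(d) && nzchar(d)) paste(r$id, d) else r$id
  }, character(1L))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- hdr
  width <- if (wrap <= 0L) max(nchar(seqs)) else as.integer(wrap)
  Biostrings::writeXStringSet(set, path, width = max(width, 1L))
  invisible(path)
}

# Mangle ids to the classic 10-character PHYLIP name field, deterministic
# and collision-free: long names are truncated and suffixed ~1, ~2, ...
phylip_names <- function(ids) {
  out <- substr(ids, 1L, 10L)
  while (anyDuplicated(out)) {
    dup <- duplicated(out) | duplicated(out, fromLast = TRUE)
    for (nm in unique(out[dup])) {
      at <- which(out == nm)
      for (k in seq_along(at)) {
        suf <- paste0("~", k)
        out[at[k]] <- paste0(substr(nm, 1L, 10L - nchar(suf)), suf)
      }
    }
  }
  out
}

#' Write a square PHYLIP distance matrix
#'
#' @param matrix Square symmetric numeric matrix.
#' @param ids Sequence names (mangled deterministically to the 10-character
#'   PHYLIP field; duplicates get `~k` suffixes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_distmat <- function(matrix, ids, path) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    stop("distance matrix must be square")
  }
  n <- nrow(matrix)
  stopifnot(length(ids) == n)
  nms <- formatC(phylip_names(ids), width = -10L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n)) {
    writeLines(paste0(nms[i], " ",
                      paste(sprintf("%.6f", matrix[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' Inverse of [write_phylip_distmat()]; used for round-tripping into
#' guide-tree tools.
#'
#' @param path PHYLIP distance-matrix file.
#' @return Numeric matrix with ids as dimnames.
#' @export
read_phylip_distmat <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  n <- as.integer(trimws(lines[[1L]]))
  ids <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[[i + 1L]]), "\\s+")[[1L]]
    ids[i] <- parts[[1L]]
    m[i, ] <- as.numeric(parts[-1L])
  }
  dimnames(m) <- list(ids, ids)
  m
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate synthetic protein sequences
#'
#' Draws `n` i.i.d.-residue sequences over the 20 standard amino acids with
#' a configurable length model.  Deterministic for a given spec and seed:
#' only integer-based sampling is used, so output is platform-stable.
#'
#' @param n Number of sequences.
#' @param length_model One of `"fixed"`, `"uniform"`, `"normal"`.
#' @param length Length for `"fixed"`.
#' @param min,max Bounds for `"uniform"`.
#' @param mean,sd Parameters for `"normal"` (rounded, truncated at 1).
#' @param composition Residue sampling weights over the 20 standard amino
#'   acids (default uniform).
#' @param seed Random seed.
#' @param prefix Id prefix (ids are `<prefix><k>`).
#' @return List of records (`id`, `description`, `residues`).
#' @examples
#' db <- synth_sequences(3, length_model = "fixed", length = 12, seed = 1)
#' @export
synth_sequences <- function(n, length_model = c("normal", "fixed", "uniform"),
                            length = 100L, min = 50L, max = 150L,
                            mean = 465, sd = 80, composition = NULL,
                            seed = 1L, prefix = "syn") {
  length_model <- match.arg(length_model)
  stopifnot(n >= 1L)
  aa20 <- AA_ORDER[1:20]
  if (is.null(composition)) composition <- rep(1, 20L)
  stopifnot(length(composition) == 20L, all(composition >= 0))
  with_seed(seed, {
    lens <- switch(length_model,
      fixed   = rep(as.integer(length), n),
      uniform = sample.int(max - min + 1L, n, replace = TRUE) + min - 1L,
      normal  = pmax(1L, as.integer(round(rnorm(n, mean, sd))))
    )
    lapply(seq_len(n), function(k) {
      res <- paste(sample(aa20, lens[k], replace = TRUE, prob = composition),
                   collapse = "")
      list(id = paste0(prefix, k), description = "", residues = res)
    })
  })
}

#' Generate a mutated sequence family
#'
#' Draws a random root sequence (or uses a supplied one) and derives
#' `copies` descendants by i.i.d. per-site point substitution (to a
#' uniformly chosen *different* residue) at rate `sub_rate`, plus indels at
#' rate `indel_rate` per site: an event is a deletion or an insertion with
#' equal probability, with geometric(1/2) length.  Rates of zero give exact
#' copies; substitution rate 1 forces every surviving site to differ.
#'
#' @param copies Number of derived sequences (the root is returned first as
#'   `<prefix>root`).
#' @param root_length Root length when `root` is not supplied.
#' @param root Optional residue string to mutate from.
#' @param sub_rate,indel_rate Per-site event probabilities in \[0, 1\].
#' @param seed Random seed.
#' @param prefix Id prefix.
#' @param include_root Prepend the root record (default TRUE).
#' @return List of records.
#' @export
synth_family <- function(copies, root_length = 200L, root = NULL,
                         sub_rate = 0.1, indel_rate = 0, seed = 1L,
                         prefix = "fam", include_root = TRUE) {
  stopifnot(copies >= 1L, sub_rate >= 0, sub_rate <= 1,
            indel_rate >= 0, indel_rate <= 1)
  aa20 <- AA_ORDER[1:20]
  with_seed(seed, {
    root_chars <- if (is.null(root)) {
      sample(aa20, root_length, replace = TRUE)
    } else {
      strsplit(toupper(gsub("\\s", "", root)), "")[[1L]]
    }
    out <- list()
    if (include_root) {
      out[[1L]] <- list(id = paste0(prefix, "root"), description = "",
                        residues = paste(root_chars, collapse = ""))
    }
    for (c_i in seq_len(copies)) {
      chars <- root_chars
      # point substitutions: forced change to one of the 19 other residues
      hit <- runif(length(chars)) < sub_rate
      if (any(hit)) {
        chars[hit] <- vapply(chars[hit], function(a) {
          sample(setdiff(aa20, a), 1L)
        }, character(1L))
      }
      if (indel_rate > 0) {
        pieces <- character(0L)
        p <- 1L
        while (p <= length(chars)) {
          if (runif(1L) < indel_rate) {
            len <- 1L + stats::rgeom(1L, 0.5)
            if (runif(1L) < 0.5) {                    # deletion of len sites
              p <- p + len
              next
            }
            pieces <- c(pieces,                       # insertion before site
                        paste(sample(aa20, len, replace = TRUE),
                              collapse = ""))
          }
          pieces <- c(pieces, chars[p])
          p <- p + 1L
        }
        if (length(pieces) == 0L) pieces <- sample(aa20, 1L)
        chars <- strsplit(paste(pieces, collapse = ""), "")[[1L]]
      }
      out[[length(out) + 1L]] <- list(id = paste0(prefix, c_i),
                                      description = "",
                                      residues = paste(chars, collapse = ""))
    }
    out
  })
}

# Encode a list of records (or pass through encoded_seq lists).
encode_records <- function(records, unknown = "X") {
  lapply(records, function(r) {
    if (inherits(r, "encoded_seq")) r
    else encode_sequence(r$id, r$residues, unknown = unknown)
  })
}
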