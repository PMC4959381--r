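#' @useDynLib swlanes, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor rnorm runif
#' @importFrom utils head write.table
NULL

# Canonical 24-symbol amino-acid alphabet in NCBI flat-file order:
# the 20 standard residues plus the ambiguity codes B (N/D), Z (Q/E),
# X (any) and the stop/translation symbol '*'.  Codes are 0..23; code 24
# is reserved for the internal lane-padding sentinel and never appears in
# an encoded sequence.
AA_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYVBZX*", "")[[1]]
SENTINEL_CODE <- 24L
SENTINEL_SCORE <- -128L

#' The 24-letter amino-acid alphabet
#'
#' Returns the ordered alphabet used for residue encoding: the 20 standard
#' amino acids followed by `B`, `Z`, `X` and `*`, matching the row order of
#' NCBI substitution-matrix flat files so tables load without remapping.
#'
#' @return Character vector of length 24.
#' @export
aa_alphabet <- function() AA_ORDER

#' Load a substitution matrix
#'
#' Reads an amino-acid substitution table either by built-in name
#' (currently `"BLOSUM62"`, bundled with the package) or from a file in the
#' NCBI flat-file format distributed with BLAST: `#` comment lines, a
#' whitespace-separated header row of residue symbols, and one labelled row
#' per symbol.  Values are keyed by symbol, so files whose rows are ordered
#' differently from the canonical alphabet load correctly.
#'
#' @param source Built-in matrix name or path to a flat file.
#' @return A symmetric 24x24 integer matrix with residue dimnames.
#' @export
load_substitution_matrix <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  path <- source
  if (!file.exists(source)) {
    path <- system.file("extdata", paste0(source, ".txt"), package = "swlanes")
    if (!nzchar(path)) {
      stop("substitution matrix not found: '", source,
           "' is neither a readable file nor a bundled matrix name")
    }
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("malformed matrix file: ", path)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  row_syms <- vapply(rows, `[`, character(1L), 1L)
  vals <- lapply(rows, function(r) {
    v <- suppressWarnings(as.integer(r[-1L]))
    if (anyNA(v) || length(v) != length(header)) {
      stop("malformed matrix row for symbol '", r[[1L]], "' in ", path)
    }
    v
  })
  m <- do.call(rbind, vals)
  dimnames(m) <- list(row_syms, header)
  missing <- setdiff(AA_ORDER, intersect(row_syms, header))
  if (length(missing)) {
    stop("matrix is missing required symbols: ",
         paste(missing, collapse = " "))
  }
  m <- m[AA_ORDER, AA_ORDER, drop = FALSE]
  if (!identical(m, t(m))) stop("substitution matrix is not symmetric: ", path)
  storage.mode(m) <- "integer"
  m
}

#' Create a scoring scheme
#'
#' Bundles a substitution table with affine gap penalties.  A gap of length
#' `g` costs `gap_open + (g - 1) * gap_extend`: the first gapped residue is
#' charged the opening penalty, each further residue the extension penalty.
#' Defaults are BLOSUM62 with open 10 and extend 2, the usual protein-search
#' setting.
#'
#' @param matrix Built-in name, file path, or an already-loaded symmetric
#'   24x24 integer matrix with residue dimnames.
#' @param gap_open Non-negative gap opening penalty (alpha).
#' @param gap_extend Non-negative gap extension penalty (beta), at most
#'   `gap_open`.  `gap_open == gap_extend` gives linear gap costs.
#' @return An object of class `sw_scheme` with elements `sbt` (24x24),
#'   `sbt_ext` (25x25, sentinel-padded, used by the kernels), `alpha`, `beta`.
#' @examples
#' sch <- scoring_scheme()
#' sch$sbt["A", "A"]
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10L,
                           gap_extend = 2L) {
  if (is.character(matrix)) matrix <- load_substitution_matrix(matrix)
  stopifnot(is.matrix(matrix), identical(dim(matrix), c(24L, 24L)))
  storage.mode(matrix) <- "integer"
  if (!identical(matrix, t(matrix))) stop("substitution matrix must be symmetric")
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (is.na(gap_open) || is.na(gap_extend) || gap_open < 0L ||
      gap_extend < 0L || gap_open < gap_extend) {
    stop("need gap_open >= gap_extend >= 0")
  }
  ext <- base::matrix(SENTINEL_SCORE, 25L, 25L)
  ext[1:24, 1:24] <- matrix
  storage.mode(ext) <- "integer"
  structure(list(sbt = matrix, sbt_ext = ext,
                 alpha = gap_open, beta = gap_extend),
            class = "sw_scheme")
}

#' @export
print.sw_scheme <- function(x, ...) {
  cat("Smith-Waterman scoring scheme\n")
  cat("  gap open (alpha):  ", x$alpha, "\n", sep = "")
  cat("  gap extend (beta): ", x$beta, "\n", sep = "")
  cat("  substitution table: 24x24, diag range [",
      min(diag(x$sbt)), ", ", max(diag(x$sbt)), "]\n", sep = "")
  invisible(x)
}

#' A match/mismatch substitution matrix
#'
#' Builds a simple identity-style table (one score on the diagonal, another
#' off it) over the 24-letter alphabet.  Used by the test suite for the
#' classic +3/-1 linear-gap setting; not a recommended search scoring.
#'
#' @param match Diagonal score.
#' @param mismatch Off-diagonal score.
#' @return 24x24 integer matrix.
#' @export
match_mismatch_matrix <- function(match = 3L, mismatch = -1L) {
  m <- base::matrix(as.integer(mismatch), 24L, 24L,
                    dimnames = list(AA_ORDER, AA_ORDER))
  diag(m) <- as.integer(match)
  m
}

#' Encode a protein sequence
#'
#' Maps residue characters to integer codes 0..23 in the canonical alphabet
#' order.  Lowercase input is accepted and upper-cased; whitespace is
#' stripped.  Characters outside the alphabet are mapped to `X` by default,
#' or rejected when `unknown = "strict"`.
#'
#' @param id Sequence identifier.
#' @param residues Character scalar of residues.
#' @param unknown `"X"` (default) or `"strict"`.
#' @return An `encoded_seq`: list with `id`, `codes` (integer vector),
#'   `length`.
#' @examples
#' encode_sequence("q1", "ARN")$codes  # 0 1 2
#' @export
encode_sequence <- function(id, residues, unknown = c("X", "strict")) {
  unknown <- match.arg(unknown)
  stopifnot(is.character(residues), length(residues) == 1L)
  res <- gsub("\\s", "", residues)
  if (!nzchar(res)) stop("empty sequence for id '", id, "'")
  chars <- strsplit(toupper(res), "")[[1L]]
  codes <- match(chars, AA_ORDER) - 1L
  if (anyNA(codes)) {
    if (unknown == "strict") {
      bad <- unique(chars[is.na(codes)])
      stop("unknown residue(s) ", paste(bad, collapse = " "),
           " in sequence '", id, "'")
    }
    codes[is.na(codes)] <- match("X", AA_ORDER) - 1L
  }
  structure(list(id = as.character(id), codes = codes,
                 length = length(codes)),
            class = "encoded_seq")
}

#' Decode an encoded sequence back to residue characters
#'
#' @param x An `encoded_seq` or an integer code vector.
#' @return Character scalar of residues.
#' @export
decode_sequence <- function(x) {
  codes <- if (inherits(x, "encoded_seq")) x$codes else as.integer(x)
  stopifnot(all(codes >= 0L & codes <= 23L))
  paste(AA_ORDER[codes + 1L], collapse = "")
}

#' @export
print.encoded_seq <- function(x, ...) {
  cat("<encoded_seq> ", x$id, " (", x$length, " aa)\n", sep = "")
  invisible(x)
}

#' Build per-column score and match profiles
#'
#' For one packed lane column (the residues occupying the same position of
#' up to 16 subject sequences) this builds the two gather tables the lane
#' kernel reads at every DP step: `sprofile[r, k] = sbt(r, column[k])` and
#' `mprofile[r, k] = 1` iff residue `r` equals `column[k]`.  Sentinel-padded
#' lanes score `-128` against everything and never match, so padded cells
#' decay to zero under the local-alignment clamp.
#'
#' @param column Integer codes of the lane column (0..24), length 1..16.
#' @param scheme An `sw_scheme`.
#' @return List with `sprofile` (24 x L integer) and `mprofile` (24 x L 0/1).
#' @export
build_column_profiles <- function(column, scheme) {
  stopifnot(inherits(scheme, "sw_scheme"))
  column <- as.integer(column)
  if (length(column) < 1L || length(column) > 16L) {
    stop("lane count must be between 1 and 16")
  }
  if (anyNA(column) || any(column < 0L | column > SENTINEL_CODE)) {
    stop("invalid residue code in lane column")
  }
  sprofile <- scheme$sbt_ext[1:24, column + 1L, drop = FALSE]
  mprofile <- outer(0:23, column, function(r, c) as.integer(r == c))
  rownames(sprofile) <- AA_ORDER
  rownames(mprofile) <- AA_ORDER
  list(sprofile = sprofile, mprofile = mprofile)
}
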