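#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif setNames sd
#' @importFrom utils read.delim write.table head
NULL

# Internal helpers shared across modules. All sequences are plain uppercase
# ACGT character scalars; coordinates are 1-based inclusive throughout.

.validate_seq <- function(x, name = deparse(substitute(x)), allow_n = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(sprintf("'%s' must be a single non-empty nucleotide string", name), call. = FALSE)
  x <- normalize_seq(x)
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  if (!grepl(pat, x))
    stop(sprintf("'%s' contains characters outside the %s alphabet",
                 name, if (allow_n) "ACGTN" else "ACGT"), call. = FALSE)
  x
}

#' Normalize a nucleotide string
#'
#' Uppercases and converts RNA (U) to DNA (T). No validation is performed;
#' see [read_fasta()] for the validating reader.
#'
#' @param x character vector of sequences.
#' @return character vector of the same length.
#' @export
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of ACGT(N) strings.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("TCAAA")  # "TTTGA"
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Longest common prefix / suffix lengths of two integer-encoded sequences.
.lcp_len <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  neq <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

.lcs_len <- function(a, b) .lcp_len(rev(a), rev(b))

.s2i <- function(s) utf8ToInt(s)
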