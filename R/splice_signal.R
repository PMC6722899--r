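# Splice-site context: co-directional repeats and GT/AG classification.
#
# A co-directional repeat is a short direct (same-strand) duplication
# present at both sides of a junction; it is what makes the exact
# breakpoint ambiguous. Given a junction (donor = last retained base,
# acceptor = first retained base) the maximal repeat is recovered by
# extending exact matches outward from the junction in both directions.

#' Find the co-directional repeat at a junction
#'
#' Extends matches between the donor context and acceptor context:
#' rightward, the maximal `k` with
#' `reference[donor+1 .. donor+k] == reference[acceptor .. acceptor+k-1]`;
#' leftward, the maximal `j` with
#' `reference[donor-j+1 .. donor] == reference[acceptor-j .. acceptor-1]`.
#' The repeat is `reference[donor-j+1 .. donor+k]` (length `j + k`), whose
#' second copy is `reference[acceptor-j .. acceptor+k-1]`. For any call
#' produced by [call_linear_junction()] or [call_backsplice()] the repeat
#' length equals the call's `ambiguity_len`.
#'
#' @param reference ACGT string.
#' @param donor_pos,acceptor_pos junction coordinates (1-based positions in
#'   `reference`); either junction flavor is accepted.
#' @return list with `repeat_seq`, `length`, `donor_copy_start`,
#'   `acceptor_copy_start` (both `NA` for an empty annotation).
#' @examples
#' find_codirectional_repeat("ATGCCTTGAAAACTTGGGAT", 8, 17)  # "CTTG"
#' @export
find_codirectional_repeat <- function(reference, donor_pos, acceptor_pos) {
  reference <- .validate_seq(reference, "reference")
  n <- nchar(reference)
  donor_pos <- as.integer(donor_pos); acceptor_pos <- as.integer(acceptor_pos)
  if (is.na(donor_pos) || is.na(acceptor_pos) ||
      donor_pos < 1L || donor_pos > n || acceptor_pos < 1L || acceptor_pos > n)
    stop("junction positions out of range [1, ", n, "]", call. = FALSE)
  r <- .s2i(reference)
  k <- 0L
  while (donor_pos + k + 1L <= n && acceptor_pos + k <= n &&
         r[donor_pos + k + 1L] == r[acceptor_pos + k]) k <- k + 1L
  j <- 0L
  while (donor_pos - j >= 1L && acceptor_pos - j - 1L >= 1L &&
         r[donor_pos - j] == r[acceptor_pos - j - 1L]) j <- j + 1L
  len <- j + k
  if (len == 0L)
    return(list(repeat_seq = "", length = 0L,
                donor_copy_start = NA_integer_, acceptor_copy_start = NA_integer_))
  list(repeat_seq = substr(reference, donor_pos - j + 1L, donor_pos + k),
       length = len,
       donor_copy_start = donor_pos - j + 1L,
       acceptor_copy_start = acceptor_pos - j)
}

#' Classify a junction's splice signal as canonical GT/AG or noncanonical
#'
#' Reads the two bases immediately 3' of the donor and immediately 5' of
#' the acceptor on the genomic sequence: for a canonical intron these are
#' the intronic GT ... AG. Junctions whose breakpoints fall inside exons --
#' the dominant case for the APN isoforms studied here -- are by this rule
#' always noncanonical.
#'
#' @param gdna genomic ACGT string.
#' @param donor_pos last retained base 5' of the junction.
#' @param acceptor_pos first retained base 3' of the junction.
#' @return list with `label` (`"canonical_GT_AG"` or `"noncanonical"`),
#'   `donor_dinucleotide`, `acceptor_dinucleotide`.
#' @export
classify_splice_signal <- function(gdna, donor_pos, acceptor_pos) {
  gdna <- .validate_seq(gdna, "gdna")
  n <- nchar(gdna)
  donor_pos <- as.integer(donor_pos); acceptor_pos <- as.integer(acceptor_pos)
  if (is.na(donor_pos) || is.na(acceptor_pos) ||
      donor_pos + 2L > n || acceptor_pos - 2L < 1L)
    stop("splice-signal window out of range", call. = FALSE)
  don <- substr(gdna, donor_pos + 1L, donor_pos + 2L)
  acc <- substr(gdna, acceptor_pos - 2L, acceptor_pos - 1L)
  list(label = if (don == "GT" && acc == "AG") "canonical_GT_AG" else "noncanonical",
       donor_dinucleotide = don, acceptor_dinucleotide = acc)
}

#' Longest common substring of two sequences
#'
#' Ties are broken by the smallest start in `s1`, then the smallest start
#' in `s2`.
#'
#' @param s1,s2 ACGT strings.
#' @return list with `string`, `length`, `start1`, `start2` (starts are
#'   `NA` when the sequences share no character).
#' @examples
#' longest_common_substring("AACTACGATCAAATCACTTG", "ATTTTGAACGAAATCACAGC")$string
#' @export
longest_common_substring <- function(s1, s2) {
  s1 <- .validate_seq(s1, "s1"); s2 <- .validate_seq(s2, "s2")
  a <- .s2i(s1); b <- .s2i(s2)
  n <- length(a); m <- length(b)
  best_len <- 0L; best1 <- NA_integer_; best2 <- NA_integer_
  # scan all diagonals; each diagonal is a vector equality with run-lengths
  for (off in seq.int(-(m - 1L), n - 1L)) {
    i0 <- max(1L, 1L + off); j0 <- i0 - off
    len <- min(n - i0, m - j0) + 1L
    eq <- a[i0:(i0 + len - 1L)] == b[j0:(j0 + len - 1L)]
    runs <- rle(eq)
    pos <- 1L
    for (t in seq_along(runs$lengths)) {
      if (runs$values[t]) {
        L <- runs$lengths[t]
        st1 <- i0 + pos - 1L; st2 <- j0 + pos - 1L
        if (L > best_len ||
            (L == best_len && (st1 < best1 || (st1 == best1 && st2 < best2)))) {
          best_len <- L; best1 <- st1; best2 <- st2
        }
      }
      pos <- pos + runs$lengths[t]
    }
  }
  list(string = if (best_len > 0L) substr(s1, best1, best1 + best_len - 1L) else "",
       length = best_len, start1 = best1, start2 = best2)
}
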