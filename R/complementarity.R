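# Reverse-complement (complementary) sequence search in circRNA flanks.
#
# Base-pairing between sequences flanking the two splice sites of a circle
# can bring donor and acceptor into proximity and promote circularization.
# Complementarity is defined here as exact reverse-complement substring
# matching: a hit is a pair (m1 in seq1, m2 in seq2) with
# m2 == reverse_complement(m1). This deterministic search recovers every
# complementary pair printed for the HaAPN circles; an RNA-folding tool can
# be layered on top but is never required.

#' Extract the window flanking a splice site
#'
#' Returns `w` bases on each side of the junction boundary (2`w` nt). With
#' `boundary = "after"` (donor-style: the junction falls immediately after
#' `splice_pos`, the last retained base) the window is
#' `gdna[splice_pos-w+1 .. splice_pos+w]`; with `boundary = "before"`
#' (acceptor-style: the junction precedes `splice_pos`, the first retained
#' base) it is `gdna[splice_pos-w .. splice_pos+w-1]`. Windows are
#' truncated at the sequence ends and flagged.
#'
#' @param gdna ACGT string.
#' @param splice_pos 1-based splice-site position.
#' @param w half-window width in nt (default 10, i.e. 20-nt windows).
#' @param boundary `"after"` (default) or `"before"`, see above.
#' @return list with `window`, `junction_offset` (bases on the 5' side of
#'   the junction within the window; `w` unless truncated) and `truncated`.
#' @examples
#' extract_flanks("AAAACCCCGGGGTTTT", 8, w = 4)$window  # "CCCCGGGG"
#' @export
extract_flanks <- function(gdna, splice_pos, w = 10L, boundary = c("after", "before")) {
  gdna <- .validate_seq(gdna, "gdna")
  boundary <- match.arg(boundary)
  n <- nchar(gdna)
  splice_pos <- as.integer(splice_pos); w <- as.integer(w)
  if (is.na(w) || w < 1L) stop("'w' must be >= 1", call. = FALSE)
  if (is.na(splice_pos) || splice_pos < 1L || splice_pos > n)
    stop("splice position out of range [1, ", n, "]", call. = FALSE)
  jx <- if (boundary == "after") splice_pos else splice_pos - 1L
  lo <- jx - w + 1L; hi <- jx + w
  lo_c <- max(1L, lo); hi_c <- min(n, hi)
  list(window = substr(gdna, lo_c, hi_c),
       junction_offset = jx - lo_c + 1L,
       truncated = lo < 1L || hi > n)
}

#' Find maximal reverse-complement matches between two sequences
#'
#' Enumerates every maximal pair of substrings `(m1, m2)` with
#' `m2 == reverse_complement(m1)` and length at least `min_len`. Maximality
#' means the pair cannot be extended on either side and remain
#' complementary; sub-hits of a longer hit are not reported.
#'
#' @param seq1,seq2 ACGT strings.
#' @param min_len minimum hit length (default 4 nt, the shortest
#'   complementary pairs observed at APN circRNA splice sites).
#' @return data.frame with columns `match1`, `match2`, `length`, `start1`,
#'   `start2` (1-based starts in `seq1`/`seq2`), sorted by decreasing
#'   length, then `start1`, then `start2`; zero rows when there is no hit.
#' @examples
#' find_rc_matches("AACTACGATCAAATCACTTG", "ATTTTGAACGAAATCACAGC", 4)
#' @export
find_rc_matches <- function(seq1, seq2, min_len = 4L) {
  seq1 <- .validate_seq(seq1, "seq1"); seq2 <- .validate_seq(seq2, "seq2")
  min_len <- as.integer(min_len)
  if (is.na(min_len) || min_len < 1L) stop("'min_len' must be >= 1", call. = FALSE)
  rc2 <- reverse_complement(seq2)
  a <- .s2i(seq1); b <- .s2i(rc2)
  n <- length(a); m <- length(b)
  out <- list()
  # maximal common-substring blocks between seq1 and revcomp(seq2) are
  # exactly the maximal reverse-complement pairs between seq1 and seq2
  for (off in seq.int(-(m - 1L), n - 1L)) {
    i0 <- max(1L, 1L + off); j0 <- i0 - off
    len <- min(n - i0, m - j0) + 1L
    eq <- a[i0:(i0 + len - 1L)] == b[j0:(j0 + len - 1L)]
    runs <- rle(eq)
    pos <- 1L
    for (t in seq_along(runs$lengths)) {
      L <- runs$lengths[t]
      if (runs$values[t] && L >= min_len) {
        st1 <- i0 + pos - 1L
        stb <- j0 + pos - 1L              # start in revcomp(seq2)
        st2 <- m - (stb + L - 1L) + 1L    # start in seq2
        out[[length(out) + 1L]] <-
          data.frame(match1 = substr(seq1, st1, st1 + L - 1L),
                     match2 = substr(seq2, st2, st2 + L - 1L),
                     length = L, start1 = st1, start2 = st2,
                     stringsAsFactors = FALSE)
      }
      pos <- pos + L
    }
  }
  if (!length(out))
    return(data.frame(match1 = character(0), match2 = character(0),
                      length = integer(0), start1 = integer(0), start2 = integer(0)))
  hits <- do.call(rbind, out)
  hits[order(-hits$length, hits$start1, hits$start2), , drop = FALSE]
}

#' Summarize complementarity across the circRNA flank-window table
#'
#' Runs [find_rc_matches()] on each row of the packaged flank-window table
#' (or any table with the same columns) and checks whether the printed
#' complementary pair, where one exists, is recovered: a printed pair
#' counts as recovered when it appears as a hit or lies inside a longer
#' maximal hit.
#'
#' @param flank_table a `flank_window_table` as returned by
#'   `load_fixture_table("T6")`.
#' @param min_len minimum hit length (default 4).
#' @return list with `per_row` (data.frame: `gene`, `isoform`, `n_hits`,
#'   `best_len`, `printed_pair`, `printed_pair_recovered`, `hits` as
#'   `m1|m2|len` joined by `;`) and counts `n_rows_with_hit`,
#'   `n_printed_pairs`, `n_printed_recovered`.
#' @export
summarize_complementarity <- function(flank_table, min_len = 4L) {
  need <- c("gene", "isoform", "seq1", "comp1", "seq2", "comp2")
  if (!all(need %in% names(flank_table)))
    stop("'flank_table' must have columns ", paste(need, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_len(nrow(flank_table)), function(i) {
    row <- flank_table[i, ]
    hits <- find_rc_matches(row$seq1, row$seq2, min_len = min_len)
    printed <- !is.na(row$comp1)
    recovered <- if (!printed) NA else
      nrow(hits) > 0L && any(mapply(function(m1, m2)
        grepl(row$comp1, m1, fixed = TRUE) && grepl(row$comp2, m2, fixed = TRUE),
        hits$match1, hits$match2))
    data.frame(gene = row$gene, isoform = row$isoform,
               n_hits = nrow(hits),
               best_len = if (nrow(hits)) max(hits$length) else 0L,
               printed_pair = if (printed) paste(row$comp1, row$comp2, sep = "|") else NA,
               printed_pair_recovered = recovered,
               hits = paste(sprintf("%s|%s|%d", hits$match1, hits$match2, hits$length),
                            collapse = ";"),
               stringsAsFactors = FALSE)
  })
  per_row <- do.call(rbind, rows)
  list(per_row = per_row,
       n_rows_with_hit = sum(per_row$n_hits > 0L),
       n_printed_pairs = sum(!is.na(per_row$printed_pair)),
       n_printed_recovered = sum(per_row$printed_pair_recovered, na.rm = TRUE))
}
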