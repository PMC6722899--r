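# Packaged transcriptions of the published HaAPN isoform tables.
#
# The six TSVs under inst/extdata transcribe, row for row, the printed
# tables of linear isoforms (deletion regions, premature-stop flags, clone
# counts per strain), the gDNA splice-site positions of linear and circular
# isoforms, and the 20-nt windows flanking each circRNA splice site together
# with the complementary pairs printed for eight of the twenty circles.
# Checksums guard against silent transcription drift: any edit to a fixture
# must be deliberate and re-pinned here.

.fixture_md5 <- c(
  table1.tsv = "a8290dbff6acc1876367e53ffda2fa58",
  table2.tsv = "9564060954871665971ba4918c91f67d",
  table3.tsv = "20b79c1eafd1a1e5cfd611dda47e7940",
  table4.tsv = "69446df79d56a9dbac0c680dd48ca5c9",
  table5.tsv = "470920d514ac411039e136432adfd7c8",
  table6.tsv = "87e0769d7209721cbbc7f37db2aa0840"
)

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "splicesleuth")
  if (!nzchar(p)) stop("fixture '", file, "' not found in installed package", call. = FALSE)
  p
}

#' Load one of the packaged isoform tables
#'
#' `table_id` selects among the six packaged tables:
#' \describe{
#'   \item{T1}{HaAPN1 linear isoforms: deletion region (cDNA bp), premature
#'     stop flag, predicted MW (kDa), clone counts in the SCD, An and LF256
#'     strains (21 rows: wild-type + 20 variants).}
#'   \item{T2}{HaAPN3 linear isoforms from the SCD strain (wild-type + 14
#'     variants).}
#'   \item{T3}{HaAPN4/6/9 linear isoforms from the SCD strain.}
#'   \item{T4}{HaAPN1 splice-site gDNA positions, 20 linear + 14 circular
#'     isoforms, with exon/intron labels.}
#'   \item{T5}{HaAPN3 splice-site gDNA positions, 13 linear + 6 circular
#'     isoforms. The printed table omits linear V6; the omission is
#'     transcribed verbatim and flagged in `attr(x, "notes")`.}
#'   \item{T6}{20-nt (one row 21-nt, as printed) windows flanking each
#'     circRNA splice site. The base marked with asterisks in print is
#'     stripped from `seq2` and recorded as `junction_offset2`; the printed
#'     complementary pairs (8 rows) are in `comp1`/`comp2`.}
#' }
#'
#' @param table_id one of `"T1"` ... `"T6"`.
#' @return a data.frame; T1-T3 carry class `isoform_table`, T4-T5
#'   `splice_site_table`, T6 `flank_window_table`.
#' @examples
#' t1 <- load_fixture_table("T1")
#' sum(t1$clones_scd)  # 160
#' @export
load_fixture_table <- function(table_id) {
  table_id <- match.arg(toupper(table_id), paste0("T", 1:6))
  file <- paste0("table", substring(table_id, 2L), ".tsv")
  path <- .fixture_path(file)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(.fixture_md5[[file]])))
    stop("fixture-integrity error: checksum mismatch for ", file,
         " (got ", md5, ")", call. = FALSE)
  x <- read.delim(path, stringsAsFactors = FALSE, na.strings = "-")
  switch(table_id,
         T1 = .check_isoform_table(x, n_rows = 21L, scd_total = 160L),
         T2 = .check_isoform_table(x, n_rows = 15L, scd_total = 80L),
         T3 = .check_isoform_table(x, n_rows = 11L, scd_total = NA),
         T4 = .check_splice_table(x, n_linear = 20L, n_circ = 14L),
         T5 = .check_splice_table(x, n_linear = 13L, n_circ = 6L,
                                  notes = "printed table omits linear V6"),
         T6 = .check_flank_table(x))
}

.check_isoform_table <- function(x, n_rows, scd_total) {
  need <- c("isoform", "deletion_start", "deletion_end", "premature_stop", "clones_scd")
  if (!all(need %in% names(x)) || nrow(x) != n_rows)
    stop("fixture-integrity error: unexpected isoform-table shape", call. = FALSE)
  wt <- x$isoform == "Wild-type"
  if (any(!is.na(x$deletion_start[wt])) ||
      any(is.na(x$deletion_start[!wt])) ||
      any(x$deletion_start[!wt] > x$deletion_end[!wt]))
    stop("fixture-integrity error: invalid deletion regions", call. = FALSE)
  if (!is.na(scd_total) && sum(x$clones_scd) != scd_total)
    stop("fixture-integrity error: clone counts do not sum to ", scd_total, call. = FALSE)
  class(x) <- c("isoform_table", "data.frame")
  x
}

.check_splice_table <- function(x, n_linear, n_circ, notes = NULL) {
  need <- c("gene", "kind", "isoform", "donor_pos", "donor_exon",
            "acceptor_pos", "acceptor_exon")
  if (!all(need %in% names(x)) ||
      sum(x$kind == "linear") != n_linear || sum(x$kind == "circular") != n_circ)
    stop("fixture-integrity error: unexpected splice-site-table shape", call. = FALSE)
  circ <- x$kind == "circular"
  if (any(x$acceptor_pos[circ] >= x$donor_pos[circ]))
    stop("fixture-integrity error: back-splice rows must have acceptor < donor",
         call. = FALSE)
  lin <- x$kind == "linear"
  if (any(x$acceptor_pos[lin] <= x$donor_pos[lin]))
    stop("fixture-integrity error: linear rows must have donor < acceptor", call. = FALSE)
  if (!is.null(notes)) attr(x, "notes") <- notes
  class(x) <- c("splice_site_table", "data.frame")
  x
}

.check_flank_table <- function(x) {
  need <- c("gene", "isoform", "seq1", "comp1", "seq2", "comp2")
  if (!all(need %in% names(x)) || nrow(x) != 20L)
    stop("fixture-integrity error: unexpected flank-window-table shape", call. = FALSE)
  marked <- regexpr("*", x$seq2, fixed = TRUE)
  if (any(marked < 0L))
    stop("fixture-integrity error: seq2 rows must carry the printed junction mark",
         call. = FALSE)
  x$junction_offset2 <- as.integer(marked)  # position of the marked base once stripped
  x$seq2 <- gsub("*", "", x$seq2, fixed = TRUE)
  if (!all(grepl("^[ACGT]+$", x$seq1)) || !all(grepl("^[ACGT]+$", x$seq2)))
    stop("fixture-integrity error: windows must be ACGT after normalization", call. = FALSE)
  if (!all(nchar(x$seq1) %in% 20:21) || !all(nchar(x$seq2) %in% 20:21))
    stop("fixture-integrity error: windows must be 20 or 21 nt as printed", call. = FALSE)
  class(x) <- c("flank_window_table", "data.frame")
  x
}
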