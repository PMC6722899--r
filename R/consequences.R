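# Frame and protein consequences of deletion isoforms.

# Average residue masses (Da) of the 20 standard amino acids, i.e. the
# monomer masses after loss of one water; protein MW = sum + one water
# (18.0153 Da). Values are the conventional average (not monoisotopic)
# residue masses used for SDS/PAGE-scale MW prediction.
.residue_mass <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_da <- 18.0153

#' Remove an inclusive region from a cDNA
#'
#' @param ref_cdna ACGT string (wild-type cDNA).
#' @param deletion_start,deletion_end first and last deleted base, 1-based
#'   inclusive cDNA coordinates.
#' @return the variant cDNA.
#' @examples
#' reconstruct_variant("ATGAAACCC", 4, 6)  # "ATGCCC"
#' @export
reconstruct_variant <- function(ref_cdna, deletion_start, deletion_end) {
  ref_cdna <- .validate_seq(ref_cdna, "ref_cdna")
  deletion_start <- as.integer(deletion_start); deletion_end <- as.integer(deletion_end)
  n <- nchar(ref_cdna)
  if (is.na(deletion_start) || is.na(deletion_end) ||
      deletion_start < 1L || deletion_end > n || deletion_start > deletion_end)
    stop("deletion region out of range: need 1 <= start <= end <= ", n, call. = FALSE)
  paste0(substr(ref_cdna, 1L, deletion_start - 1L),
         substr(ref_cdna, deletion_end + 1L, n))
}

#' Classify a deletion as in-frame or frameshifting
#'
#' @param deletion_start,deletion_end inclusive cDNA region.
#' @return `"in_frame"` when the deleted length is a multiple of 3,
#'   `"frameshift"` otherwise.
#' @examples
#' classify_frame(1633, 2403)  # in_frame (771 bp)
#' classify_frame(1637, 2295)  # frameshift (659 bp)
#' @export
classify_frame <- function(deletion_start, deletion_end) {
  deletion_start <- as.integer(deletion_start); deletion_end <- as.integer(deletion_end)
  if (any(is.na(deletion_start)) || any(is.na(deletion_end)) ||
      any(deletion_start > deletion_end) || any(deletion_start < 1L))
    stop("invalid deletion region", call. = FALSE)
  len <- deletion_end - deletion_start + 1L
  ifelse(len %% 3L == 0L, "in_frame", "frameshift")
}

#' Translate an ORF and flag premature termination
#'
#' Translates from the ATG at `start_codon_pos` up to the first in-frame
#' stop codon. The stop is premature when it falls strictly before the
#' codon index homologous to the wild-type stop (`reference_stop_codon`,
#' expressed in the analyzed sequence's own codon numbering, 1 = the start
#' codon; for an in-frame deletion of d codons the caller passes the
#' wild-type stop index minus d). When `reference_stop_codon` is `NULL`
#' the heuristic is used: any stop before the final 10 codons that the
#' sequence could encode is flagged premature.
#'
#' @param cdna ACGT string.
#' @param start_codon_pos 1-based position of the ATG (default 1).
#' @param reference_stop_codon homologous wild-type stop codon index, or
#'   `NULL` for the heuristic.
#' @return list with `peptide`, `stop_codon` (codon index of the stop, `NA`
#'   if none), `premature_stop`, `runs_off` (`TRUE` when no in-frame stop
#'   exists before the sequence end).
#' @examples
#' scan_orf("ATGAAATGA", reference_stop_codon = 3)  # "MK", not premature
#' @export
scan_orf <- function(cdna, start_codon_pos = 1L, reference_stop_codon = NULL) {
  cdna <- .validate_seq(cdna, "cdna")
  start_codon_pos <- as.integer(start_codon_pos)
  if (is.na(start_codon_pos) || start_codon_pos < 1L ||
      start_codon_pos + 2L > nchar(cdna))
    stop("start codon position out of range", call. = FALSE)
  if (substr(cdna, start_codon_pos, start_codon_pos + 2L) != "ATG")
    stop("no ATG at position ", start_codon_pos, call. = FALSE)
  orf <- substr(cdna, start_codon_pos, nchar(cdna))
  n_codons <- nchar(orf) %/% 3L
  codons <- substring(orf, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_idx <- which(aa == "*")[1L]
  runs_off <- is.na(stop_idx)
  peptide <- paste(aa[seq_len(if (runs_off) n_codons else stop_idx - 1L)], collapse = "")
  premature <- if (runs_off) FALSE
  else if (!is.null(reference_stop_codon)) stop_idx < as.integer(reference_stop_codon)
  else stop_idx < n_codons - 10L
  list(peptide = peptide, stop_codon = if (runs_off) NA_integer_ else stop_idx,
       premature_stop = premature, runs_off = runs_off)
}

#' Predict protein molecular weight from a peptide sequence
#'
#' Sum of average residue masses plus one water (18.0153 Da), in kDa.
#'
#' @param peptide string of one-letter codes for the 20 standard residues.
#' @return molecular weight in kDa.
#' @examples
#' predict_mw("G")   # 0.0751 kDa
#' predict_mw("GG")  # 0.1321 kDa
#' @export
predict_mw <- function(peptide) {
  if (!is.character(peptide) || length(peptide) != 1L || is.na(peptide) || !nzchar(peptide))
    stop("'peptide' must be a non-empty string", call. = FALSE)
  res <- strsplit(toupper(peptide), "", fixed = TRUE)[[1L]]
  bad <- setdiff(res, names(.residue_mass))
  if (length(bad))
    stop("nonstandard residue(s): ", paste(unique(bad), collapse = ", "), call. = FALSE)
  unname(sum(.residue_mass[res]) + .water_da) / 1000
}

#' Audit printed premature-stop flags against deletion frame
#'
#' For every variant row of an isoform table, a frameshifting deletion
#' (length not a multiple of 3) must carry a printed premature-stop flag of
#' "Yes"; that holds for every frameshift row of the packaged tables. The
#' converse (in-frame implies "No") is a soft expectation: in-frame rows
#' flagged "Yes" -- a junction-generated stop codon or a table error -- are
#' reported as exceptions, not failures.
#'
#' @param records an `isoform_table` (see [load_fixture_table()]), or any
#'   data.frame with `isoform`, `deletion_start`, `deletion_end`,
#'   `premature_stop`.
#' @return data.frame with one row per variant: `isoform` (prefixed by
#'   `gene` when present), `deletion_len`, `frame`, `printed_flag`,
#'   `consistent` (frameshift rows only: printed flag is "Yes"),
#'   `exception` (in-frame rows printed "Yes").
#' @export
audit_frame_consistency <- function(records) {
  need <- c("isoform", "deletion_start", "deletion_end", "premature_stop")
  if (!all(need %in% names(records)))
    stop("'records' must have columns ", paste(need, collapse = ", "), call. = FALSE)
  x <- records[!is.na(records$deletion_start), , drop = FALSE]
  id <- if ("gene" %in% names(x)) paste(x$gene, x$isoform) else x$isoform
  frame <- classify_frame(x$deletion_start, x$deletion_end)
  data.frame(isoform = id,
             deletion_len = x$deletion_end - x$deletion_start + 1L,
             frame = frame,
             printed_flag = x$premature_stop,
             consistent = ifelse(frame == "frameshift", x$premature_stop == "Yes", NA),
             exception = frame == "in_frame" & x$premature_stop == "Yes",
             stringsAsFactors = FALSE)
}
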