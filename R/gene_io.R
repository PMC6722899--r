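# Sequence and gene-model I/O.
#
# A gene model couples one genomic (coding-strand) sequence with an ordered
# set of exon intervals; every junction call in the package is expressed in
# this coordinate frame (1-based, inclusive). Genes annotated on the reverse
# strand are expected to be supplied already flipped to coding-strand
# orientation.

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased, RNA is converted to DNA (U to T), and any
#' character outside ACGTN is rejected. Empty records are an error.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names are the FASTA ids,
#'   truncated at the first whitespace).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgu"), fa)
#' read_fasta(fa)  # c(x = "ACGT")
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records", call. = FALSE)
  seqs <- normalize_seq(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop("FASTA file '", path, "' has an empty header", call. = FALSE)
  bad <- which(!grepl("^[ACGTN]+$", seqs) | !nzchar(seqs))
  if (length(bad))
    stop(sprintf("record '%s' in '%s' is empty or contains non-ACGTN characters",
                 ids[bad[1L]], path), call. = FALSE)
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of ACGTN sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("'seqs' must be a named character vector", call. = FALSE)
  set <- Biostrings::DNAStringSet(normalize_seq(seqs))
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Construct and validate a gene model
#'
#' @param gene_id gene identifier.
#' @param sequence genomic (coding-strand) nucleotide sequence.
#' @param exons two-column matrix or data.frame of exon `start`/`end`
#'   positions, 1-based inclusive, sorted and non-overlapping.
#' @return an object of class `gene_model` with elements `gene_id`,
#'   `sequence`, `exons` (data.frame with `start`, `end`), `cdna` (spliced
#'   exon concatenation) and `cdna_length`.
#' @export
gene_model <- function(gene_id, sequence, exons) {
  sequence <- .validate_seq(sequence, "sequence", allow_n = TRUE)
  exons <- as.data.frame(exons)
  if (ncol(exons) < 2L) stop("'exons' needs start and end columns", call. = FALSE)
  names(exons)[1:2] <- c("start", "end")
  exons <- exons[, c("start", "end")]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  n <- nchar(sequence)
  if (nrow(exons) == 0L) stop("gene model must have at least one exon", call. = FALSE)
  if (any(is.na(exons)) || any(exons$start > exons$end))
    stop("exon intervals must satisfy start <= end", call. = FALSE)
  if (any(exons$start < 1L) || any(exons$end > n))
    stop("exon intervals out of sequence range [1, ", n, "]", call. = FALSE)
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("exons must be sorted and non-overlapping", call. = FALSE)
  cdna <- paste(substring(sequence, exons$start, exons$end), collapse = "")
  structure(list(gene_id = as.character(gene_id), sequence = sequence,
                 exons = exons, cdna = cdna, cdna_length = nchar(cdna)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d bp gDNA, %d exons, %d bp cDNA\n",
              x$gene_id, nchar(x$sequence), nrow(x$exons), x$cdna_length))
  invisible(x)
}

#' Read a gene model from a FASTA file plus an exon table
#'
#' The exon table is a 3-column TSV (`gene_id`, `exon_start`, `exon_end`)
#' with a header line; intervals are 1-based inclusive.
#'
#' @param fasta_path FASTA file containing exactly one sequence (or one whose
#'   id matches the exon table's `gene_id`).
#' @param exon_table_path TSV of exon intervals.
#' @return a [gene_model()].
#' @export
read_gene_model <- function(fasta_path, exon_table_path) {
  seqs <- read_fasta(fasta_path)
  tab <- read.delim(exon_table_path, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L)
    stop("exon table must have columns gene_id, exon_start, exon_end", call. = FALSE)
  names(tab)[1:3] <- c("gene_id", "exon_start", "exon_end")
  gid <- unique(tab$gene_id)
  if (length(gid) != 1L)
    stop("exon table describes more than one gene; expected exactly one", call. = FALSE)
  seq <- if (gid %in% names(seqs)) seqs[[gid]] else if (length(seqs) == 1L) seqs[[1L]]
         else stop("gene '", gid, "' not found in ", fasta_path, call. = FALSE)
  gene_model(gid, seq, tab[, c("exon_start", "exon_end")])
}
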