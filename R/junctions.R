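# Junction calling by exact split decomposition.
#
# A deletion (exon-skipping) variant equals a prefix plus a suffix of its
# reference; a circRNA head-to-tail junction read equals a reference suffix
# block followed by an upstream block. When a short co-directional repeat
# flanks the breakpoint the split is not unique: all placements that
# reproduce the query are equivalent and form a contiguous family obtained
# by sliding the junction across the repeat. Calls are normalized to the
# placement with the maximal donor position, so the retained repeat copy is
# the 5'-most one and `repeat_seq` is the reference substring ending at the
# canonical donor. `ambiguity_len` is the width of the family, which equals
# the repeat length (see find_codirectional_repeat()).

.junction_call <- function(kind, donor = NA_integer_, acceptor = NA_integer_,
                           space = "cDNA", deletion_len = NA_integer_,
                           ambiguity_len = 0L, repeat_seq = "") {
  structure(list(kind = kind, donor_pos = as.integer(donor),
                 acceptor_pos = as.integer(acceptor), coordinate_space = space,
                 deletion_len = as.integer(deletion_len),
                 ambiguity_len = as.integer(ambiguity_len),
                 repeat_seq = repeat_seq, canonical = "max-donor"),
            class = "junction_call")
}

#' @export
print.junction_call <- function(x, ...) {
  if (x$kind == "none") {
    cat("<junction_call> none (query matches reference contiguously)\n")
  } else {
    cat(sprintf("<junction_call> %s: donor %d, acceptor %d (%s)%s, ambiguity %d bp%s\n",
                x$kind, x$donor_pos, x$acceptor_pos, x$coordinate_space,
                if (!is.na(x$deletion_len)) sprintf(", deletion %d bp", x$deletion_len) else "",
                x$ambiguity_len,
                if (nzchar(x$repeat_seq)) sprintf(" [repeat %s]", x$repeat_seq) else ""))
  }
  invisible(x)
}

#' Call a single-deletion junction between a reference and a variant
#'
#' Finds the unique contiguous deletion (up to repeat-induced ambiguity)
#' that turns `reference` into `variant`. The variant is accepted iff its
#' longest common prefix `p` and suffix `s` with the reference satisfy
#' `p + s >= nchar(variant)`; the excess `p + s - nchar(variant)` is the
#' breakpoint ambiguity and equals the length of the co-directional repeat
#' at the junction. The canonical call takes the maximal donor
#' (`donor = p`), i.e. the deletion is pushed 3' and the retained repeat
#' copy is the 5' one; `acceptor` is the first retained base 3' of the
#' deletion.
#'
#' @param reference,variant ACGT strings; `variant` no longer than
#'   `reference`. Coordinates in the returned call are positions in
#'   `reference` (cDNA space when a cDNA is supplied).
#' @param min_anchor minimum exact match length required on each side of
#'   the junction at the canonical placement (default 8, exceeding the
#'   longest commonly observed 4-8 bp junction repeats).
#' @return a `junction_call`; `kind` is `"none"` when the sequences are
#'   identical, otherwise `"linear_deletion"`.
#' @examples
#' call_linear_junction("ATGCCTTGAAAACTTGGGAT", "ATGCCTTGGGAT", min_anchor = 4)
#' @export
call_linear_junction <- function(reference, variant, min_anchor = 8L) {
  reference <- .validate_seq(reference, "reference")
  variant <- .validate_seq(variant, "variant")
  min_anchor <- as.integer(min_anchor)
  if (is.na(min_anchor) || min_anchor < 1L) stop("'min_anchor' must be >= 1", call. = FALSE)
  nR <- nchar(reference); nV <- nchar(variant)
  if (nV > nR) stop("not a deletion: variant is longer than the reference", call. = FALSE)
  if (identical(reference, variant)) return(.junction_call("none"))
  r <- .s2i(reference); v <- .s2i(variant)
  p <- .lcp_len(r, v)
  s <- .lcs_len(r, v)
  if (p + s < nV)
    stop("not explainable by a single contiguous deletion", call. = FALSE)
  ambiguity <- p + s - nV
  deletion_len <- nR - nV
  donor <- p                      # maximal-donor canonical placement
  acceptor <- donor + deletion_len + 1L
  anchor5 <- donor; anchor3 <- nV - donor
  if (anchor5 < min_anchor || anchor3 < min_anchor)
    stop(sprintf("anchor too short: %d/%d bp flank the junction (min_anchor = %d)",
                 anchor5, anchor3, min_anchor), call. = FALSE)
  repeat_seq <- if (ambiguity > 0L) substr(reference, donor - ambiguity + 1L, donor) else ""
  .junction_call("linear_deletion", donor, acceptor, "cDNA",
                 deletion_len, ambiguity, repeat_seq)
}

#' Call a circRNA back-splice junction from a junction-spanning read
#'
#' Decomposes `junction_read` as `R1 + R2` where `R1` matches the reference
#' exactly, ending at the donor (the 3' end of the circle), and `R2`
#' matches exactly, starting at the acceptor (the 5' end of the circle),
#' with `acceptor <= donor` (head-to-tail). Split placements that differ
#' only by sliding the junction across a co-directional repeat are
#' collapsed to the maximal-donor canonical form; genuinely distinct
#' decompositions at different loci are an error, not silently resolved.
#'
#' @param reference ACGT reference (gDNA or cDNA).
#' @param junction_read ACGT read spanning the back-splice; must be shorter
#'   than the reference.
#' @param min_anchor minimum exact match on each side of the junction.
#' @return a `junction_call` with `kind = "backsplice"` (`donor_pos` >
#'   `acceptor_pos`), or `kind = "none"` if the read matches the reference
#'   contiguously.
#' @examples
#' call_backsplice("AAACCCGGGTTTACGTACGA", "TTACGCCCGG", min_anchor = 4)
#' @export
call_backsplice <- function(reference, junction_read, min_anchor = 8L) {
  reference <- .validate_seq(reference, "reference")
  junction_read <- .validate_seq(junction_read, "junction_read")
  min_anchor <- as.integer(min_anchor)
  if (is.na(min_anchor) || min_anchor < 1L) stop("'min_anchor' must be >= 1", call. = FALSE)
  nR <- nchar(reference); nQ <- nchar(junction_read)
  if (nQ >= nR) stop("junction read must be shorter than the reference", call. = FALSE)
  if (grepl(junction_read, reference, fixed = TRUE))
    return(.junction_call("none"))
  canon <- .backsplice_decompositions(reference, junction_read, min_anchor)
  if (nrow(canon) == 0L) stop("no backsplice decomposition", call. = FALSE)
  if (nrow(canon) > 1L) {
    stop("ambiguous backsplice: multiple non-equivalent decompositions at (donor, acceptor) = ",
         paste(sprintf("(%d, %d)", canon[, 1L], canon[, 2L]), collapse = ", "),
         call. = FALSE)
  }
  d <- canon[1L, 1L]; a <- canon[1L, 2L]
  rep_ann <- find_codirectional_repeat(reference, d, a)
  .junction_call("backsplice", d, a, "gDNA", NA_integer_,
                 rep_ann$length, rep_ann$repeat_seq)
}

# Enumerate head-to-tail decompositions of `read` against `reference`:
# every split read = R1 + R2 with R1 matching exactly ending at a donor, R2
# matching exactly starting at an acceptor <= donor, and both arms >=
# min_anchor. Candidates that differ only by sliding the junction across a
# repeat are collapsed to the maximal-donor form; rows of the returned
# matrix (columns donor, acceptor) are the distinct junctions.
.backsplice_decompositions <- function(reference, read, min_anchor) {
  nR <- nchar(reference); nQ <- nchar(read)
  r <- .s2i(reference)
  cands <- list()
  if (nQ >= 2L * min_anchor) {
    for (i in seq.int(min_anchor, nQ - min_anchor)) {
      r1 <- substr(read, 1L, i)
      r2 <- substr(read, i + 1L, nQ)
      ends <- .find_all(reference, r1) + i - 1L      # donor candidates
      starts <- .find_all(reference, r2)             # acceptor candidates
      if (!length(ends) || !length(starts)) next
      for (d in ends) for (a in starts) {
        if (a <= d) cands[[length(cands) + 1L]] <- c(d, a)
      }
    }
  }
  if (!length(cands))
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("donor", "acceptor"))))
  canon <- unique(t(vapply(cands, function(da) {
    d <- da[1L]; a <- da[2L]
    while (d < nR && r[d + 1L] == r[a]) { d <- d + 1L; a <- a + 1L }
    c(d, a)
  }, integer(2L))))
  colnames(canon) <- c("donor", "acceptor")
  canon
}

# all start positions of fixed pattern `pat` in `x`
.find_all <- function(x, pat) {
  out <- integer(0); from <- 1L
  repeat {
    hit <- regexpr(pat, substr(x, from, nchar(x)), fixed = TRUE)
    if (hit < 0L) break
    pos <- from + as.integer(hit) - 1L
    out <- c(out, pos)
    from <- pos + 1L
  }
  out
}

#' Map a cDNA position to its genomic coordinate
#'
#' @param pos 1-based cDNA position(s).
#' @param model a [gene_model()].
#' @return integer gDNA position(s) of the `pos`-th exonic base.
#' @export
map_cdna_to_gdna <- function(pos, model) {
  stopifnot(inherits(model, "gene_model"))
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > model$cdna_length))
    stop("cDNA position out of range [1, ", model$cdna_length, "]", call. = FALSE)
  lens <- model$exons$end - model$exons$start + 1L
  ends <- cumsum(lens)
  idx <- findInterval(pos - 1L, ends) + 1L
  model$exons$start[idx] + (pos - c(0L, ends)[idx] - 1L)
}

#' Map a genomic position to its cDNA coordinate
#'
#' Inverse of [map_cdna_to_gdna()]; the position must be exonic.
#'
#' @param pos 1-based gDNA position(s) inside an exon.
#' @param model a [gene_model()].
#' @return integer cDNA position(s).
#' @export
map_gdna_to_cdna <- function(pos, model) {
  stopifnot(inherits(model, "gene_model"))
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > nchar(model$sequence)))
    stop("gDNA position out of range", call. = FALSE)
  lens <- model$exons$end - model$exons$start + 1L
  offs <- cumsum(c(0L, lens))[seq_along(lens)]
  idx <- findInterval(pos, model$exons$start)
  if (any(idx < 1L) || any(pos > model$exons$end[pmax(idx, 1L)]))
    stop("gDNA position is not exonic", call. = FALSE)
  offs[idx] + (pos - model$exons$start[idx] + 1L)
}

#' Label a genomic position by exon or intron
#'
#' @param pos 1-based gDNA position(s).
#' @param model a [gene_model()].
#' @return `"exonK"` when `pos` lies inside exon K (boundaries inclusive),
#'   `"intronK"` when it lies after exon K and before exon K+1, and
#'   `"intron0"` for positions 5' of the first exon.
#' @export
assign_exon <- function(pos, model) {
  stopifnot(inherits(model, "gene_model"))
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L) || any(pos > nchar(model$sequence)))
    stop("gDNA position out of range [1, ", nchar(model$sequence), "]", call. = FALSE)
  idx <- findInterval(pos, model$exons$start)
  inside <- idx >= 1L & pos <= model$exons$end[pmax(idx, 1L)]
  ifelse(inside, paste0("exon", idx), paste0("intron", idx))
}
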