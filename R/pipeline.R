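# Pipeline orchestration and summary reporting.

#' Percentage of variant clones in an isoform table
#'
#' @param records an isoform table with clone-count columns (see
#'   [load_fixture_table()]).
#' @param strain strain name matching a `clones_<strain>` column (e.g.
#'   `"scd"`, `"an"`, `"lf256"`).
#' @return percentage (0-100) of clones that are variants (non-wild-type).
#' @examples
#' summarize_clone_fractions(load_fixture_table("T1"), "scd")  # 30.625
#' @export
summarize_clone_fractions <- function(records, strain) {
  col <- paste0("clones_", tolower(strain))
  if (!col %in% names(records))
    stop("no clone-count column for strain '", strain, "'", call. = FALSE)
  counts <- records[[col]]
  total <- sum(counts)
  if (total == 0) stop("zero clones in strain '", strain, "'", call. = FALSE)
  wt <- records$isoform == "Wild-type"
  100 * sum(counts[!wt]) / total
}

#' Call and annotate junctions for a batch of query sequences
#'
#' Thin wrapper running [call_linear_junction()] or [call_backsplice()]
#' over a set of queries against one gene, annotating each accepted call
#' with its co-directional repeat and exon labels.
#'
#' @param model a [gene_model()]; linear variants are called against its
#'   cDNA, junction reads against its gDNA.
#' @param queries named character vector of query sequences.
#' @param kind `"linear"` or `"backsplice"`.
#' @param min_anchor minimum junction anchor (default 8).
#' @return data.frame with columns `query_id`, `kind`, `donor_pos`,
#'   `acceptor_pos`, `deletion_len`, `ambiguity_len`, `repeat_seq`,
#'   `exon_donor`, `exon_acceptor`, `error` (NA unless the query was
#'   rejected, in which case the message is recorded and the call columns
#'   are NA).
#' @export
call_junctions <- function(model, queries, kind = c("linear", "backsplice"),
                           min_anchor = 8L) {
  stopifnot(inherits(model, "gene_model"))
  kind <- match.arg(kind)
  if (is.null(names(queries)) || any(!nzchar(names(queries))))
    stop("'queries' must be named", call. = FALSE)
  rows <- lapply(names(queries), function(id) {
    res <- tryCatch(
      if (kind == "linear") call_linear_junction(model$cdna, queries[[id]], min_anchor)
      else call_backsplice(model$sequence, queries[[id]], min_anchor),
      error = function(e) conditionMessage(e))
    if (is.character(res))
      return(data.frame(query_id = id, kind = NA, donor_pos = NA, acceptor_pos = NA,
                        deletion_len = NA, ambiguity_len = NA, repeat_seq = NA,
                        exon_donor = NA, exon_acceptor = NA, error = res,
                        stringsAsFactors = FALSE))
    gd <- if (res$kind == "none") c(NA_integer_, NA_integer_)
    else if (identical(res$coordinate_space, "cDNA"))
      c(map_cdna_to_gdna(res$donor_pos, model), map_cdna_to_gdna(res$acceptor_pos, model))
    else c(res$donor_pos, res$acceptor_pos)
    data.frame(query_id = id, kind = res$kind,
               donor_pos = res$donor_pos, acceptor_pos = res$acceptor_pos,
               deletion_len = res$deletion_len, ambiguity_len = res$ambiguity_len,
               repeat_seq = res$repeat_seq,
               exon_donor = if (is.na(gd[1L])) NA else assign_exon(gd[1L], model),
               exon_acceptor = if (is.na(gd[2L])) NA else assign_exon(gd[2L], model),
               error = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full fixture-driven analysis and build a summary report
#'
#' In fixtures mode (the default) the report reproduces the published
#' summary numbers from the packaged tables: isoform counts per gene,
#' variant clone fractions per strain, the frame-consistency audit, the
#' flank-complementarity summary, and the linear-circular splice-site
#' proximity statistics with a permutation test per gene. Alternatively,
#' supply a gene model plus query sequences to analyze user data.
#'
#' @param fixtures if `TRUE`, analyze the packaged tables.
#' @param model,variants,circ_reads user-data mode: a [gene_model()],
#'   named linear variant cDNAs and named back-splice junction reads.
#' @param min_len minimum complementarity hit length (default 4).
#' @param min_anchor junction anchor for user-data calls (default 8).
#' @param n_perm,seed permutation-test settings.
#' @return list of class `pipeline_report`; in fixtures mode the elements
#'   are `counts`, `clone_fractions`, `frame_audit`, `complementarity`,
#'   `association`; in user-data mode `linear_calls` and `circ_calls`.
#' @export
run_pipeline <- function(fixtures = TRUE, model = NULL, variants = NULL,
                         circ_reads = NULL, min_len = 4L, min_anchor = 8L,
                         n_perm = 999L, seed = 1L) {
  if (!fixtures) {
    if (is.null(model)) stop("configuration error: 'model' is required", call. = FALSE)
    rep <- list(
      linear_calls = if (length(variants))
        call_junctions(model, variants, "linear", min_anchor) else NULL,
      circ_calls = if (length(circ_reads))
        call_junctions(model, circ_reads, "backsplice", min_anchor) else NULL)
    rep$counts <- list(
      n_linear = if (is.null(rep$linear_calls)) 0L
                 else sum(rep$linear_calls$kind %in% "linear_deletion"),
      n_circ = if (is.null(rep$circ_calls)) 0L
               else sum(rep$circ_calls$kind %in% "backsplice"))
    class(rep) <- "pipeline_report"
    return(rep)
  }
  t1 <- load_fixture_table("T1"); t2 <- load_fixture_table("T2")
  t3 <- load_fixture_table("T3"); t4 <- load_fixture_table("T4")
  t5 <- load_fixture_table("T5"); t6 <- load_fixture_table("T6")
  counts <- list(
    n_linear_hapn1 = sum(t1$isoform != "Wild-type"),
    n_linear_hapn3 = sum(t2$isoform != "Wild-type"),
    n_circ_hapn1 = sum(t4$kind == "circular"),
    n_circ_hapn3 = sum(t5$kind == "circular"))
  clone_fractions <- c(
    scd_hapn1 = summarize_clone_fractions(t1, "scd"),
    an_hapn1 = summarize_clone_fractions(t1, "an"),
    lf256_hapn1 = summarize_clone_fractions(t1, "lf256"),
    scd_hapn3 = summarize_clone_fractions(t2, "scd"))
  audit <- rbind(audit_frame_consistency(t1), audit_frame_consistency(t2),
                 audit_frame_consistency(t3))
  comp <- summarize_complementarity(t6, min_len = min_len)
  association <- lapply(list(HaAPN1 = t4, HaAPN3 = t5), function(tab) {
    lin <- tab[tab$kind == "linear", ]; circ <- tab[tab$kind == "circular", ]
    list(
      acceptors_vs_donors = site_proximity_stat(circ$acceptor_pos, lin$donor_pos),
      donors_vs_acceptors = site_proximity_stat(circ$donor_pos, lin$acceptor_pos),
      permutation = proximity_permutation_test(
        c(circ$acceptor_pos, circ$donor_pos),
        c(lin$donor_pos, lin$acceptor_pos),
        n_perm = n_perm, seed = seed))
  })
  structure(list(counts = counts, clone_fractions = clone_fractions,
                 frame_audit = audit, complementarity = comp,
                 association = association),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$counts)) {
    cat("  counts:", paste(names(x$counts), unlist(x$counts), sep = "=",
                           collapse = ", "), "\n")
  }
  if (!is.null(x$clone_fractions))
    cat("  variant clone fractions (%):",
        paste(names(x$clone_fractions), sprintf("%.1f", x$clone_fractions),
              sep = "=", collapse = ", "), "\n")
  if (!is.null(x$frame_audit)) {
    fs <- x$frame_audit$frame == "frameshift"
    cat(sprintf("  frame audit: %d/%d frameshift rows flagged Yes; %d in-frame exception(s)\n",
                sum(x$frame_audit$consistent[fs]), sum(fs), sum(x$frame_audit$exception)))
  }
  if (!is.null(x$complementarity))
    cat(sprintf("  complementarity: %d/%d printed pairs recovered; %d/%d rows with a hit\n",
                x$complementarity$n_printed_recovered, x$complementarity$n_printed_pairs,
                x$complementarity$n_rows_with_hit, nrow(x$complementarity$per_row)))
  for (g in names(x$association)) {
    a <- x$association[[g]]
    cat(sprintf("  %s proximity: circ acceptors vs linear donors %.2f bp, circ donors vs linear acceptors %.2f bp, p = %.4g\n",
                g, a$acceptors_vs_donors, a$donors_vs_acceptors, a$permutation$p_value))
  }
  invisible(x)
}
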