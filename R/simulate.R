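# Synthetic genes with planted repeat-mediated splice events.
#
# The generator emulates the structure the analysis assumes: a multi-exon
# gene (14 exons by default, as in the APN genes analyzed), deletion
# variants whose breakpoints fall inside 4-8 nt co-directional repeat
# copies, circRNA junction reads, and optional 4-5 nt reverse-complement
# flank pairs near circular splice sites. Each planted repeat pair is
# written with mismatching bases immediately outside both copies, so the
# exact-match prefix/suffix arithmetic of the junction callers recovers
# the planted truth exactly (ambiguity equals the planted repeat length,
# and the canonical max-donor call is the recorded one). Canonical introns
# start GT and end AG.

.rand_bases <- function(n, gc = 0.5) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is tested under: a
#' 14-exon gene, junction repeats of 4-8 nt, complementary flank pairs of
#' 4-5 nt planted at half of the circles, and error-free (Sanger-grade)
#' query sequences.
#'
#' @param n_exons number of exons (default 14).
#' @param exon_len_range,intron_len_range inclusive bp ranges for exon and
#'   intron lengths.
#' @param repeat_len_range inclusive nt range of planted junction repeats
#'   (default 4-8).
#' @param n_linear_variants,n_circ_isoforms events planted per gene.
#' @param reads_per_circ junction reads emitted per circular isoform.
#' @param read_anchor_range inclusive nt range of the read arm lengths on
#'   each side of the back-splice.
#' @param complementary_flank_prob probability that a circle also gets a
#'   planted reverse-complement flank pair.
#' @param complementary_len_range inclusive nt range of planted flank
#'   pairs (default 4-5).
#' @param error_rate per-base substitution probability applied to emitted
#'   variant sequences and junction reads (default 0).
#' @param gc_bias expected G+C fraction of generated sequence (default 0.5,
#'   uniform base composition).
#' @param seed mandatory RNG seed; all simulation randomness derives from
#'   it and the caller's RNG state is never touched.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_exons = 14L,
                       exon_len_range = c(150L, 300L),
                       intron_len_range = c(80L, 250L),
                       repeat_len_range = c(4L, 8L),
                       n_linear_variants = 4L,
                       n_circ_isoforms = 2L,
                       reads_per_circ = 2L,
                       read_anchor_range = c(12L, 18L),
                       complementary_flank_prob = 0.5,
                       complementary_len_range = c(4L, 5L),
                       error_rate = 0,
                       gc_bias = 0.5,
                       seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  cfg <- list(n_exons = as.integer(n_exons),
              exon_len_range = as.integer(exon_len_range),
              intron_len_range = as.integer(intron_len_range),
              repeat_len_range = as.integer(repeat_len_range),
              n_linear_variants = as.integer(n_linear_variants),
              n_circ_isoforms = as.integer(n_circ_isoforms),
              reads_per_circ = as.integer(reads_per_circ),
              read_anchor_range = as.integer(read_anchor_range),
              complementary_flank_prob = as.numeric(complementary_flank_prob),
              complementary_len_range = as.integer(complementary_len_range),
              error_rate = as.numeric(error_rate),
              gc_bias = as.numeric(gc_bias),
              seed = as.integer(seed))
  rng <- function(r) length(r) == 2L && !anyNA(r) && r[1L] >= 1L && r[1L] <= r[2L]
  if (is.na(cfg$n_exons) || cfg$n_exons < 1L) stop("'n_exons' must be >= 1", call. = FALSE)
  if (!rng(cfg$exon_len_range) || !rng(cfg$intron_len_range) ||
      !rng(cfg$repeat_len_range) || !rng(cfg$read_anchor_range) ||
      !rng(cfg$complementary_len_range))
    stop("ranges must be positive (lo, hi) pairs with lo <= hi", call. = FALSE)
  if (cfg$intron_len_range[1L] < 4L)
    stop("introns need >= 4 bp to carry GT...AG", call. = FALSE)
  if (cfg$complementary_flank_prob < 0 || cfg$complementary_flank_prob > 1 ||
      cfg$error_rate < 0 || cfg$error_rate > 1 || cfg$gc_bias <= 0 || cfg$gc_bias >= 1)
    stop("probabilities must lie in [0, 1] and gc_bias in (0, 1)", call. = FALSE)
  if (is.na(cfg$seed) || cfg$seed > .Machine$integer.max - 3L)
    stop("'seed' must be an integer below 2^31 - 3", call. = FALSE)
  structure(cfg, class = "sim_config")
}

.sample_range <- function(r) if (r[1L] == r[2L]) r[1L] else sample(seq.int(r[1L], r[2L]), 1L)

# sample one integer uniformly from [lo, hi]; safe when lo == hi (a bare
# sample(x, 1) would draw from 1:x)
.sample_int <- function(lo, hi) if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L

#' Generate a synthetic gene with planted splice events
#'
#' Builds a random gene under `config` and plants the repeat pairs that
#' seed the linear-deletion and circular events: for each linear event, a
#' repeat at two cDNA loci (the variant later deletes the intervening
#' segment plus one copy); for each circular event, a repeat spanning the
#' back-splice donor and acceptor contexts in gDNA, plus (with probability
#' `complementary_flank_prob`) a reverse-complement flank pair just inside
#' the circle ends. Planted loci are kept disjoint and flanked by forced
#' mismatches so every event's canonical junction call is unambiguous.
#'
#' @param config a [sim_config()].
#' @param gene_id identifier for the generated gene.
#' @return list of class `sim_gene`: `model` (a [gene_model()]), `seeds`
#'   (data.frame of planted events: type, repeat locus/length/sequence,
#'   planted flank motif) and `config`.
#' @export
generate_gene <- function(config, gene_id = "simgene") {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, .generate_gene_impl(config, gene_id))
}

.generate_gene_impl <- function(config, gene_id) {
  n_ex <- config$n_exons
  exon_lens <- vapply(seq_len(n_ex), function(i) .sample_range(config$exon_len_range), integer(1L))
  intron_lens <- if (n_ex > 1L)
    vapply(seq_len(n_ex - 1L), function(i) .sample_range(config$intron_len_range), integer(1L))
  else integer(0)
  pieces <- list(); starts <- integer(n_ex); pos <- 1L
  for (i in seq_len(n_ex)) {
    starts[i] <- pos
    pieces[[length(pieces) + 1L]] <- .rand_bases(exon_lens[i], config$gc_bias)
    pos <- pos + exon_lens[i]
    if (i < n_ex) {
      intr <- .rand_bases(intron_lens[i], config$gc_bias)
      intr[1:2] <- c("G", "T"); intr[length(intr) - 1:0] <- c("A", "G")
      pieces[[length(pieces) + 1L]] <- intr
      pos <- pos + intron_lens[i]
    }
  }
  g <- unlist(pieces)
  exons <- data.frame(start = starts, end = starts + exon_lens - 1L)
  cmap <- unlist(mapply(seq.int, exons$start, exons$end, SIMPLIFY = FALSE))
  n_cdna <- length(cmap); n_g <- length(g)
  reserved <- logical(n_g)
  seeds <- list()

  reserve <- function(idx) reserved[idx[idx >= 1L & idx <= n_g]] <<- TRUE
  free <- function(idx) all(idx >= 1L & idx <= n_g) && !any(reserved[idx])

  # linear events: repeat R at cDNA loci i and j; forced mismatches at
  # (i-1, j-1) and (i+r, j+r) pin the common prefix/suffix exactly
  for (e in seq_len(config$n_linear_variants)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      r <- .sample_range(config$repeat_len_range)
      lo_i <- 13L; hi_j <- n_cdna - r - 12L
      if (hi_j - lo_i < r + 40L) break
      i <- .sample_int(lo_i, hi_j - r - 40L)
      j <- .sample_int(i + r + 40L, hi_j)
      w1 <- cmap[seq.int(i - 2L, min(i + r + 1L, n_cdna))]
      w2 <- cmap[seq.int(j - 2L, min(j + r + 1L, n_cdna))]
      if (!free(w1) || !free(w2)) next
      placed <- TRUE
      break
    }
    if (!placed)
      stop("cannot place repeat pair disjointly; ranges are infeasible for n_linear_variants",
           call. = FALSE)
    R <- .rand_bases(r, config$gc_bias)
    g[cmap[seq.int(i, i + r - 1L)]] <- R
    g[cmap[seq.int(j, j + r - 1L)]] <- R
    if (g[cmap[i - 1L]] == g[cmap[j - 1L]]) g[cmap[j - 1L]] <- .other_base(g[cmap[j - 1L]])
    if (g[cmap[i + r]] == g[cmap[j + r]]) g[cmap[j + r]] <- .other_base(g[cmap[j + r]])
    reserve(w1); reserve(w2)
    seeds[[length(seeds) + 1L]] <- data.frame(
      event_id = sprintf("%s_V%d", gene_id, e), type = "linear",
      repeat_len = r, repeat_seq = paste(R, collapse = ""),
      locus1 = i, locus2 = j, motif = NA_character_, motif_len = NA_integer_,
      stringsAsFactors = FALSE)
  }

  # circular events: repeat R at gDNA [d-r+1..d] and [a-r..a-1]; forced
  # mismatches at (d+1 vs a) and (d-r vs a-r-1) make (d, a) the canonical
  # max-donor call with ambiguity exactly r
  for (e in seq_len(config$n_circ_isoforms)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      r <- .sample_range(config$repeat_len_range)
      lo_a <- r + 14L; hi_d <- n_g - 10L
      if (hi_d - lo_a < 220L)
        stop("gene too short for circular events", call. = FALSE)
      a <- .sample_int(lo_a, hi_d - 220L)
      d <- .sample_int(a + 200L, hi_d)
      wa <- seq.int(a - r - 1L, a + 7L)
      wd <- seq.int(d - r, min(d + 7L, n_g))
      if (!free(wa) || !free(wd)) next
      placed <- TRUE
      break
    }
    if (!placed)
      stop("cannot place back-splice repeat disjointly; ranges are infeasible", call. = FALSE)
    R <- .rand_bases(r, config$gc_bias)
    g[seq.int(d - r + 1L, d)] <- R
    g[seq.int(a - r, a - 1L)] <- R
    if (g[d + 1L] == g[a]) g[d + 1L] <- .other_base(g[d + 1L])
    if (g[d - r] == g[a - r - 1L]) g[d - r] <- .other_base(g[d - r])
    motif <- NA_character_; mlen <- NA_integer_
    if (runif(1L) < config$complementary_flank_prob) {
      mlen <- .sample_range(config$complementary_len_range)
      m <- .rand_bases(mlen, config$gc_bias)
      g[seq.int(d + 2L, d + 1L + mlen)] <- m
      g[seq.int(a + 2L, a + 1L + mlen)] <-
        strsplit(reverse_complement(paste(m, collapse = "")), "", fixed = TRUE)[[1L]]
      motif <- paste(m, collapse = "")
    }
    reserve(wa); reserve(wd)
    seeds[[length(seeds) + 1L]] <- data.frame(
      event_id = sprintf("%s_C%d", gene_id, e), type = "circ",
      repeat_len = r, repeat_seq = paste(R, collapse = ""),
      locus1 = a, locus2 = d, motif = motif, motif_len = mlen,
      stringsAsFactors = FALSE)
  }

  model <- gene_model(gene_id, paste(g, collapse = ""), exons)
  structure(list(model = model,
                 seeds = if (length(seeds)) do.call(rbind, seeds) else NULL,
                 config = config),
            class = "sim_gene")
}

.inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- which(runif(length(v)) < rate)
    for (h in hit) v[h] <- .other_base(v[h])
    paste(v, collapse = "")
  }, character(1L), USE.NAMES = TRUE)
}

#' Emit deletion-variant sequences with ground truth
#'
#' For each planted linear event the variant removes the segment between
#' the two repeat copies plus one copy, so the junction carries the repeat
#' as a co-directional repeat. Truth records the canonical (max-donor)
#' call that [call_linear_junction()] must return.
#'
#' @param sim a `sim_gene` from [generate_gene()].
#' @param config optional [sim_config()]; defaults to `sim$config`.
#' @return list with `sequences` (named variant cDNAs) and `truth`
#'   (data.frame: event_id, donor, acceptor and deletion region in cDNA
#'   coordinates, deletion_len, ambiguity_len, repeat_seq, frame).
#' @export
simulate_linear_variants <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "sim_gene"))
  seeds <- sim$seeds[sim$seeds$type == "linear", , drop = FALSE]
  cdna <- sim$model$cdna; n <- nchar(cdna)
  if (!nrow(seeds))
    return(list(sequences = character(0), truth = NULL))
  seqs <- character(0); truth <- list()
  for (k in seq_len(nrow(seeds))) {
    s <- seeds[k, ]
    i <- s$locus1; j <- s$locus2; r <- s$repeat_len
    v <- paste0(substr(cdna, 1L, i - 1L), substr(cdna, j, n))
    seqs[[s$event_id]] <- v
    truth[[k]] <- data.frame(
      event_id = s$event_id,
      donor = i + r - 1L, acceptor = j + r,
      deletion_start = i + r, deletion_end = j + r - 1L,
      deletion_len = j - i, ambiguity_len = r, repeat_seq = s$repeat_seq,
      frame = classify_frame(i + r, j + r - 1L),
      stringsAsFactors = FALSE)
  }
  seqs <- .with_seed(config$seed + 1L, .inject_errors(seqs, config$error_rate))
  list(sequences = seqs, truth = do.call(rbind, truth))
}

#' Emit back-splice junction reads with ground truth
#'
#' Each planted circle yields `reads_per_circ` reads of the form
#' `gdna[d-L1+1 .. d] + gdna[a .. a+L2-1]` with arm lengths drawn from
#' `read_anchor_range`, i.e. reads straddling the head-to-tail junction.
#'
#' @param sim a `sim_gene` from [generate_gene()].
#' @param config optional [sim_config()]; defaults to `sim$config`.
#' @return list with `reads` (named character) and `truth` (data.frame:
#'   read_id, event_id, donor, acceptor in gDNA coordinates,
#'   ambiguity_len, repeat_seq, planted motif and its reverse complement).
#' @export
simulate_circ_reads <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "sim_gene"))
  seeds <- sim$seeds[sim$seeds$type == "circ", , drop = FALSE]
  if (!nrow(seeds))
    return(list(reads = character(0), truth = NULL))
  gdna <- sim$model$sequence
  .with_seed(config$seed + 2L, {
    reads <- character(0); truth <- list()
    for (k in seq_len(nrow(seeds))) {
      s <- seeds[k, ]
      a <- s$locus1; d <- s$locus2
      span <- d - a + 1L
      for (rd in seq_len(config$reads_per_circ)) {
        L1 <- min(.sample_range(config$read_anchor_range), span)
        L2 <- min(.sample_range(config$read_anchor_range), span)
        # a junction read must identify its junction uniquely; when a read
        # arm happens to match a second locus (chance k-mer duplication),
        # grow the arms -- mirroring the discard of non-uniquely-mapping
        # junction reads in real circRNA validation
        ok <- FALSE
        for (grow in 0:12) {
          read <- paste0(substr(gdna, d - L1 + 1L, d), substr(gdna, a, a + L2 - 1L))
          if (!grepl(read, gdna, fixed = TRUE)) {
            dec <- .backsplice_decompositions(gdna, read, min(8L, L1, L2))
            # the planted (d, a) is always among the candidates and is its
            # own canonical form, so a unique decomposition is the truth
            if (nrow(dec) == 1L) { ok <- TRUE; break }
          }
          L1 <- min(L1 + 6L, span, d)
          L2 <- min(L2 + 6L, span, nchar(gdna) - a + 1L)
        }
        if (!ok)
          stop("cannot emit an unambiguous junction read for ", s$event_id, call. = FALSE)
        id <- sprintf("%s_r%d", s$event_id, rd)
        reads[[id]] <- read
        truth[[length(truth) + 1L]] <- data.frame(
          read_id = id, event_id = s$event_id,
          donor = d, acceptor = a,
          ambiguity_len = s$repeat_len, repeat_seq = s$repeat_seq,
          motif = s$motif,
          motif_rc = if (is.na(s$motif)) NA_character_ else reverse_complement(s$motif),
          stringsAsFactors = FALSE)
      }
    }
    list(reads = .inject_errors(reads, config$error_rate),
         truth = do.call(rbind, truth))
  })
}

#' Simulate a multi-gene dataset
#'
#' Convenience wrapper: generates `n_genes` independent genes (per-gene
#' seeds derived deterministically from `config$seed`) and pools variants,
#' junction reads and truth tables.
#'
#' @param config a [sim_config()].
#' @param n_genes number of genes.
#' @return list with `genes` (list of `sim_gene`), `linear` and `circ`
#'   (each: per-gene list with sequences/reads and truth).
#' @export
simulate_dataset <- function(config, n_genes = 50L) {
  stopifnot(inherits(config, "sim_config"))
  n_genes <- as.integer(n_genes)
  gene_seeds <- .with_seed(config$seed,
                           sample.int(.Machine$integer.max - 3L, n_genes))
  out <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    cfg_i <- config; cfg_i$seed <- gene_seeds[i]
    sim <- generate_gene(cfg_i, gene_id = sprintf("g%03d", i))
    out[[i]] <- list(sim = sim,
                     linear = simulate_linear_variants(sim, cfg_i),
                     circ = simulate_circ_reads(sim, cfg_i))
  }
  out
}
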