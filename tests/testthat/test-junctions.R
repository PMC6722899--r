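test_that("linear junction calling recovers the repeat-flanked deletion", {
  # 8-bp deletion flanked by the CTTG repeat: canonical max-donor placement
  jc <- call_linear_junction("ATGCCTTGAAAACTTGGGAT", "ATGCCTTGGGAT", min_anchor = 4)
  expect_equal(jc$kind, "linear_deletion")
  expect_equal(jc$donor_pos, 8L)
  expect_equal(jc$acceptor_pos, 17L)
  expect_equal(jc$deletion_len, 8L)
  expect_equal(jc$ambiguity_len, 4L)
  expect_identical(jc$repeat_seq, "CTTG")

  # repeat-free deletion
  jc2 <- call_linear_junction("AAACCCGGGTTT", "AAATTT", min_anchor = 3)
  expect_equal(jc2$donor_pos, 3L)
  expect_equal(jc2$acceptor_pos, 10L)
  expect_equal(jc2$ambiguity_len, 0L)
  expect_identical(jc2$repeat_seq, "")

  expect_equal(call_linear_junction("ACGTACGTAA", "ACGTACGTAA")$kind, "none")
})

test_that("linear junction calling rejects what is not a single deletion", {
  expect_error(call_linear_junction("ACGT", "ACGTA"), "not a deletion")
  # a substitution is not a deletion
  expect_error(call_linear_junction("ACGTACGTACGT", "ACGTAGGTACGT", min_anchor = 2),
               "single contiguous deletion")
  # an interior insertion relative to the reference is not a deletion either
  expect_error(call_linear_junction("AAAACCCCGGGGTTTT", "AAAATTGGGGTTTT", min_anchor = 2),
               "single contiguous deletion")
  expect_error(call_linear_junction("ATGCCTTGAAAACTTGGGAT", "ATGCCTTGGGAT",
                                    min_anchor = 5), "anchor too short")
})

test_that("back-splice calling decomposes head-to-tail reads", {
  jc <- call_backsplice("AAACCCGGGTTTACGTACGA", "TTACGCCCGG", min_anchor = 4)
  expect_equal(jc$kind, "backsplice")
  expect_equal(jc$donor_pos, 15L)
  expect_equal(jc$acceptor_pos, 4L)
  expect_equal(jc$ambiguity_len, 0L)

  expect_equal(call_backsplice("AAACCCGGGTTTACGTACGA", "CCCGGGTTT",
                               min_anchor = 4)$kind, "none")

  # read arms both overlap a 7-bp direct repeat; the oracle fixes the
  # expected canonical tuple (computed by oracle_backsplice, frozen here)
  jc3 <- call_backsplice("GGTTACGGCAATTACGGCTT", "ACGGCTTGGTTACGGCA", min_anchor = 4)
  orc <- oracle_backsplice("GGTTACGGCAATTACGGCTT", "ACGGCTTGGTTACGGCA", 4)
  expect_equal(orc$status, "call")
  expect_equal(jc3$donor_pos, 20L)
  expect_equal(jc3$acceptor_pos, 1L)
  expect_equal(jc3$ambiguity_len, 0L)
  expect_equal(jc3$donor_pos, orc$donor)
  expect_equal(jc3$acceptor_pos, orc$acceptor)
  expect_equal(jc3$ambiguity_len, orc$ambiguity)
})

test_that("repeat-induced back-splice ambiguity is canonicalized to the max donor", {
  # CAT repeat at the circle's 3' end [12..14] and just upstream of its 5'
  # end [4..6]: the junction can slide across the repeat, and the
  # canonical call keeps the maximal donor
  g <- "AAGCATTTTTTCATGGGGAA"
  read <- paste0(substr(g, 9, 14), substr(g, 7, 12))  # arms around (d=14, a=7)
  jc <- call_backsplice(g, read, min_anchor = 4)
  orc <- oracle_backsplice(g, read, 4)
  expect_equal(jc$donor_pos, 14L)
  expect_equal(jc$acceptor_pos, 7L)
  expect_equal(jc$ambiguity_len, 3L)
  expect_identical(jc$repeat_seq, "CAT")
  expect_equal(jc$donor_pos, orc$donor)
  expect_equal(jc$acceptor_pos, orc$acceptor)
  expect_equal(jc$ambiguity_len, orc$ambiguity)
  expect_identical(jc$repeat_seq, orc$repeat_seq)
})

test_that("non-equivalent decompositions raise an ambiguity error", {
  # the same arm pair occurs at two distinct loci
  block <- "ACGTACGGTTCA"
  ref <- paste0("AATT", block, "GGCCGGCC", block, "TTAA")
  read <- paste0(substr(block, 7, 12), substr(block, 1, 6))
  expect_error(call_backsplice(ref, read, min_anchor = 4), "ambiguous backsplice")
})

test_that("junction callers agree with brute-force split enumeration", {
  set.seed(20230917)
  n_agree <- 0L
  for (case in 1:150) {
    nR <- sample(20:60, 1)
    ref <- rand_dna(nR)
    min_anchor <- sample(3:6, 1)
    # linear: random true deletions, plus occasional unrelated variants
    if (case %% 3 == 0) {
      var <- rand_dna(sample(5:nR, 1))
    } else {
      d0 <- sample(0:(nR - 2), 1)
      del <- sample(1:(nR - d0 - 1), 1)
      var <- paste0(substr(ref, 1, d0), substr(ref, d0 + del + 1, nR))
    }
    orc <- oracle_linear(ref, var, min_anchor)
    got <- tryCatch(call_linear_junction(ref, var, min_anchor),
                    error = function(e) conditionMessage(e))
    if (orc$status == "call") {
      expect_false(is.character(got), label = sprintf("case %d unexpectedly errored", case))
      expect_equal(got$donor_pos, orc$donor)
      expect_equal(got$acceptor_pos, orc$acceptor)
      expect_equal(got$deletion_len, orc$deletion_len)
      expect_equal(got$ambiguity_len, orc$ambiguity)
      expect_identical(got$repeat_seq, orc$repeat_seq)
      # conservation
      expect_equal(got$deletion_len + nchar(var), nR)
      n_agree <- n_agree + 1L
    } else if (orc$status == "none") {
      expect_equal(got$kind, "none")
    } else {
      expect_true(is.character(got), label = sprintf("case %d should be rejected", case))
    }
  }
  expect_gt(n_agree, 40L)  # the generator must exercise accepted calls

  # back-splice: reads built around true circles, plus unrelated reads
  n_agree <- 0L
  for (case in 1:120) {
    nR <- sample(25:60, 1)
    ref <- rand_dna(nR)
    min_anchor <- sample(3:5, 1)
    if (case %% 4 == 0) {
      read <- rand_dna(sample(8:(nR - 1), 1))
    } else {
      a <- sample(1:(nR - 10), 1)
      d <- sample((a + 8):nR, 1)
      L1 <- sample(min_anchor:min(8, d - a + 1), 1)
      L2 <- sample(min_anchor:min(8, d - a + 1), 1)
      read <- paste0(substr(ref, d - L1 + 1, d), substr(ref, a, a + L2 - 1))
    }
    if (nchar(read) >= nR) next
    orc <- oracle_backsplice(ref, read, min_anchor)
    got <- tryCatch(call_backsplice(ref, read, min_anchor),
                    error = function(e) conditionMessage(e))
    if (orc$status == "call") {
      expect_false(is.character(got), label = sprintf("circ case %d unexpectedly errored", case))
      expect_equal(got$donor_pos, orc$donor)
      expect_equal(got$acceptor_pos, orc$acceptor)
      expect_equal(got$ambiguity_len, orc$ambiguity)
      expect_identical(got$repeat_seq, orc$repeat_seq)
      n_agree <- n_agree + 1L
    } else if (orc$status == "none") {
      expect_equal(got$kind, "none")
    } else if (orc$status == "ambiguous") {
      expect_match(got, "ambiguous backsplice")
    } else {
      expect_true(is.character(got))
    }
  }
  expect_gt(n_agree, 30L)
})

test_that("shifting a junction within its ambiguity interval gives the same canonical call", {
  set.seed(99)
  for (case in 1:25) {
    ref <- rand_dna(50)
    # plant a repeat: copy the block [21..24] to [31..34]
    r <- substr(ref, 21, 24)
    ref <- paste0(substr(ref, 1, 30), r, substr(ref, 35, 50))
    calls <- lapply(0:4, function(t) {
      # delete [21+t .. 30+t]: all placements across the repeat are equivalent
      v <- paste0(substr(ref, 1, 20 + t), substr(ref, 31 + t, 50))
      call_linear_junction(ref, v, min_anchor = 4)
    })
    base <- calls[[1]]
    for (jc in calls[-1]) {
      expect_equal(jc$donor_pos, base$donor_pos)
      expect_equal(jc$acceptor_pos, base$acceptor_pos)
      expect_identical(jc$repeat_seq, base$repeat_seq)
    }
    expect_gte(base$ambiguity_len, 4L)
  }
})

test_that("cDNA/gDNA coordinate maps are mutually inverse and exon labels correct", {
  m <- toy_model()
  expect_equal(map_cdna_to_gdna(5, m), 9L)
  expect_equal(map_cdna_to_gdna(4, m), 4L)
  expect_error(map_cdna_to_gdna(9, m), "out of range")
  expect_equal(map_gdna_to_cdna(9, m), 5L)
  expect_error(map_gdna_to_cdna(6, m), "not exonic")

  expect_equal(assign_exon(2, m), "exon1")
  expect_equal(assign_exon(6, m), "intron1")
  expect_equal(assign_exon(12, m), "exon2")

  set.seed(7)
  for (rep in 1:20) {
    n_ex <- sample(2:6, 1)
    starts <- sort(sample(seq(1, 180, by = 10), n_ex))
    ends <- starts + sample(3:8, n_ex, replace = TRUE)
    m2 <- gene_model("r", rand_dna(200), data.frame(start = starts, end = ends))
    pos <- seq_len(m2$cdna_length)
    expect_equal(map_gdna_to_cdna(map_cdna_to_gdna(pos, m2), m2), pos)
  }
})
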