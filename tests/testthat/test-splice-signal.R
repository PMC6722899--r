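test_that("co-directional repeat extension recovers the junction repeat", {
  ann <- find_codirectional_repeat("ATGCCTTGAAAACTTGGGAT", 8, 17)
  expect_identical(ann$repeat_seq, "CTTG")
  expect_equal(ann$length, 4L)
  expect_equal(ann$donor_copy_start, 5L)
  expect_equal(ann$acceptor_copy_start, 13L)

  ann0 <- find_codirectional_repeat("AAACCCGGGTTT", 3, 10)
  expect_equal(ann0$length, 0L)
  expect_identical(ann0$repeat_seq, "")

  expect_error(find_codirectional_repeat("ACGT", 9, 2), "out of range")
})

test_that("repeat length equals the caller's ambiguity for the same junction", {
  set.seed(512)
  checked <- 0L
  for (case in 1:60) {
    ref <- rand_dna(sample(30:60, 1))
    d0 <- sample(5:(nchar(ref) - 10), 1)
    del <- sample(1:(nchar(ref) - d0 - 5), 1)
    var <- paste0(substr(ref, 1, d0), substr(ref, d0 + del + 1, nchar(ref)))
    jc <- tryCatch(call_linear_junction(ref, var, min_anchor = 3),
                   error = function(e) NULL)
    if (is.null(jc) || jc$kind == "none") next
    ann <- find_codirectional_repeat(ref, jc$donor_pos, jc$acceptor_pos)
    expect_equal(ann$length, jc$ambiguity_len)
    expect_identical(ann$repeat_seq,
                     if (jc$ambiguity_len) jc$repeat_seq else "")
    checked <- checked + 1L
  }
  expect_gt(checked, 20L)
})

test_that("splice signals are classified by the flanking dinucleotides", {
  # constructed canonical intron: exon|GTAAGT...TTTCAG|exon
  g <- "CAGGTAAGTCCCTTTCAGGCA"
  sig <- classify_splice_signal(g, donor_pos = 3, acceptor_pos = 19)
  expect_equal(sig$label, "canonical_GT_AG")
  expect_equal(sig$donor_dinucleotide, "GT")
  expect_equal(sig$acceptor_dinucleotide, "AG")

  sig2 <- classify_splice_signal("AAAACCCCTTTT", 4, 9)
  expect_equal(sig2$label, "noncanonical")
  expect_equal(sig2$donor_dinucleotide, "CC")
  expect_equal(sig2$acceptor_dinucleotide, "CC")

  expect_error(classify_splice_signal("ACGT", 3, 2), "out of range")
})

test_that("simulated annotated introns all carry canonical GT/AG", {
  sim <- generate_gene(sim_config(seed = 11, n_linear_variants = 0L,
                                  n_circ_isoforms = 0L))
  ex <- sim$model$exons
  labs <- vapply(seq_len(nrow(ex) - 1L), function(k)
    classify_splice_signal(sim$model$sequence, ex$end[k], ex$start[k + 1])$label,
    character(1))
  expect_true(all(labs == "canonical_GT_AG"))
})

test_that("longest common substring matches brute force and the fixture windows", {
  # windows of two circular isoforms (frozen from the brute-force oracle)
  r1 <- longest_common_substring("TAACTACGATCAAATCACTT", "GAATGAAGCCCAAATCACTC")
  expect_identical(r1$string, "CAAATCACT")
  expect_equal(r1$length, 9L)
  r2 <- longest_common_substring("AACTACGATCAAATCACTTG", "ATTTTGAACGAAATCACAGC")
  expect_identical(r2$string, "AAATCAC")
  expect_equal(r2$length, 7L)
  expect_identical(longest_common_substring("ACGTA", "ACGTA")$string, "ACGTA")

  set.seed(31)
  for (case in 1:60) {
    s1 <- rand_dna(sample(4:30, 1)); s2 <- rand_dna(sample(4:30, 1))
    got <- longest_common_substring(s1, s2)
    exp <- oracle_lcs(s1, s2)
    expect_equal(got$length, exp$length)
    expect_identical(got$string, exp$string)
    expect_equal(got$start1, exp$start1)
    expect_equal(got$start2, exp$start2)
  }
})

test_that("every circRNA flank-window pair shares a repeat of length >= 4", {
  t6 <- load_fixture_table("T6")
  lens <- mapply(function(a, b) longest_common_substring(a, b)$length,
                 t6$seq1, t6$seq2)
  expect_true(all(lens >= 4L))
})
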