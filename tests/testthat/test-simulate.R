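test_that("sim_config validates its inputs and requires a seed", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, error_rate = 1.5), "probabilities")
  expect_error(sim_config(seed = 1, repeat_len_range = c(8, 4)), "ranges")
  expect_error(sim_config(seed = 1, intron_len_range = c(2, 3)), "GT")
  cfg <- sim_config(seed = 5)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_exons, 14L)
  expect_equal(cfg$repeat_len_range, c(4L, 8L))
})

test_that("gene generation is deterministic and structurally correct", {
  cfg <- sim_config(seed = 13)
  a <- generate_gene(cfg)
  b <- generate_gene(cfg)
  expect_identical(a$model$sequence, b$model$sequence)
  expect_identical(a$seeds, b$seeds)

  expect_equal(nrow(a$model$exons), 14L)
  expect_equal(a$model$cdna_length,
               sum(a$model$exons$end - a$model$exons$start + 1L))
  # 13 introns, each GT...AG
  ex <- a$model$exons
  for (k in 1:13) {
    expect_identical(substr(a$model$sequence, ex$end[k] + 1, ex$end[k] + 2), "GT")
    expect_identical(substr(a$model$sequence, ex$start[k + 1] - 2, ex$start[k + 1] - 1), "AG")
  }
})

test_that("generated base composition is unbiased at gc_bias = 0.5", {
  cfg <- sim_config(seed = 2024, n_exons = 4L, n_linear_variants = 0L,
                    n_circ_isoforms = 0L)
  bases <- unlist(lapply(1:30, function(i) {
    cfg$seed <- 2024 + i
    strsplit(generate_gene(cfg)$model$sequence, "")[[1]]
  }))
  gc <- mean(bases %in% c("G", "C"))
  n <- length(bases)
  ci <- 0.5 + c(-1, 1) * 1.96 * sqrt(0.25 / n)
  expect_gt(gc, ci[1] - 0.01)
  expect_lt(gc, ci[2] + 0.01)
})

test_that("error-free linear variants are recovered exactly from truth", {
  sim <- generate_gene(sim_config(seed = 3))
  lv <- simulate_linear_variants(sim)
  expect_equal(nrow(lv$truth), 4L)
  for (k in seq_len(nrow(lv$truth))) {
    tr <- lv$truth[k, ]
    jc <- call_linear_junction(sim$model$cdna, lv$sequences[[tr$event_id]])
    expect_equal(jc$donor_pos, tr$donor)
    expect_equal(jc$acceptor_pos, tr$acceptor)
    expect_equal(jc$deletion_len, tr$deletion_len)
    expect_equal(jc$ambiguity_len, tr$ambiguity_len)
    expect_identical(jc$repeat_seq, tr$repeat_seq)
    # the deletion region recorded in truth reproduces the variant
    expect_identical(reconstruct_variant(sim$model$cdna, tr$deletion_start, tr$deletion_end),
                     unname(lv$sequences[[tr$event_id]]))
  }
})

test_that("error-free junction reads are recovered exactly from truth", {
  sim <- generate_gene(sim_config(seed = 17, complementary_flank_prob = 1))
  cr <- simulate_circ_reads(sim)
  expect_equal(length(unique(cr$truth$event_id)), 2L)
  for (k in seq_len(nrow(cr$truth))) {
    tr <- cr$truth[k, ]
    jc <- call_backsplice(sim$model$sequence, cr$reads[[tr$read_id]])
    expect_equal(jc$kind, "backsplice")
    expect_equal(jc$donor_pos, tr$donor)
    expect_equal(jc$acceptor_pos, tr$acceptor)
    expect_equal(jc$ambiguity_len, tr$ambiguity_len)
    expect_identical(jc$repeat_seq, tr$repeat_seq)
  }
})

test_that("planted complementary flank pairs are found with full sensitivity", {
  found <- 0L; total <- 0L
  for (s in c(21, 22, 23)) {
    sim <- generate_gene(sim_config(seed = s, complementary_flank_prob = 1))
    tru <- sim$seeds[sim$seeds$type == "circ", ]
    for (k in seq_len(nrow(tru))) {
      total <- total + 1L
      a <- tru$locus1[k]; d <- tru$locus2[k]; m <- tru$motif[k]
      wd <- extract_flanks(sim$model$sequence, d, 10, "after")$window
      wa <- extract_flanks(sim$model$sequence, a, 10, "before")$window
      hits <- find_rc_matches(wd, wa, 4)
      hit <- any(mapply(function(m1, m2)
        grepl(m, m1, fixed = TRUE) && grepl(reverse_complement(m), m2, fixed = TRUE),
        hits$match1, hits$match2))
      found <- found + hit
    }
  }
  expect_equal(found, total)
  expect_equal(total, 6L)
})

test_that("reads with arms below the caller's anchor are rejected", {
  sim <- generate_gene(sim_config(seed = 29))
  tru <- sim$seeds[sim$seeds$type == "circ", ][1, ]
  a <- tru$locus1; d <- tru$locus2
  g <- sim$model$sequence
  short_read <- paste0(substr(g, d - 5, d), substr(g, a, a + 5))  # 6-bp arms
  expect_error(call_backsplice(g, short_read, min_anchor = 8),
               "no backsplice decomposition")
  # the same junction with default-length arms is callable
  long_read <- paste0(substr(g, d - 13, d), substr(g, a, a + 13))
  jc <- call_backsplice(g, long_read, min_anchor = 8)
  expect_equal(jc$donor_pos, d)
  expect_equal(jc$acceptor_pos, a)
})

test_that("base-call errors perturb emitted sequences but not the reference", {
  cfg0 <- sim_config(seed = 41, error_rate = 0)
  cfgE <- sim_config(seed = 41, error_rate = 0.1)
  sim0 <- generate_gene(cfg0); simE <- generate_gene(cfgE)
  expect_identical(sim0$model$sequence, simE$model$sequence)
  v0 <- simulate_linear_variants(sim0)$sequences
  vE <- simulate_linear_variants(simE)$sequences
  expect_identical(names(v0), names(vE))
  expect_equal(nchar(v0), nchar(vE))
  expect_false(all(v0 == vE))
})
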