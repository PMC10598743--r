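test_that("simulators are deterministic given the seed", {
  cfg <- sim_config(seed = 11, n_units = 6)
  a <- simulate_netseq(cfg)
  b <- simulate_netseq(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$coverage$plus, b$coverage$plus)
  expect_identical(a$coverage$minus, b$coverage$minus)
  expect_identical(a$truth, b$truth)

  pa <- suppressMessages(simulate_polya(a$units, a$truth, cfg, genome = a$genome))
  pb <- suppressMessages(simulate_polya(b$units, b$truth, cfg, genome = b$genome))
  expect_identical(pa, pb)

  ta <- simulate_feature_tracks(a$truth, a$units, cfg, a$genome)
  tb <- simulate_feature_tracks(b$truth, b$units, cfg, b$genome)
  expect_identical(ta, tb)

  ra <- suppressMessages(simulate_3reads(pa, a$genome, a$units, cfg))
  rb <- suppressMessages(simulate_3reads(pb, b$genome, b$units, cfg))
  expect_identical(ra, rb)
})

test_that("zero pause rate gives pure NB background and empty truth", {
  cfg <- sim_config(seed = 3, n_units = 4, pause_rate = 0)
  sim <- simulate_netseq(cfg)
  expect_identical(nrow(sim$truth), 0L)
  # coupled poly(A) with no pauses is vacuously empty
  expect_identical(nrow(simulate_polya(sim$units, sim$truth, cfg)), 0L)
})

test_that("pause_fold at or below 1 is refused", {
  expect_error(sim_config(pause_fold = 1), "pause_fold")
  expect_error(sim_config(pause_fold = 0.5), "pause_fold")
})

test_that("background dispersion approaches the Poisson limit as size grows", {
  # NB variance is mu + mu^2/size; at size 1e8 var/mean should be ~1
  cfg <- sim_config(seed = 5, n_units = 80, nb_dispersion = 1e8, pause_rate = 0)
  sim <- simulate_netseq(cfg)
  x <- unlist(lapply(seq_len(nrow(sim$units)), function(i) {
    u <- sim$units[i, ]
    coverage_at(sim$coverage, u$chrom, u$strand,
                seq.int(u$range_start, u$range_end - 1L))
  }))
  expect_gte(length(x), 1e5)
  vm <- var(x) / mean(x)
  expect_gt(vm, 0.9); expect_lt(vm, 1.1)

  # and at the default dispersion the background is visibly overdispersed
  cfg2 <- sim_config(seed = 5, n_units = 30, pause_rate = 0)
  sim2 <- simulate_netseq(cfg2)
  u <- sim2$units[1, ]
  y <- unlist(lapply(seq_len(nrow(sim2$units)), function(i) {
    u <- sim2$units[i, ]
    coverage_at(sim2$coverage, u$chrom, u$strand,
                seq.int(u$range_start, u$range_end - 1L))
  }))
  expect_gt(var(y) / mean(y), 1.2)
})

test_that("coupled poly(A) sites sit a fixed offset upstream of their pause", {
  u <- one_unit(strand = "+", tu_start = 0L, tu_end = 1000L)
  truth <- pause_df(u, 120L)
  cfg <- sim_config(seed = 2, polya_coupling = "coupled",
                    coupling_offset_range = c(20L, 20L))
  prof <- simulate_polya(u, truth, cfg)
  expect_identical(prof$rel_pos, 100L)
  expect_identical(prof$pos0, as.integer(u$stop_codon_ref + 100L))

  um <- one_unit(strand = "-", tu_start = 500L, tu_end = 1500L)
  profm <- simulate_polya(um, pause_df(um, 120L), cfg)
  expect_identical(profm$rel_pos, 100L)
  expect_identical(profm$pos0, as.integer(um$stop_codon_ref - 1L - 100L))

  # offsets pushing a site below position 0 drop it with a message
  expect_message(
    none <- simulate_polya(u, pause_df(u, 5L), cfg), "dropped")
  expect_identical(nrow(none), 0L)
})

test_that("uniform poly(A) placement is uniform over the window", {
  cfg <- sim_config(seed = 13, n_units = 100, polya_coupling = "uniform",
                    polya_sites_per_unit = 100)
  sim <- simulate_netseq(cfg)
  prof <- simulate_polya(sim$units, sim$truth, cfg)
  expect_gte(nrow(prof), 9000)
  bins <- table(cut(prof$rel_pos, breaks = seq(0, 400, 40),
                    include.lowest = TRUE, right = FALSE))
  expect_gt(suppressWarnings(chisq.test(bins)$p.value), 0.01)
})

test_that("3'READS reads are T-stretches plus the reverse-complemented sense 17-mer", {
  set.seed(1)
  gstr <- random_dna(400, seed = 99)
  g <- mini_genome(chr1 = gstr)
  u <- one_unit(tu_start = 0L, tu_end = 100L, utr3_len = 300L, chrom = "chr1",
                seqlengths = genome_seqlengths(g))
  cfg <- sim_config(seed = 4, tail_extra_mean = 1)  # extra tail Ts fixed at 1
  prof <- simulate_polya(u, pause_df(u, c(100L, 200L)),
                         sim_config(seed = 4, coupling_offset_range = c(20L, 20L),
                                    tail_extra_mean = 1),
                         genome = g)
  reads <- simulate_3reads(prof, g, u, cfg)
  expect_identical(nrow(reads), sum(prof$count))
  for (i in seq_len(nrow(prof))) {
    s17 <- sense_sequence(g, "chr1", "+", prof$pos0[i] - 16L, prof$pos0[i] + 1L)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s17)))
    hits <- grepl(paste0("^T+", rc, "$"), reads$read)
    expect_identical(sum(hits), prof$count[i])
  }
})

test_that("feature tracks have the configured signal-to-noise against pauses", {
  cfg0 <- sim_config(seed = 21, n_units = 80, pause_rate = 10,
                     feature_snr = c(dna_shape = 0, chromatin = 10))
  sim <- simulate_netseq(cfg0)
  tracks <- simulate_feature_tracks(sim$truth, sim$units, cfg0, sim$genome)
  ind <- numeric(genome_seqlengths(sim$genome)[[1]])
  ind[sim$truth$pos0 + 1L] <- 1
  expect_gte(length(ind), 1e5)
  r0 <- cor(tracks$dna_shape$chrS1, ind)
  r10 <- cor(tracks$chromatin$chrS1, ind)
  expect_lt(abs(r0), 0.05)   # snr 0: pure noise
  expect_gt(r10, 0.5)        # snr 10: strong point-biserial association
})
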