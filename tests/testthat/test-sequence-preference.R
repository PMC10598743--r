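test_that("pause trinucleotides are read on the sense strand", {
  # + strand: top-strand ...T[G]A... at offsets (-1, 0, +1)
  g <- mini_genome(chr1 = "AAATGAAAA")
  u <- one_unit(tu_start = 0L, tu_end = 2L, utr3_len = 7L, chrom = "chr1",
                seqlengths = genome_seqlengths(g))
  p <- pause_df(u, 2L)                 # pos0 = 4, the G
  expect_identical(p$pos0, 4L)
  cnt <- trinuc_counts(p, g)
  expect_identical(unname(cnt["TGA"]), 1L)
  expect_identical(sum(cnt), 1L)

  # - strand: top-strand TCA centered at the pause reads TGA in sense
  gm <- mini_genome(chr1 = "AAATCAAAA")
  um <- make_units("m1", "chr1", "-", tu_start = 7L, tu_end = 9L,
                   utr3_len = 7L, seqlengths = genome_seqlengths(gm))
  pm <- pause_df(um, 2L)               # pos0 = 7 - 1 - 2 = 4, center of TCA
  expect_identical(pm$pos0, 4L)
  cntm <- trinuc_counts(pm, gm)
  expect_identical(unname(cntm["TGA"]), 1L)

  expect_error(trinuc_counts(p, g, offset_start = 3L), "offset")
})

test_that("trinucleotide counts are conserved and match a brute-force scan", {
  cfg <- sim_config(seed = 37, n_units = 10)
  sim <- simulate_netseq(cfg)
  calls <- call_pauses(sim$coverage, sim$units)
  gstr <- as.character(sim$genome[[1]])
  for (off in c(-1L, 1L, 2L)) {
    cnt <- trinuc_counts(calls, sim$genome, offset_start = off)
    expect_identical(sum(cnt) + attr(cnt, "skipped"), nrow(calls))
    # independent scan: substring per pause, complemented by hand on -
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    tri <- vapply(seq_len(nrow(calls)), function(i) {
      p <- calls$pos0[i]
      if (calls$strand[i] == "+") {
        substr(gstr, p + off + 1L, p + off + 3L)
      } else {
        raw <- substr(gstr, p - off - 2L + 1L, p - off + 1L)
        paste(rev(comp[strsplit(raw, "")[[1]]]), collapse = "")
      }
    }, character(1))
    brute <- table(factor(tri, levels = names(cnt)))
    expect_identical(as.integer(brute), as.integer(cnt))
  }
})

test_that("preference ratios follow the stated pseudocount arithmetic", {
  cfg <- sim_config(seed = 41, n_units = 8)
  sim <- simulate_netseq(cfg)
  calls <- call_pauses(sim$coverage, sim$units)
  # identical sets: every defined log2 is exactly 0
  tb <- preference_table(calls, calls, sim$genome, pseudocount = 1)
  expect_true(all(tb$log2 == 0))

  # closed forms on constructed counts: 8 vs 4 at pseudocount 0 -> log2 = 1
  g <- mini_genome(chr1 = paste0(strrep("A", 3), strrep("TGA", 12),
                                 strrep("A", 3)))
  u <- one_unit(tu_start = 0L, tu_end = 2L, utr3_len = 37L, chrom = "chr1",
                seqlengths = genome_seqlengths(g))
  # pauses on the G of each TGA triplet (genomic 4, 7, ... = relative 2, 5, ...)
  real <- pause_df(u, as.integer(2 + 3 * (0:7)))       # 8 TGA contexts
  shuf <- pause_df(u, as.integer(2 + 3 * (8:11)), provenance = "shuffled")
  t0 <- preference_table(real, shuf, g, pseudocount = 0)
  expect_equal(t0$ratio[t0$trinuc == "TGA"], 2)
  expect_equal(t0$log2[t0$trinuc == "TGA"], 1)
  expect_false(all(t0$defined))   # 0/0 cells are flagged, not dropped

  # real 0, shuffled 7, pseudocount 1 -> ratio 1/8, log2 -3
  shuf7 <- pause_df(u, as.integer(2 + 3 * (0:6)), provenance = "shuffled")
  empty_real <- pause_df(u, 0L)   # AAT context, not TGA
  t1 <- preference_table(empty_real, shuf7, g, pseudocount = 1)
  expect_equal(t1$ratio[t1$trinuc == "TGA"], 1 / 8)
  expect_equal(t1$log2[t1$trinuc == "TGA"], -3)
})

test_that("region delta subtracts UTR from body ratios", {
  cfg <- sim_config(seed = 43, n_units = 8)
  sim <- simulate_netseq(cfg)
  calls <- call_pauses(sim$coverage, sim$units)
  shuf <- shuffle_pauses(calls, sim$units, seed = 2)
  body <- preference_table(calls[calls$region == "body", ],
                           shuf[shuf$region == "body", ], sim$genome)
  utr <- preference_table(calls[calls$region == "utr3", ],
                          shuf[shuf$region == "utr3", ], sim$genome)
  d <- region_delta(body, utr)
  expect_equal(d$delta, body$ratio - utr$ratio)
  expect_equal(region_delta(body, body)$delta, rep(0, 64))
  b2 <- preference_table(calls, shuf, sim$genome, offset_start = 1L)
  expect_error(region_delta(body, b2), "offsets")
})

test_that("preference correlation matrices are symmetric, unit-diagonal, and
           scale-invariant; shuffled-vs-shuffled tables show no strong preferences", {
  cfg <- sim_config(seed = 47, n_units = 80, pause_rate = 30)
  sim <- simulate_netseq(cfg)
  calls <- call_pauses(sim$coverage, sim$units)
  s1 <- shuffle_pauses(calls, sim$units, seed = 101)
  s2 <- shuffle_pauses(calls, sim$units, seed = 202)
  s3 <- shuffle_pauses(calls, sim$units, seed = 303)
  t_real <- preference_table(calls, s1, sim$genome)
  m <- preference_correlation_matrix(list(a = t_real, b = t_real))
  expect_equal(unname(m), matrix(1, 2, 2))

  scaled <- t_real; scaled$ratio <- 2 * scaled$ratio
  m2 <- preference_correlation_matrix(list(t_real, scaled))
  expect_equal(m2[1, 2], 1)

  # hand Pearson on the 64 ratio vectors
  t_s12 <- preference_table(s1, s2, sim$genome)
  t_s23 <- preference_table(s2, s3, sim$genome)
  m3 <- preference_correlation_matrix(list(t_s12, t_s23))
  x <- t_s12$ratio; y <- t_s23$ratio
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(m3[1, 2], hand, tolerance = 1e-12)

  # null sanity: two shuffled sets show no strong enrichment at trinucleotides
  # with decent counts
  null_tb <- preference_table(s1, s2, sim$genome)
  well <- null_tb$shuffled >= 50
  expect_true(any(well))
  expect_true(all(abs(null_tb$log2[well]) <= 1))
})
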