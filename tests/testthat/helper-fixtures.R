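# small fixture builders shared across test files

# genome from literal chromosome strings
mini_genome <- function(...) {
  Biostrings::DNAStringSet(unlist(list(...)))
}

# one unit spanning [tu_start, tu_end) with a 3' UTR window
one_unit <- function(strand = "+", tu_start = 0L, tu_end = 1000L,
                     utr3_len = 400L, chrom = "chr1", id = "g1",
                     seqlengths = NULL) {
  make_units(unit_id = id, chrom = chrom, strand = strand,
             tu_start = tu_start, tu_end = tu_end, utr3_len = utr3_len,
             seqlengths = seqlengths)
}

# coverage track with counts written over a unit's analysis range
track_with_counts <- function(unit, counts, seqlengths) {
  tr <- coverage_track(seqlengths)
  coverage_set(tr, unit$chrom, unit$strand,
               seq.int(unit$range_start, unit$range_end - 1L), counts)
}

# pause-set data.frame from relative positions of one unit
pause_df <- function(unit, rel_pos, count = 10L, provenance = "real") {
  n <- length(rel_pos)
  data.frame(unit_id = rep(unit$unit_id, n), chrom = rep(unit$chrom, n),
             strand = rep(unit$strand, n),
             pos0 = as.integer(rel_to_genomic(rel_pos, unit$strand,
                                              unit$stop_codon_ref)),
             rel_pos = as.integer(rel_pos), count = rep_len(count, n),
             local_mean = rep(NA_real_, n), local_sd = rep(NA_real_, n),
             region = ifelse(rel_pos >= 0 & rel_pos < unit$utr3_len, "utr3",
                             ifelse(rel_pos < 0, "body", "downstream")),
             provenance = rep_len(provenance, n), stringsAsFactors = FALSE)
}

# poly(A) profile data.frame from relative positions of one unit
polya_df <- function(unit, rel_pos, count = 1L) {
  data.frame(unit_id = unit$unit_id, chrom = unit$chrom, strand = unit$strand,
             pos0 = as.integer(rel_to_genomic(rel_pos, unit$strand,
                                              unit$stop_codon_ref)),
             rel_pos = as.integer(rel_pos), count = count,
             stringsAsFactors = FALSE)
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
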