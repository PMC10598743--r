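#' Simulation configuration
#'
#' Bundles all parameters of the synthetic-data generator. Every simulator is
#' a pure function of `(config, seed)`: the same configuration reproduces
#' bit-identical output. Background NET-seq coverage is drawn i.i.d. per
#' nucleotide from a negative binomial parameterized by mean and size
#' (`size -> Inf` recovers the Poisson limit); rare planted pauses override
#' the background with `pause_fold` times the background mean.
#'
#' @param seed Integer seed; sub-streams used by the individual simulators are
#'   derived from it by fixed offsets.
#' @param n_units Number of transcription units.
#' @param unit_len Gene-body length in nt.
#' @param utr3_len 3' UTR window length in nt.
#' @param nb_mean Background mean, reads/nt.
#' @param nb_dispersion NB size parameter (larger = closer to Poisson).
#' @param pause_rate Planted pauses per kb of transcription unit.
#' @param pause_fold Planted pause count as a multiple of `nb_mean`
#'   (must exceed 1).
#' @param polya_coupling `"coupled"` (each 3' UTR pause spawns a poly(A) site
#'   a short distance upstream) or `"uniform"` (sites placed uniformly over
#'   the window).
#' @param coupling_offset_range Integer interval of upstream offsets (nt)
#'   used in coupled mode.
#' @param polya_sites_per_unit Expected sites per unit in uniform mode.
#' @param polya_mean_reads Mean reads per poly(A) site (counts are
#'   `1 + Poisson(polya_mean_reads - 1)`).
#' @param tail_extra_mean Mean number of poly(A)-tail Ts a genuine 3'READS
#'   read carries beyond the downstream genomic A-run (draws are
#'   `1 + Poisson(tail_extra_mean - 1)`, so always >= 1).
#' @param internal_priming_frac Fraction of 3'READS reads anchored inside
#'   genomic A-runs with all their 5' Ts genomically templated
#'   (internal-priming artifacts).
#' @param feature_snr Named numeric vector of per-category signal-to-noise
#'   ratios for the genomic feature tracks.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_units = 50L,
                       unit_len = 1000L,
                       utr3_len = 400L,
                       nb_mean = 4,
                       nb_dispersion = 10,
                       pause_rate = 5,
                       pause_fold = 20,
                       polya_coupling = c("coupled", "uniform"),
                       coupling_offset_range = c(5L, 45L),
                       polya_sites_per_unit = 3,
                       polya_mean_reads = 5,
                       tail_extra_mean = 4,
                       internal_priming_frac = 0,
                       feature_snr = c(dna_shape = 2, chromatin = 2, ctd = 2)) {
  polya_coupling <- match.arg(polya_coupling)
  cfg <- list(seed = as.integer(seed), n_units = as.integer(n_units),
              unit_len = as.integer(unit_len), utr3_len = as.integer(utr3_len),
              nb_mean = nb_mean, nb_dispersion = nb_dispersion,
              pause_rate = pause_rate, pause_fold = pause_fold,
              polya_coupling = polya_coupling,
              coupling_offset_range = as.integer(coupling_offset_range),
              polya_sites_per_unit = polya_sites_per_unit,
              polya_mean_reads = polya_mean_reads,
              tail_extra_mean = tail_extra_mean,
              internal_priming_frac = internal_priming_frac,
              feature_snr = feature_snr)
  stopifnot(cfg$n_units > 0, cfg$unit_len > 0, cfg$utr3_len > 0,
            cfg$nb_mean > 0, cfg$nb_dispersion > 0, cfg$pause_rate >= 0,
            length(cfg$coupling_offset_range) == 2L,
            cfg$coupling_offset_range[1] <= cfg$coupling_offset_range[2],
            cfg$coupling_offset_range[1] >= 0,
            cfg$coupling_offset_range[2] < cfg$utr3_len,
            cfg$internal_priming_frac >= 0, cfg$internal_priming_frac <= 1,
            all(cfg$feature_snr >= 0))
  if (cfg$pause_fold <= 1)
    stop("pause_fold must exceed 1: planted pauses must rise above background")
  class(cfg) <- "sim_config"
  cfg
}

# fixed seed offsets so each simulator draws from its own stream
SEED_NETSEQ <- 0L; SEED_POLYA <- 101L; SEED_READS <- 202L; SEED_TRACKS <- 303L

#' Simulate a NET-seq experiment with planted pauses
#'
#' Generates a random genome, lays out `n_units` transcription units
#' (alternating strands) each with a `utr3_len`-nt 3' UTR window, draws
#' i.i.d. NB background coverage over every unit's analysis range on its
#' transcribed strand, and plants pauses uniformly at `pause_rate`/kb whose
#' counts are set to `round(pause_fold * nb_mean)`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genome` (`DNAStringSet`), `units`
#'   (`data.frame`), `coverage` (`CoverageTrack`) and `truth` (`data.frame` of
#'   planted pauses: `unit_id, chrom, strand, pos0, rel_pos, region, count`).
#' @export
simulate_netseq <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + SEED_NETSEQ)
  gap <- 200L
  span <- config$unit_len + config$utr3_len
  chrom <- "chrS1"
  glen <- config$n_units * (span + gap) + gap
  genome <- Biostrings::DNAStringSet(stats::setNames(
    paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE), collapse = ""),
    chrom))

  origin <- gap + (seq_len(config$n_units) - 1L) * (span + gap)
  strand <- rep(c("+", "-"), length.out = config$n_units)
  tu_start <- ifelse(strand == "+", origin, origin + config$utr3_len)
  tu_end <- ifelse(strand == "+", origin + config$unit_len, origin + span)
  units <- make_units(unit_id = sprintf("g%03d", seq_len(config$n_units)),
                      chrom = rep(chrom, config$n_units), strand = strand,
                      tu_start = tu_start, tu_end = tu_end,
                      utr3_len = config$utr3_len,
                      seqlengths = genome_seqlengths(genome))

  track <- coverage_track(genome_seqlengths(genome))
  pause_count <- as.integer(round(config$pause_fold * config$nb_mean))
  truth <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    n <- u$range_end - u$range_start
    bg <- stats::rnbinom(n, size = config$nb_dispersion, mu = config$nb_mean)
    npause <- stats::rpois(1L, config$pause_rate * n / 1000)
    if (npause > n) npause <- n
    if (npause > 0L) {
      at <- sample.int(n, npause)          # 1-based offsets into the range
      bg[at] <- pause_count
      pos0 <- u$range_start + at - 1L
      rel <- genomic_to_rel(pos0, u$strand, u$stop_codon_ref)
      truth[[i]] <- data.frame(unit_id = u$unit_id, chrom = u$chrom,
                               strand = u$strand, pos0 = pos0, rel_pos = rel,
                               region = region_of_rel(rel, u$utr3_len),
                               count = pause_count, stringsAsFactors = FALSE)
    }
    track <- coverage_set(track, u$chrom, u$strand,
                          seq.int(u$range_start, u$range_end - 1L), bg)
  }
  truth <- if (any(!vapply(truth, is.null, logical(1))))
    do.call(rbind, truth) else
    data.frame(unit_id = character(), chrom = character(), strand = character(),
               pos0 = integer(), rel_pos = integer(), region = character(),
               count = integer(), stringsAsFactors = FALSE)
  truth <- truth[order(truth$unit_id, truth$rel_pos), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = genome, units = units, coverage = track, truth = truth)
}

#' Simulate a poly(A)-site profile
#'
#' In `"coupled"` mode every planted 3' UTR pause spawns one poly(A) site at
#' `pause_rel - U(coupling_offset_range)` nt (transcript orientation); sites
#' pushed below relative position 0 are dropped with a message. In
#' `"uniform"` mode, `Poisson(polya_sites_per_unit)` sites per unit are placed
#' uniformly (without replacement) over the 3' UTR window. Site read counts
#' are `1 + Poisson(polya_mean_reads - 1)`.
#'
#' When a `genome` is supplied, sites whose own templated base is an A are
#' shifted one nucleotide upstream until they rest on a non-A base (sites
#' pushed below position 0 are dropped). This mirrors how poly(A) sites are
#' annotated in practice: tail-derived Ts on a read are indistinguishable
#' from genomically templated As, so the last *non-A* templated base defines
#' the site.
#'
#' @param units Unit `data.frame`.
#' @param truth_pauses Planted-pause `data.frame` from [simulate_netseq()]
#'   (required in coupled mode).
#' @param config A [sim_config()].
#' @param genome Optional `DNAStringSet`; enables the non-A site convention
#'   above (recommended whenever reads will be simulated from the profile).
#' @return A poly(A) profile `data.frame` with `unit_id, chrom, strand, pos0,
#'   rel_pos, count` (sites at the same nucleotide are aggregated).
#' @export
simulate_polya <- function(units, truth_pauses, config, genome = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + SEED_POLYA)
  rows <- list()
  if (config$polya_coupling == "coupled") {
    p <- truth_pauses[truth_pauses$region == "utr3", , drop = FALSE]
    if (nrow(p) == 0L)           # vacuous case: nothing to couple to
      return(data.frame(unit_id = character(), chrom = character(),
                        strand = character(), pos0 = integer(),
                        rel_pos = integer(), count = integer(),
                        stringsAsFactors = FALSE))
    offs <- seq.int(config$coupling_offset_range[1],
                    config$coupling_offset_range[2])
    off <- offs[sample.int(length(offs), nrow(p), replace = TRUE)]
    rel <- p$rel_pos - off
    drop <- rel < 0L
    if (any(drop))
      message(sum(drop), " coupled poly(A) site(s) dropped (upstream of the window)")
    p <- p[!drop, , drop = FALSE]; rel <- rel[!drop]
    if (nrow(p) > 0L) {
      stopc <- units$stop_codon_ref[match(p$unit_id, units$unit_id)]
      rows[[1L]] <- data.frame(
        unit_id = p$unit_id, chrom = p$chrom, strand = p$strand,
        pos0 = as.integer(rel_to_genomic(rel, p$strand, stopc)),
        rel_pos = rel, stringsAsFactors = FALSE)
    }
  } else {
    for (i in seq_len(nrow(units))) {
      u <- units[i, ]
      k <- stats::rpois(1L, config$polya_sites_per_unit)
      k <- min(k, u$utr3_len)
      if (k == 0L) next
      rel <- sample.int(u$utr3_len, k) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = u$unit_id, chrom = u$chrom, strand = u$strand,
        pos0 = as.integer(rel_to_genomic(rel, u$strand, u$stop_codon_ref)),
        rel_pos = rel, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(unit_id = character(), chrom = character(),
                      strand = character(), pos0 = integer(),
                      rel_pos = integer(), count = integer(),
                      stringsAsFactors = FALSE))
  prof <- do.call(rbind, rows)
  if (!is.null(genome)) {
    # non-A site convention: slide upstream off any sense-strand A
    stopc <- units$stop_codon_ref[match(prof$unit_id, units$unit_id)]
    for (i in seq_len(nrow(prof))) {
      rel <- prof$rel_pos[i]
      repeat {
        if (rel < 0L) break
        pos0 <- rel_to_genomic(rel, prof$strand[i], stopc[i])
        b <- sense_sequence(genome, prof$chrom[i], prof$strand[i], pos0, pos0 + 1L)
        if (b != "A") break
        rel <- rel - 1L
      }
      prof$rel_pos[i] <- rel
      if (rel >= 0L)
        prof$pos0[i] <- as.integer(rel_to_genomic(rel, prof$strand[i], stopc[i]))
    }
    drop <- prof$rel_pos < 0L
    if (any(drop))
      message(sum(drop), " poly(A) site(s) dropped (shifted upstream of the window)")
    prof <- prof[!drop, , drop = FALSE]
    if (nrow(prof) == 0L)
      return(data.frame(unit_id = character(), chrom = character(),
                        strand = character(), pos0 = integer(),
                        rel_pos = integer(), count = integer(),
                        stringsAsFactors = FALSE))
  }
  prof$count <- 1L + stats::rpois(nrow(prof), max(config$polya_mean_reads - 1, 0))
  # aggregate sites landing on the same nucleotide
  key <- paste(prof$chrom, prof$strand, prof$pos0)
  agg <- rowsum(prof$count, key)
  first <- !duplicated(key)
  out <- prof[first, , drop = FALSE]
  out$count <- as.integer(agg[match(paste(out$chrom, out$strand, out$pos0),
                                    rownames(agg)), 1L])
  out <- out[order(out$unit_id, out$rel_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# length of the sense-strand A-run starting immediately downstream of pos0
downstream_a_run <- function(genome, chrom, strand, pos0, max_scan = 60L) {
  len <- genome_seqlengths(genome)[[chrom]]
  if (strand == "+") {
    from <- pos0 + 1L
    if (from >= len) return(0L)
    s <- sense_sequence(genome, chrom, "+", from, min(len, from + max_scan))
  } else {
    to <- pos0            # half-open end = pos0 (positions pos0-1 downwards)
    if (to <= 0L) return(0L)
    s <- sense_sequence(genome, chrom, "-", max(0L, to - max_scan), to)
  }
  m <- regexpr("^A+", s)
  if (m == -1L) 0L else attr(m, "match.length")
}

#' Simulate raw 3'READS R1 reads
#'
#' For each poly(A)-supporting read at a site, the R1 read is `k` leading Ts
#' followed by the reverse complement of the 17 sense-strand nucleotides
#' ending at the site. Genuine reads carry `k = downstream_A_run + extra`
#' with `extra >= 1` drawn from the tail distribution, so their T-stretch
#' always exceeds the genomically encoded As. With probability
#' `internal_priming_frac` a read is instead anchored inside a genomic A-run
#' (a random unit position whose downstream sense A-run has length `r >= 1`)
#' with `k` uniform on `1..r`, emulating internal priming.
#'
#' Sites within 17 nt of the chromosome 5' edge (transcript orientation) are
#' skipped with a message.
#'
#' @param profile Poly(A) profile `data.frame` (with `count` per site).
#' @param genome `DNAStringSet`.
#' @param units Unit `data.frame` (used to place internal-priming reads).
#' @param config A [sim_config()].
#' @return A `data.frame` with columns `id` and `read`; attribute `skipped`
#'   counts sites lost to the 17-nt edge rule.
#' @export
simulate_3reads <- function(profile, genome, units, config) {
  stopifnot(inherits(config, "sim_config"), all(profile$count > 0))
  set.seed(config$seed + SEED_READS)
  seqlen <- genome_seqlengths(genome)
  reads <- character(0); ids <- character(0); skipped <- 0L

  sense17_at <- function(chrom, strand, pos0) {
    if (strand == "+") {
      if (pos0 - 16L < 0L) return(NULL)
      sense_sequence(genome, chrom, "+", pos0 - 16L, pos0 + 1L)
    } else {
      if (pos0 + 17L > seqlen[[chrom]]) return(NULL)
      sense_sequence(genome, chrom, "-", pos0, pos0 + 17L)
    }
  }
  # candidate anchors for internal priming: non-A positions followed by a
  # sense-strand genomic A-run (so the anchor survives T-trimming and is
  # removed by the downstream t_count > A_run filter, as in real data)
  ip_anchor <- function() {
    for (try in 1:500) {
      u <- units[sample.int(nrow(units), 1L), ]
      pos0 <- sample.int(u$range_end - u$range_start, 1L) + u$range_start - 1L
      b <- sense_sequence(genome, u$chrom, u$strand, pos0, pos0 + 1L)
      if (b == "A") next
      r <- downstream_a_run(genome, u$chrom, u$strand, pos0)
      if (r >= 1L) return(list(chrom = u$chrom, strand = u$strand,
                               pos0 = pos0, run = r))
    }
    stop("could not find a genomic A-run for internal priming")
  }

  for (i in seq_len(nrow(profile))) {
    site <- profile[i, ]
    for (j in seq_len(site$count)) {
      internal <- stats::runif(1) < config$internal_priming_frac
      if (internal) {
        a <- ip_anchor()
        tmpl <- sense17_at(a$chrom, a$strand, a$pos0)
        if (is.null(tmpl)) { skipped <- skipped + 1L; next }
        k <- sample.int(a$run, 1L)
      } else {
        tmpl <- sense17_at(site$chrom, site$strand, site$pos0)
        if (is.null(tmpl)) { skipped <- skipped + 1L; next }
        run <- downstream_a_run(genome, site$chrom, site$strand, site$pos0)
        k <- run + 1L + stats::rpois(1L, max(config$tail_extra_mean - 1, 0))
      }
      reads <- c(reads, paste0(strrep("T", k), revcomp_chr(tmpl)))
      ids <- c(ids, sprintf("read%06d", length(ids) + 1L))
    }
  }
  if (skipped > 0L)
    message(skipped, " read(s) skipped: site within 17 nt of the chromosome edge")
  out <- data.frame(id = ids, read = reads, stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Write simulated reads as FASTQ
#'
#' Qualities are constant `I` (unused downstream).
#'
#' @param reads `data.frame` with `id` and `read` columns.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(reads$read, reads$id))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(x))))
  invisible(path)
}

#' Simulate per-position genomic feature tracks
#'
#' Each named category gets one genome-wide, strand-agnostic numeric track:
#' standard Gaussian noise plus `snr` times a smoothed indicator of the
#' planted pause positions (triangular kernel `0.5, 1, 0.5`). `snr = 0` gives
#' pure noise.
#'
#' @param truth_pauses Planted-pause `data.frame`.
#' @param units Unit `data.frame` (unused beyond validation; kept for a
#'   uniform simulator signature).
#' @param config A [sim_config()]; `config$feature_snr` names the categories.
#' @param seqlengths Chromosome lengths (or `DNAStringSet`).
#' @return Named list: category -> list(chrom -> numeric vector).
#' @export
simulate_feature_tracks <- function(truth_pauses, units, config, seqlengths) {
  stopifnot(inherits(config, "sim_config"))
  seqlengths <- genome_seqlengths(seqlengths)
  set.seed(config$seed + SEED_TRACKS)
  kern <- c(0.5, 1, 0.5)
  ind <- lapply(seqlengths, function(n) numeric(n))
  for (i in seq_len(nrow(truth_pauses))) {
    ch <- truth_pauses$chrom[i]; p <- truth_pauses$pos0[i] + 1L
    at <- p + (-1:1)
    ok <- at >= 1L & at <= seqlengths[[ch]]
    ind[[ch]][at[ok]] <- pmax(ind[[ch]][at[ok]], kern[ok])
  }
  out <- list()
  for (cat in names(config$feature_snr)) {
    snr <- config$feature_snr[[cat]]
    out[[cat]] <- lapply(names(seqlengths), function(ch)
      stats::rnorm(seqlengths[[ch]]) + snr * ind[[ch]])
    names(out[[cat]]) <- names(seqlengths)
  }
  out
}

#' Write planted truth to TSV
#'
#' @param truth_pauses Planted-pause `data.frame`.
#' @param polya Poly(A) profile `data.frame` (or `NULL`).
#' @param path Output path; columns `unit_id, rel_pos, kind`.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth_pauses, polya = NULL, path) {
  df <- data.frame(unit_id = truth_pauses$unit_id,
                   rel_pos = truth_pauses$rel_pos, kind = "pause",
                   stringsAsFactors = FALSE)
  if (!is.null(polya) && nrow(polya) > 0L)
    df <- rbind(df, data.frame(unit_id = polya$unit_id,
                               rel_pos = polya$rel_pos, kind = "polya",
                               stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
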