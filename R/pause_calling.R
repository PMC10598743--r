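#' Pause-calling parameters
#'
#' Defaults follow the standard NET-seq pause definition: a pause is a
#' nucleotide with at least `min_pause_reads` reads whose count exceeds the
#' local mean by more than `z_threshold` standard deviations, where mean and
#' sd come from a negative-binomial (method-of-moments) fit to the
#' surrounding `2 * local_halfwidth` nucleotides, and calling is restricted
#' to transcription units with at least `min_gene_coverage` reads per
#' nucleotide.
#'
#' @param min_gene_coverage Minimum unit-level mean coverage (reads/nt).
#' @param local_halfwidth Half-width of the local background window in nt
#'   (100 = a 200-nt surround).
#' @param z_threshold Number of standard deviations above the local mean.
#' @param min_pause_reads Minimum read count at a called pause.
#' @return A `pause_params` list.
#' @export
pause_params <- function(min_gene_coverage = 2, local_halfwidth = 100L,
                         z_threshold = 3, min_pause_reads = 2L) {
  p <- list(min_gene_coverage = min_gene_coverage,
            local_halfwidth = as.integer(local_halfwidth),
            z_threshold = z_threshold,
            min_pause_reads = as.integer(min_pause_reads))
  stopifnot(p$local_halfwidth >= 10L, p$z_threshold > 0,
            p$min_gene_coverage >= 0, p$min_pause_reads >= 0)
  class(p) <- "pause_params"
  p
}

# minimum combined flank (nt, focal excluded) for a position to be callable
MIN_LOCAL_WINDOW <- 50L

unit_counts <- function(track, u) {
  coverage_at(track, u$chrom, u$strand, seq.int(u$range_start, u$range_end - 1L))
}

#' Filter transcription units by coverage
#'
#' A unit passes when its total read count over the analysis range (unit
#' interval plus 3' UTR window) divided by the range length is at least
#' `min_gene_coverage` (boundary inclusive).
#'
#' @param track A `CoverageTrack`.
#' @param units Unit `data.frame`.
#' @param params A [pause_params()].
#' @return The subset of `units` passing the threshold.
#' @export
filter_units_by_coverage <- function(track, units, params = pause_params()) {
  if (nrow(units) == 0L) stop("empty unit list")
  mean_cov <- vapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    sum(unit_counts(track, u)) / (u$range_end - u$range_start)
  }, numeric(1))
  units[mean_cov >= params$min_gene_coverage, , drop = FALSE]
}

#' Local negative-binomial background at one position
#'
#' Method-of-moments NB fit on the window of up to `local_halfwidth` nt on
#' each side of `focal`, excluding the focal nucleotide itself. The fitted
#' variance is floored at the mean (an NB requires variance >= mean; without
#' the floor, zero-variance windows would make every nucleotide a pause), so
#' `sd = sqrt(max(sample variance, mean))`.
#'
#' @param counts Integer vector of per-nucleotide counts for one unit.
#' @param focal 1-based index of the focal position within `counts`.
#' @param params A [pause_params()].
#' @return List with `mean`, `sd`, `n_window` (window size, focal excluded)
#'   and `callable` (window at least 50 nt).
#' @export
fit_local_background <- function(counts, focal, params = pause_params()) {
  n <- length(counts)
  stopifnot(focal >= 1L, focal <= n)
  hw <- params$local_halfwidth
  w <- counts[setdiff(seq.int(max(1L, focal - hw), min(n, focal + hw)), focal)]
  m <- length(w)
  if (m == 0L) return(list(mean = 0, sd = 0, n_window = 0L, callable = FALSE))
  mu <- mean(w)
  v <- if (m > 1L) stats::var(w) else 0
  v <- max(v, mu)           # Poisson floor
  list(mean = mu, sd = sqrt(v), n_window = m, callable = m >= MIN_LOCAL_WINDOW)
}

# vectorized rolling background over a whole unit (focal excluded),
# identical to fit_local_background() position by position
rolling_background <- function(x, hw) {
  n <- length(x)
  cs <- c(0, cumsum(as.numeric(x)))      # cs[k + 1] = sum of x[1..k]
  cs2 <- c(0, cumsum(as.numeric(x)^2))
  i <- seq_len(n)
  lo <- pmax(1L, i - hw); hi <- pmin(n, i + hw)
  S <- cs[hi + 1L] - cs[lo] - x
  S2 <- cs2[hi + 1L] - cs2[lo] - x^2
  m <- hi - lo                       # window size excluding focal
  mu <- ifelse(m > 0L, S / m, 0)
  v <- ifelse(m > 1L, (S2 - S^2 / pmax(m, 1L)) / pmax(m - 1L, 1L), 0)
  v <- pmax(v, mu)
  list(mean = mu, sd = sqrt(v), n_window = m)
}

#' Call Pol II pauses
#'
#' A nucleotide is called a pause when its read count is at least
#' `min_pause_reads` and strictly exceeds `mean + z_threshold * sd` of its
#' local background ([fit_local_background()]). Strict inequality makes
#' perfectly uniform coverage non-pausing even at zero variance. Positions
#' with less than 50 nt of combined flanking context are not callable.
#' Replicate tracks should be summed (`track1 + track2`) before calling.
#'
#' @param track A `CoverageTrack` (replicates combined).
#' @param units Unit `data.frame`.
#' @param params A [pause_params()].
#' @param filter_units Apply [filter_units_by_coverage()] first
#'   (default `TRUE`).
#' @return A pause set: `data.frame` with columns `unit_id, chrom, strand,
#'   pos0, rel_pos, count, local_mean, local_sd, region, provenance`
#'   (`region` is `"utr3"` for relative positions in `[0, utr3_len)`, else
#'   `"body"`; `provenance` is `"real"`).
#' @export
call_pauses <- function(track, units, params = pause_params(),
                        filter_units = TRUE) {
  if (filter_units) units <- filter_units_by_coverage(track, units, params)
  res <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    x <- unit_counts(track, u)
    bg <- rolling_background(x, params$local_halfwidth)
    hit <- x >= params$min_pause_reads &
      x > bg$mean + params$z_threshold * bg$sd &
      bg$n_window >= MIN_LOCAL_WINDOW
    if (!any(hit)) next
    pos0 <- seq.int(u$range_start, u$range_end - 1L)[hit]
    rel <- genomic_to_rel(pos0, u$strand, u$stop_codon_ref)
    res[[i]] <- data.frame(unit_id = u$unit_id, chrom = u$chrom,
                           strand = u$strand, pos0 = pos0, rel_pos = rel,
                           count = x[hit], local_mean = bg$mean[hit],
                           local_sd = bg$sd[hit],
                           region = region_of_rel(rel, u$utr3_len),
                           provenance = "real", stringsAsFactors = FALSE)
  }
  out <- if (any(!vapply(res, is.null, logical(1)))) do.call(rbind, res) else
    data.frame(unit_id = character(), chrom = character(), strand = character(),
               pos0 = integer(), rel_pos = integer(), count = integer(),
               local_mean = numeric(), local_sd = numeric(),
               region = character(), provenance = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$unit_id, out$rel_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate shuffled control pauses
#'
#' For each unit (and, when `stratify_by_region = TRUE`, each region within
#' the unit) the same number of positions as in the source pause set is drawn
#' uniformly without replacement from that unit/region; read counts are
#' copied from the source records so downstream read-weighted statistics stay
#' comparable. If a region holds fewer positions than pauses, sampling falls
#' back to replacement with a warning.
#'
#' @param pauses A pause set `data.frame`.
#' @param units Unit `data.frame`.
#' @param seed Mandatory integer seed.
#' @param stratify_by_region Keep shuffled pauses in the source pause's
#'   region (`body`/`utr3`; default `TRUE`).
#' @return A pause set with `provenance = "shuffled"` and attribute `seed`.
#' @export
shuffle_pauses <- function(pauses, units, seed, stratify_by_region = TRUE) {
  if (nrow(pauses) == 0L) stop("cannot shuffle an empty pause set")
  stopifnot(!missing(seed))
  set.seed(as.integer(seed))
  res <- list()
  groups <- if (stratify_by_region)
    split(pauses, list(pauses$unit_id, pauses$region), drop = TRUE)
  else split(pauses, pauses$unit_id)
  for (g in groups) {
    u <- unit_row(units, g$unit_id[1])
    rel_all <- genomic_to_rel(seq.int(u$range_start, u$range_end - 1L),
                              u$strand, u$stop_codon_ref)
    pool <- if (stratify_by_region)
      rel_all[region_of_rel(rel_all, u$utr3_len) == g$region[1]] else rel_all
    k <- nrow(g)
    if (length(pool) < k) {
      warning("region shorter than pause count in unit ", u$unit_id,
              "; sampling with replacement")
      rel <- pool[sample.int(length(pool), k, replace = TRUE)]
    } else rel <- pool[sample.int(length(pool), k)]
    res[[length(res) + 1L]] <- data.frame(
      unit_id = u$unit_id, chrom = u$chrom, strand = u$strand,
      pos0 = as.integer(rel_to_genomic(rel, u$strand, u$stop_codon_ref)),
      rel_pos = rel, count = g$count, local_mean = NA_real_,
      local_sd = NA_real_, region = region_of_rel(rel, u$utr3_len),
      provenance = "shuffled", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$unit_id, out$rel_pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Draw uniform candidate positions within 3' UTR windows
#'
#' Samples `n` positions uniformly without replacement from the pooled 3' UTR
#' windows of `units`, returning them as a shuffled-provenance pause set
#' (count 1). Useful for building statistically identical null sets, e.g.
#' shuffled-vs-shuffled classifier baselines.
#'
#' @param units Unit `data.frame`.
#' @param n Number of positions.
#' @param seed Integer seed.
#' @return A pause set `data.frame` with `provenance = "shuffled"`.
#' @export
random_pause_set <- function(units, n, seed) {
  set.seed(as.integer(seed))
  pool <- do.call(rbind, lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    rel <- seq.int(0L, u$utr3_len - 1L)
    data.frame(unit_id = u$unit_id, chrom = u$chrom, strand = u$strand,
               pos0 = as.integer(rel_to_genomic(rel, u$strand, u$stop_codon_ref)),
               rel_pos = rel, stringsAsFactors = FALSE)
  }))
  if (n > nrow(pool)) stop("n exceeds the number of available UTR positions")
  out <- pool[sample.int(nrow(pool), n), , drop = FALSE]
  out$count <- 1L; out$local_mean <- NA_real_; out$local_sd <- NA_real_
  out$region <- "utr3"; out$provenance <- "shuffled"
  out <- out[order(out$unit_id, out$rel_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage of maximal overlap between two pause sets
#'
#' `100 * |A intersect B| / min(|A|, |B|)`, with positions identified by
#' (chromosome, strand, genomic position). The smaller set is the
#' denominator, so identical sets give 100 regardless of size difference.
#'
#' @param set_a,set_b Pause sets.
#' @return Percentage in `[0, 100]`.
#' @export
pause_overlap <- function(set_a, set_b) {
  if (nrow(set_a) == 0L || nrow(set_b) == 0L)
    stop("pause overlap undefined for empty sets")
  ka <- unique(paste(set_a$chrom, set_a$strand, set_a$pos0))
  kb <- unique(paste(set_b$chrom, set_b$strand, set_b$pos0))
  100 * length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Replicate correlation at gene or nucleotide level
#'
#' Gene level: Pearson correlation of per-unit RPKM
#' (`reads * 1e9 / (range length * total mapped reads)`). Nucleotide level:
#' Pearson correlation of raw per-nucleotide counts over all positions of
#' units whose mean coverage strictly exceeds `min_cov` in both tracks.
#'
#' @param track_a,track_b `CoverageTrack` replicates.
#' @param units Unit `data.frame`.
#' @param level `"gene"` or `"nucleotide"`.
#' @param min_cov Coverage threshold for the nucleotide level (default 2,
#'   strict).
#' @return Pearson correlation coefficient.
#' @export
replicate_correlations <- function(track_a, track_b, units,
                                   level = c("gene", "nucleotide"),
                                   min_cov = 2) {
  level <- match.arg(level)
  if (level == "gene") {
    ta <- total_reads(track_a); tb <- total_reads(track_b)
    reads <- vapply(seq_len(nrow(units)), function(i) {
      u <- units[i, ]
      c(sum(unit_counts(track_a, u)), sum(unit_counts(track_b, u)))
    }, numeric(2))
    len <- units$range_end - units$range_start
    a <- reads[1, ] * 1e9 / (len * ta)
    b <- reads[2, ] * 1e9 / (len * tb)
  } else {
    a <- numeric(0); b <- numeric(0)
    for (i in seq_len(nrow(units))) {
      u <- units[i, ]
      xa <- unit_counts(track_a, u); xb <- unit_counts(track_b, u)
      if (mean(xa) > min_cov && mean(xb) > min_cov) {
        a <- c(a, xa); b <- c(b, xb)
      }
    }
  }
  if (length(a) < 3L) stop("fewer than 3 paired observations")
  stats::cor(a, b)
}

#' Per-unit pause density in the 3' UTR
#'
#' Number of pauses in the 3' UTR window per kilobase:
#' `1000 * n_utr3_pauses / utr3_len`, reported for every unit (0 when a unit
#' has no UTR pauses).
#'
#' @param pauses A pause set.
#' @param units Unit `data.frame`.
#' @return Named numeric vector, one density per unit.
#' @export
pause_density <- function(pauses, units) {
  p <- pauses[pauses$region == "utr3", , drop = FALSE]
  n <- table(factor(p$unit_id, levels = units$unit_id))
  stats::setNames(1000 * as.numeric(n) / units$utr3_len, units$unit_id)
}
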