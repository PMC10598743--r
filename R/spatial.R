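#' Read-weighted average position
#'
#' `sum(position * reads) / sum(reads)` over the records of one unit; applies
#' identically to pause sets and poly(A) profiles. Positions are
#' transcript-relative (nt downstream of the stop codon).
#'
#' @param positions Vector of positions.
#' @param weights Read counts (same length).
#' @return Weighted average position (nt).
#' @export
weighted_average_position <- function(positions, weights) {
  stopifnot(length(positions) == length(weights), all(weights >= 0))
  if (length(positions) == 0L || sum(weights) == 0)
    stop("weighted average undefined: zero total reads")
  sum(positions * weights) / sum(weights)
}

#' Per-unit weighted average positions
#'
#' @param events `data.frame` with `unit_id`, `rel_pos` and `count` columns,
#'   restricted to the region of interest beforehand (e.g. `region ==
#'   "utr3"`).
#' @return Named numeric vector of weighted averages per unit.
#' @export
weighted_average_by_unit <- function(events) {
  vapply(split(events, events$unit_id), function(g)
    weighted_average_position(g$rel_pos, g$count), numeric(1))
}

#' Metagene profile of event-associated nucleotides
#'
#' For each transcript-relative position `p` in `[0, utr3_len)`, the
#' percentage of units carrying at least one event (pause or poly(A) site) at
#' `p`. Events are unweighted indicators: a position with >= 1 read counts
#' once.
#'
#' @param events `data.frame` with `unit_id` and `rel_pos`.
#' @param units Unit `data.frame` (the denominator is `nrow(units)`).
#' @param utr3_len Window length (default from `units`).
#' @return Numeric vector of length `utr3_len`, values in `[0, 100]`;
#'   element `i` is relative position `i - 1`.
#' @export
metagene_profile <- function(events, units, utr3_len = NULL) {
  if (nrow(units) == 0L) stop("no units")
  if (is.null(utr3_len)) utr3_len <- units$utr3_len[1]
  e <- events[!is.na(events$rel_pos) & events$rel_pos >= 0L &
                events$rel_pos < utr3_len &
                events$unit_id %in% units$unit_id, , drop = FALSE]
  e <- e[!duplicated(paste(e$unit_id, e$rel_pos)), , drop = FALSE]
  100 * tabulate(e$rel_pos + 1L, utr3_len) / nrow(units)
}

UPSTREAM_BINS <- seq(0L, 50L, by = 10L)

#' Poly(A)-site counts in 10-nt bins upstream of each pause
#'
#' For every pause, counts poly(A) sites at distance `d = pause_rel -
#' site_rel` (transcript orientation, same unit) falling in the half-open
#' bins `[0,10), [10,20), [20,30), [30,40), [40,50)`. `d = 0` (co-located)
#' lands in the first bin; `d >= 50` and downstream sites (`d < 0`) are
#' ignored.
#'
#' @param pauses Pause set with `unit_id` and `rel_pos`.
#' @param polya Poly(A) profile with `unit_id` and `rel_pos`.
#' @return Integer matrix, one row per pause (rows follow `pauses`), columns
#'   `[0,10)` ... `[40,50)`.
#' @export
upstream_bin_counts <- function(pauses, polya) {
  nb <- length(UPSTREAM_BINS) - 1L
  m <- matrix(0L, nrow(pauses), nb,
              dimnames = list(NULL, paste0("[", UPSTREAM_BINS[-(nb + 1L)], ",",
                                           UPSTREAM_BINS[-1L], ")")))
  sites <- split(polya$rel_pos[!is.na(polya$unit_id)],
                 polya$unit_id[!is.na(polya$unit_id)])
  for (i in seq_len(nrow(pauses))) {
    s <- sites[[pauses$unit_id[i]]]
    if (is.null(s)) next
    d <- pauses$rel_pos[i] - s
    d <- d[d >= 0L & d < 50L]
    if (length(d)) m[i, ] <- m[i, ] + tabulate(d %/% 10L + 1L, nb)
  }
  m
}

ks_statistic <- function(a, b) {
  support <- sort(unique(c(a, b)))
  fa <- cumsum(tabulate(match(a, support), length(support))) / length(a)
  fb <- cumsum(tabulate(match(b, support), length(support))) / length(b)
  max(abs(fa - fb))
}

#' Two-sample KS test of real vs shuffled per-pause counts
#'
#' Compares the distributions of per-pause poly(A)-site counts (one upstream
#' bin, or the pooled 0-50 nt window) between real and shuffled pauses.
#' `method = "asymptotic"` uses [stats::ks.test()]; with the heavily tied
#' small-integer counts its p-value is conservative. `method =
#' "permutation"` computes a Monte-Carlo permutation p-value for the same D
#' statistic, which is calibrated under exchangeability regardless of ties.
#'
#' @param real_counts,shuffled_counts Numeric vectors of per-pause counts
#'   (length >= 10 each).
#' @param method `"asymptotic"` or `"permutation"`.
#' @param B Number of permutations (permutation method).
#' @param seed Optional seed for the permutation draw.
#' @return List with `statistic` (D) and `p.value`.
#' @export
ks_real_vs_shuffled <- function(real_counts, shuffled_counts,
                                method = c("asymptotic", "permutation"),
                                B = 1999L, seed = NULL) {
  method <- match.arg(method)
  if (length(real_counts) < 10L || length(shuffled_counts) < 10L)
    stop("KS comparison needs at least 10 pauses per set")
  if (method == "asymptotic") {
    kt <- suppressWarnings(stats::ks.test(real_counts, shuffled_counts))
    return(list(statistic = unname(kt$statistic), p.value = kt$p.value))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  d_obs <- ks_statistic(real_counts, shuffled_counts)
  pooled <- c(real_counts, shuffled_counts)
  support <- sort(unique(pooled))
  codes <- match(pooled, support)
  na <- length(real_counts); n <- length(pooled); ns <- length(support)
  tot <- tabulate(codes, ns)
  exceed <- 0L
  for (b in seq_len(B)) {
    ta <- tabulate(codes[sample.int(n, na)], ns)
    d <- max(abs(cumsum(ta) / na - cumsum(tot - ta) / (n - na)))
    if (d >= d_obs - 1e-12) exceed <- exceed + 1L
  }
  list(statistic = d_obs, p.value = (1L + exceed) / (B + 1L))
}

nearest_upstream_distance <- function(pauses, polya) {
  sites <- split(polya$rel_pos[!is.na(polya$unit_id)],
                 polya$unit_id[!is.na(polya$unit_id)])
  vapply(seq_len(nrow(pauses)), function(i) {
    s <- sites[[pauses$unit_id[i]]]
    if (is.null(s)) return(NA_real_)
    d <- pauses$rel_pos[i] - s
    d <- d[d >= 0L]
    if (length(d)) min(d) else NA_real_
  }, numeric(1))
}

#' Real/shuffled ratio of distances to the nearest upstream poly(A) site
#'
#' Mean distance from each real pause to its nearest upstream poly(A) site
#' (same unit, transcript orientation, `d >= 0`), divided by the same mean
#' over shuffled pauses. Pauses with no upstream site in the window are
#' excluded from their own set (applied symmetrically). The standard error
#' is propagated from the two means by the delta method.
#'
#' @param real_pauses,shuffled_pauses Pause sets with `unit_id`, `rel_pos`.
#' @param polya Poly(A) profile with `unit_id`, `rel_pos`.
#' @return List with `ratio`, `se`, `mean_real`, `mean_shuffled`, `n_real`,
#'   `n_shuffled`.
#' @export
distance_ratio <- function(real_pauses, shuffled_pauses, polya) {
  dr <- nearest_upstream_distance(real_pauses, polya)
  ds <- nearest_upstream_distance(shuffled_pauses, polya)
  dr <- dr[!is.na(dr)]; ds <- ds[!is.na(ds)]
  if (length(dr) == 0L || length(ds) == 0L)
    stop("no pauses with an upstream poly(A) site")
  mr <- mean(dr); ms <- mean(ds)
  vr <- if (length(dr) > 1L) stats::var(dr) / length(dr) else 0
  vs <- if (length(ds) > 1L) stats::var(ds) / length(ds) else 0
  ratio <- mr / ms
  se <- ratio * sqrt(vr / mr^2 + vs / ms^2)
  list(ratio = ratio, se = se, mean_real = mr, mean_shuffled = ms,
       n_real = length(dr), n_shuffled = length(ds))
}
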