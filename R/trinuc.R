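ALL_TRINUCS <- {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# sense-strand context string for each pause at offsets from..to (inclusive)
sense_context <- function(pauses, genome, from, to) {
  chrs <- lapply(as.character(genome), identity)
  lens <- genome_seqlengths(genome)
  width <- to - from + 1L
  out <- rep(NA_character_, nrow(pauses))
  plus <- pauses$strand == "+"
  # genomic interval covering the context, [lo, hi] 0-based inclusive
  lo <- ifelse(plus, pauses$pos0 + from, pauses$pos0 - to)
  hi <- lo + width - 1L
  ok <- lo >= 0L & hi < lens[pauses$chrom]
  if (any(ok & plus)) {
    i <- which(ok & plus)
    out[i] <- substring(unlist(chrs[pauses$chrom[i]], use.names = FALSE),
                        lo[i] + 1L, hi[i] + 1L)
  }
  if (any(ok & !plus)) {
    i <- which(ok & !plus)
    out[i] <- revcomp_chr(substring(unlist(chrs[pauses$chrom[i]],
                                           use.names = FALSE),
                                    lo[i] + 1L, hi[i] + 1L))
  }
  out
}

#' Trinucleotide counts around pause sites
#'
#' Counts the sense-strand trinucleotide at offsets
#' `(offset_start, offset_start + 1, offset_start + 2)` relative to each
#' pause (offset 0 = the pause nucleotide; the classic pause trinucleotide
#' uses `offset_start = -1`, i.e. positions -1, 0, +1). Contexts are always
#' read in transcription direction: minus-strand pauses use the reverse
#' complement of the top strand. Pauses whose context contains `N` or runs
#' off the chromosome are skipped and reported in the `skipped` attribute.
#'
#' @param pauses A pause set `data.frame`.
#' @param genome `DNAStringSet`.
#' @param offset_start First offset of the trinucleotide, in `-4..2`.
#' @return Named integer vector of 64 trinucleotide counts (attribute
#'   `skipped` = number of excluded pauses, attribute `offset_start`).
#' @export
trinuc_counts <- function(pauses, genome, offset_start = -1L) {
  offset_start <- as.integer(offset_start)
  if (offset_start < -4L || offset_start > 2L)
    stop("offset_start must be in -4..2")
  ctx <- sense_context(pauses, genome, offset_start, offset_start + 2L)
  valid <- !is.na(ctx) & ctx %in% ALL_TRINUCS
  counts <- table(factor(ctx[valid], levels = ALL_TRINUCS))
  out <- stats::setNames(as.integer(counts), ALL_TRINUCS)
  attr(out, "skipped") <- sum(!valid)
  attr(out, "offset_start") <- offset_start
  out
}

#' Normalized trinucleotide pause-preference table
#'
#' For every trinucleotide, the number of real pauses with that sense-strand
#' context is divided by the number of shuffled pauses with it (after adding
#' `pseudocount` to both); the log2 of this normalized preference is the
#' heat-map statistic. With `pseudocount = 0`, zero denominators give
#' non-finite values which are flagged in `defined`, not dropped.
#'
#' @param real_pauses,shuffled_pauses Pause sets over the same units.
#' @param genome `DNAStringSet`.
#' @param offset_start First offset of the trinucleotide (default -1).
#' @param pseudocount Added to numerator and denominator (default 1).
#' @return `data.frame` with columns `trinuc, real, shuffled, ratio, log2,
#'   defined`; attribute `offset_start`.
#' @export
preference_table <- function(real_pauses, shuffled_pauses, genome,
                             offset_start = -1L, pseudocount = 1) {
  if (nrow(real_pauses) == 0L || nrow(shuffled_pauses) == 0L)
    stop("both pause sets must be nonempty")
  r <- trinuc_counts(real_pauses, genome, offset_start)
  s <- trinuc_counts(shuffled_pauses, genome, offset_start)
  ratio <- (as.numeric(r) + pseudocount) / (as.numeric(s) + pseudocount)
  out <- data.frame(trinuc = ALL_TRINUCS, real = as.integer(r),
                    shuffled = as.integer(s), ratio = ratio,
                    log2 = log2(ratio), stringsAsFactors = FALSE)
  out$defined <- is.finite(out$log2)
  attr(out, "offset_start") <- as.integer(offset_start)
  out
}

#' Gene-body minus 3' UTR preference difference
#'
#' Per trinucleotide, the raw real/shuffled ratio in the 3' UTR is subtracted
#' from the ratio in the gene body; positive values mark trinucleotides more
#' favored as pause contexts in the gene body.
#'
#' @param body_table,utr_table Preference tables ([preference_table()]) at
#'   the same offsets.
#' @return `data.frame` with columns `trinuc, delta`.
#' @export
region_delta <- function(body_table, utr_table) {
  if (!identical(attr(body_table, "offset_start"),
                 attr(utr_table, "offset_start")))
    stop("preference tables computed at different offsets")
  stopifnot(identical(body_table$trinuc, utr_table$trinuc))
  data.frame(trinuc = body_table$trinuc,
             delta = body_table$ratio - utr_table$ratio,
             stringsAsFactors = FALSE)
}

#' Pearson correlation matrix of preference tables
#'
#' Correlates the 64 normalized real/shuffled ratios between conditions
#' (strains, regions). Entries undefined in either table of a pair are
#' excluded pairwise; a table with fewer than 3 defined entries is an error.
#'
#' @param tables Named list of preference tables at the same offsets.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
preference_correlation_matrix <- function(tables) {
  stopifnot(length(tables) >= 2L)
  off <- lapply(tables, attr, "offset_start")
  if (length(unique(off)) != 1L)
    stop("preference tables computed at different offsets")
  for (tb in tables)
    if (sum(tb$defined) < 3L) stop("table with fewer than 3 defined entries")
  n <- length(tables)
  nm <- names(tables)
  if (is.null(nm)) nm <- paste0("set", seq_len(n))
  m <- matrix(1, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    ok <- tables[[i]]$defined & tables[[j]]$defined
    m[i, j] <- m[j, i] <- stats::cor(tables[[i]]$ratio[ok],
                                     tables[[j]]$ratio[ok])
  }
  m
}
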