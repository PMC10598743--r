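#' Count and trim 5' T-stretches from 3'READS R1 reads
#'
#' The leading T run of each read (>= 1 T, potentially poly(A)-derived) is
#' counted and removed; reads not starting with T, and reads shorter than 17
#' nt after trimming, are discarded. The T count travels with the read for
#' the downstream internal-priming filter.
#'
#' @param reads A FASTQ path, or a `data.frame` with `id` and `read` columns
#'   (as produced by [simulate_3reads()]).
#' @return `data.frame` with columns `id, t_count, seq17` (first 17 trimmed
#'   bases); attributes `n_no_t` and `n_short` count the discarded reads.
#' @export
preprocess_3reads <- function(reads) {
  if (is.character(reads)) {
    x <- Biostrings::readDNAStringSet(reads, format = "fastq")
    reads <- data.frame(id = names(x), read = as.character(x),
                        stringsAsFactors = FALSE)
  }
  m <- regexpr("^T+", reads$read)
  t_count <- ifelse(m == 1L, attr(m, "match.length"), 0L)
  no_t <- t_count == 0L
  trimmed <- substring(reads$read, t_count + 1L)
  short <- !no_t & nchar(trimmed) < 17L
  keep <- !no_t & !short
  out <- data.frame(id = paste0(reads$id[keep], ":T", t_count[keep]),
                    t_count = as.integer(t_count[keep]),
                    seq17 = substring(trimmed[keep], 1L, 17L),
                    stringsAsFactors = FALSE)
  attr(out, "n_no_t") <- sum(no_t)
  attr(out, "n_short") <- sum(short)
  out
}

# genome-wide exact matches of constant-width patterns on the top strand;
# returns data.frame(pattern_idx, chrom, start0)
match_kmers <- function(patterns, genome) {
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(patterns))
  hits <- list()
  for (ch in names(genome)) {
    m <- Biostrings::matchPDict(pd, genome[[ch]])
    n <- S4Vectors::elementNROWS(m)
    if (sum(n) == 0L) next
    hits[[ch]] <- data.frame(pattern_idx = rep(seq_along(patterns), n),
                             chrom = ch,
                             start0 = unlist(lapply(m, IRanges::start),
                                             use.names = FALSE) - 1L,
                             stringsAsFactors = FALSE)
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(pattern_idx = integer(), chrom = character(),
               start0 = integer(), stringsAsFactors = FALSE)
}

#' Map trimmed 3'READS reads by exact unique 17-mer matching
#'
#' The 17 trimmed bases are reverse-complemented into the transcript-sense
#' 17-mer and matched exactly against both strands of the genome. Reads with
#' zero or multiple genome-wide matches are dropped (non-mapping is a value,
#' not an error). For a mapped read, `pos0` is the genomic coordinate of the
#' 3'-most templated base (transcript orientation) and `a_run` the length of
#' the maximal sense-strand A-run starting immediately downstream of it.
#'
#' @param treads Output of [preprocess_3reads()].
#' @param genome `DNAStringSet`.
#' @return `data.frame` with columns `id, t_count, chrom, strand, pos0,
#'   a_run`, one row per uniquely mapped read.
#' @export
map_3reads <- function(treads, genome) {
  if (nrow(treads) == 0L)
    return(data.frame(id = character(), t_count = integer(),
                      chrom = character(), strand = character(),
                      pos0 = integer(), a_run = integer(),
                      stringsAsFactors = FALSE))
  uniq <- unique(treads$seq17)
  sense <- revcomp_chr(uniq)
  # a sense-strand occurrence on + is a top-strand match of `sense`;
  # on - it is a top-strand match of revcomp(sense) = the read itself
  hp <- match_kmers(sense, genome)
  hm <- match_kmers(uniq, genome)
  n_hits <- tabulate(hp$pattern_idx, length(uniq)) +
    tabulate(hm$pattern_idx, length(uniq))
  res <- data.frame(seq17 = uniq, chrom = NA_character_,
                    strand = NA_character_, pos0 = NA_integer_,
                    stringsAsFactors = FALSE)
  one_p <- which(n_hits == 1L & tabulate(hp$pattern_idx, length(uniq)) == 1L)
  if (length(one_p)) {
    idx <- match(one_p, hp$pattern_idx)
    res$chrom[one_p] <- hp$chrom[idx]
    res$strand[one_p] <- "+"
    res$pos0[one_p] <- hp$start0[idx] + 16L   # 3'-most templated base
  }
  one_m <- which(n_hits == 1L & tabulate(hm$pattern_idx, length(uniq)) == 1L)
  if (length(one_m)) {
    idx <- match(one_m, hm$pattern_idx)
    res$chrom[one_m] <- hm$chrom[idx]
    res$strand[one_m] <- "-"
    res$pos0[one_m] <- hm$start0[idx]         # leftmost base = sense 3' end
  }
  j <- match(treads$seq17, res$seq17)
  out <- data.frame(id = treads$id, t_count = treads$t_count,
                    chrom = res$chrom[j], strand = res$strand[j],
                    pos0 = res$pos0[j], stringsAsFactors = FALSE)
  out <- out[!is.na(out$chrom), , drop = FALSE]
  out$a_run <- vapply(seq_len(nrow(out)), function(i)
    downstream_a_run(genome, out$chrom[i], out$strand[i], out$pos0[i]),
    integer(1))
  rownames(out) <- NULL
  out
}

#' Internal-priming retention rule
#'
#' A mapped read is retained iff its 5' T-stretch cannot be fully explained
#' by genomically encoded As: `t_count > a_run` (strict; a read whose Ts are
#' all templated is discarded).
#'
#' @param t_count Number of trimmed 5' Ts.
#' @param a_run Downstream sense-strand genomic A-run length.
#' @return Logical vector.
#' @export
polya_read_retained <- function(t_count, a_run) t_count > a_run

#' Call poly(A) sites from mapped 3'READS reads
#'
#' Applies the internal-priming filter ([polya_read_retained()]) and
#' accumulates the retained reads per (chromosome, strand, position) into a
#' poly(A) profile.
#'
#' @param mapped Output of [map_3reads()].
#' @param units Optional unit `data.frame` for 3' UTR annotation.
#' @return Poly(A) profile `data.frame` (`chrom, pos0, strand, count`, plus
#'   `unit_id`/`rel_pos` when `units` is given); attribute `retained_frac` is
#'   the fraction of mapped reads surviving the filter.
#' @export
call_polya_sites <- function(mapped, units = NULL) {
  keep <- polya_read_retained(mapped$t_count, mapped$a_run)
  kept <- mapped[keep, , drop = FALSE]
  if (nrow(kept) == 0L) {
    out <- data.frame(chrom = character(), pos0 = integer(),
                      strand = character(), count = integer(),
                      stringsAsFactors = FALSE)
  } else {
    key <- paste(kept$chrom, kept$strand, kept$pos0)
    first <- !duplicated(key)
    out <- data.frame(chrom = kept$chrom[first], pos0 = kept$pos0[first],
                      strand = kept$strand[first],
                      count = as.integer(table(key)[key[first]]),
                      stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$strand, out$pos0), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(units)) out <- annotate_polya_units(out, units)
  attr(out, "retained_frac") <-
    if (nrow(mapped)) sum(keep) / nrow(mapped) else NA_real_
  out
}
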