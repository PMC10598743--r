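#' Strand-specific single-nucleotide coverage tracks
#'
#' A `CoverageTrack` stores non-negative integer read counts (3' ends of
#' nascent RNA fragments) at every nucleotide of every chromosome, separately
#' for the two strands. Internally it holds one dense integer vector per
#' (chromosome, strand); position `p` (0-based) of chromosome `ch` on strand
#' `s` is `track[[s]][[ch]][p + 1]`.
#'
#' @param seqlengths Named integer vector of chromosome lengths.
#' @return An empty (all-zero) `CoverageTrack`.
#' @export
coverage_track <- function(seqlengths) {
  seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
  stopifnot(!is.null(names(seqlengths)), all(seqlengths > 0L))
  zero <- lapply(seqlengths, function(n) integer(n))
  structure(list(plus = zero, minus = zero, seqlengths = seqlengths),
            class = "CoverageTrack")
}

strand_slot <- function(strand) {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ifelse(strand == "+", "plus", "minus")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack:", length(x$seqlengths), "chromosome(s),",
      total_reads(x), "reads\n")
  invisible(x)
}

#' Total mapped reads in a track
#'
#' @param track A `CoverageTrack`.
#' @return Total read count summed over both strands.
#' @export
total_reads <- function(track) {
  sum(vapply(track$plus, sum, numeric(1))) +
    sum(vapply(track$minus, sum, numeric(1)))
}

#' Positionwise sum of two coverage tracks
#'
#' Used to combine biological replicates before coverage thresholding and
#' pause calling.
#'
#' @param e1,e2 `CoverageTrack` objects over the same genome.
#' @return A `CoverageTrack`.
#' @export
"+.CoverageTrack" <- function(e1, e2) {
  if (!identical(e1$seqlengths, e2$seqlengths))
    stop("tracks are defined over different genomes")
  out <- e1
  for (ch in names(e1$seqlengths)) {
    out$plus[[ch]] <- e1$plus[[ch]] + e2$plus[[ch]]
    out$minus[[ch]] <- e1$minus[[ch]] + e2$minus[[ch]]
  }
  out
}

#' Read counts at genomic positions
#'
#' @param track A `CoverageTrack`.
#' @param chrom Chromosome name (scalar).
#' @param strand `"+"` or `"-"` (scalar).
#' @param pos0 Vector of 0-based positions.
#' @return Integer vector of counts.
#' @export
coverage_at <- function(track, chrom, strand, pos0) {
  v <- track[[strand_slot(strand)]][[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  if (any(pos0 < 0L | pos0 >= length(v)))
    stop("position outside [0, ", length(v), ") on ", chrom)
  v[pos0 + 1L]
}

#' Set read counts at genomic positions
#'
#' @inheritParams coverage_at
#' @param count Integer vector of counts (recycled).
#' @return The modified `CoverageTrack`.
#' @export
coverage_set <- function(track, chrom, strand, pos0, count) {
  slot <- strand_slot(strand)
  v <- track[[slot]][[chrom]]
  if (any(pos0 < 0L | pos0 >= length(v)))
    stop("position outside [0, ", length(v), ") on ", chrom)
  v[pos0 + 1L] <- as.integer(count)
  track[[slot]][[chrom]] <- v
  track
}

import_bedgraph_strand <- function(path, seqlengths) {
  if (!is.null(path) && (!file.exists(path) || file.size(path) == 0))
    return(NULL)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) return(NULL)
  if (!all(as.character(GenomicRanges::seqnames(gr)) %in% names(seqlengths)))
    stop("bedGraph chromosome not present in genome: ", path)
  sc <- gr$score
  if (any(sc < 0)) stop("negative coverage value in ", path)
  if (any(abs(sc - round(sc)) > 1e-9))
    stop("non-integer coverage value in ", path, " (3'-end counts are integral)")
  if (!GenomicRanges::isDisjoint(gr))
    stop("overlapping intervals in bedGraph: ", path)
  if (any(GenomicRanges::end(gr) > seqlengths[as.character(GenomicRanges::seqnames(gr))]))
    stop("bedGraph interval beyond chromosome end in ", path)
  gr
}

#' Load strand-specific coverage from bedGraph files
#'
#' Expands per-interval bedGraph values to per-nucleotide integer counts, one
#' file per strand. Intervals within a file must be non-overlapping, values
#' non-negative integers. An empty (or `NULL`) file yields zero coverage on
#' that strand.
#'
#' @param bedgraph_plus,bedgraph_minus Paths to the `+` and `-` strand
#'   bedGraph files (`NULL` or empty file = no coverage).
#' @param seqlengths Named integer vector of chromosome lengths, or a
#'   `DNAStringSet` genome.
#' @return A `CoverageTrack`.
#' @export
load_coverage <- function(bedgraph_plus, bedgraph_minus, seqlengths) {
  seqlengths <- genome_seqlengths(seqlengths)
  track <- coverage_track(seqlengths)
  for (side in c("plus", "minus")) {
    path <- if (side == "plus") bedgraph_plus else bedgraph_minus
    gr <- import_bedgraph_strand(path, seqlengths)
    if (is.null(gr)) next
    for (ch in unique(as.character(GenomicRanges::seqnames(gr)))) {
      gi <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
      v <- track[[side]][[ch]]
      idx <- IRanges::IRanges(GenomicRanges::start(gi), GenomicRanges::end(gi))
      pos <- unlist(mapply(seq.int, IRanges::start(idx), IRanges::end(idx),
                           SIMPLIFY = FALSE), use.names = FALSE)
      val <- rep(as.integer(round(gi$score)), IRanges::width(idx))
      v[pos] <- v[pos] + val
      track[[side]][[ch]] <- v
    }
  }
  track
}

strand_to_bedgraph <- function(vecs, path) {
  rows <- list()
  for (ch in names(vecs)) {
    r <- rle(vecs[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths      # 0-based starts
    keep <- r$values != 0L
    if (any(keep))
      rows[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                               end = ends[keep], value = r$values[keep])
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               value = integer())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a coverage track as per-strand bedGraph files
#'
#' Zero-count runs are omitted; `load_coverage()` on the output reproduces the
#' per-nucleotide counts exactly.
#'
#' @param track A `CoverageTrack`.
#' @param bedgraph_plus,bedgraph_minus Output paths.
#' @return The two paths, invisibly.
#' @export
write_coverage <- function(track, bedgraph_plus, bedgraph_minus) {
  strand_to_bedgraph(track$plus, bedgraph_plus)
  strand_to_bedgraph(track$minus, bedgraph_minus)
  invisible(c(bedgraph_plus, bedgraph_minus))
}
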