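#' Construct transcription units with 3' UTR windows
#'
#' A transcription unit is a stranded genomic interval (`[tu_start, tu_end)`,
#' 0-based half-open) anchored at the stop codon. `stop_codon_ref` is the
#' half-open boundary such that the 3' UTR window of `utr3_len` nt downstream
#' of the stop codon (in transcription direction) is
#' `[stop_codon_ref, stop_codon_ref + utr3_len)` on `+` and
#' `[stop_codon_ref - utr3_len, stop_codon_ref)` on `-`. Transcript-relative
#' position 0 is the first nucleotide downstream of the stop codon.
#'
#' Units whose window extends beyond chromosome bounds are excluded (not
#' truncated) with a warning, keeping window lengths uniform for metagene
#' averaging.
#'
#' @param unit_id Character vector of unit identifiers.
#' @param chrom Chromosome names.
#' @param strand `"+"` or `"-"` per unit.
#' @param tu_start,tu_end 0-based half-open unit interval.
#' @param utr3_len 3' UTR window length in nt (default 400).
#' @param stop_codon_ref Stop-codon anchor; defaults to `tu_end` on `+` and
#'   `tu_start` on `-` (the downstream unit boundary).
#' @param seqlengths Optional named chromosome lengths (or `DNAStringSet`);
#'   when given, out-of-bounds units are dropped with a warning.
#' @return A `data.frame` with columns `unit_id, chrom, strand, tu_start,
#'   tu_end, stop_codon_ref, utr3_len, utr_start, utr_end, range_start,
#'   range_end` (`utr_*` = genomic UTR window, `range_*` = union of unit
#'   interval and window, the analysis range).
#' @export
make_units <- function(unit_id, chrom, strand, tu_start, tu_end,
                       utr3_len = 400L, stop_codon_ref = NULL,
                       seqlengths = NULL) {
  n <- length(unit_id)
  stopifnot(length(chrom) == n, length(strand) == n,
            length(tu_start) == n, length(tu_end) == n,
            all(strand %in% c("+", "-")), utr3_len > 0)
  if (any(tu_start >= tu_end)) stop("tu_start must be < tu_end")
  if (anyDuplicated(unit_id)) stop("duplicate unit ids")
  if (is.null(stop_codon_ref))
    stop_codon_ref <- ifelse(strand == "+", tu_end, tu_start)
  utr3_len <- as.integer(utr3_len)
  utr_start <- ifelse(strand == "+", stop_codon_ref, stop_codon_ref - utr3_len)
  utr_end <- utr_start + utr3_len
  u <- data.frame(unit_id = as.character(unit_id), chrom = as.character(chrom),
                  strand = strand,
                  tu_start = as.integer(tu_start), tu_end = as.integer(tu_end),
                  stop_codon_ref = as.integer(stop_codon_ref),
                  utr3_len = utr3_len,
                  utr_start = as.integer(utr_start),
                  utr_end = as.integer(utr_end),
                  stringsAsFactors = FALSE)
  u$range_start <- pmin(u$tu_start, u$utr_start)
  u$range_end <- pmax(u$tu_end, u$utr_end)
  if (!is.null(seqlengths)) {
    seqlengths <- genome_seqlengths(seqlengths)
    if (!all(u$chrom %in% names(seqlengths)))
      stop("unit chromosome absent from genome")
    bad <- u$range_start < 0L | u$range_end > seqlengths[u$chrom]
    if (any(bad)) {
      warning(sum(bad), " unit(s) excluded: 3' UTR window outside chromosome",
              " bounds (", paste(utils::head(u$unit_id[bad], 5), collapse = ", "),
              if (sum(bad) > 5) ", ..." else "", ")")
      u <- u[!bad, , drop = FALSE]
    }
  } else if (any(u$range_start < 0L)) {
    bad <- u$range_start < 0L
    warning(sum(bad), " unit(s) excluded: window extends below position 0")
    u <- u[!bad, , drop = FALSE]
  }
  rownames(u) <- NULL
  u
}

#' Load transcription units from BED6 or GFF3
#'
#' BED intervals are 0-based half-open; GFF3 records (1-based closed) are
#' converted to the internal 0-based half-open convention. Strand is
#' mandatory. Each unit is extended by a 3' UTR window of `utr3_len` nt
#' downstream of its stop-codon anchor (the downstream unit boundary).
#'
#' @param path BED6 or GFF3 file.
#' @param utr3_len 3' UTR window length (default 400).
#' @param seqlengths Optional chromosome lengths for bounds checking.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return A unit `data.frame` (see [make_units()]).
#' @export
load_units <- function(path, utr3_len = 400L, seqlengths = NULL,
                       format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3" && !is.null(gr$type)) {
    keep <- as.character(gr$type) %in% c("gene", "transcript", "mRNA")
    if (any(keep)) gr <- gr[keep]
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("units without strand in ", path)
  ids <- if (!is.null(gr$name)) as.character(gr$name)
         else if (!is.null(gr$ID)) as.character(gr$ID)
         else if (!is.null(gr$Name)) as.character(gr$Name)
         else paste0("unit", seq_along(gr))
  make_units(unit_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = strand,
             tu_start = GenomicRanges::start(gr) - 1L,
             tu_end = GenomicRanges::end(gr),
             utr3_len = utr3_len, seqlengths = seqlengths)
}

#' Write units as BED6
#'
#' @param units Unit `data.frame`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_units <- function(units, path) {
  df <- data.frame(units$chrom, units$tu_start, units$tu_end,
                   units$unit_id, 0L, units$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Transcript-relative to genomic coordinates
#'
#' Relative position 0 is the first nucleotide downstream of the stop codon;
#' positive positions run downstream in transcription direction (decreasing
#' genomic coordinate on `-`), negative positions lie in the gene body.
#'
#' @param rel_pos Vector of transcript-relative positions.
#' @param strand `"+"` or `"-"` (recycled).
#' @param stop_codon_ref Stop-codon anchor (recycled).
#' @return 0-based genomic positions.
#' @export
rel_to_genomic <- function(rel_pos, strand, stop_codon_ref) {
  n <- length(rel_pos)
  strand <- rep_len(strand, n)
  stop_codon_ref <- rep_len(stop_codon_ref, n)
  ifelse(strand == "+", stop_codon_ref + rel_pos, stop_codon_ref - 1L - rel_pos)
}

#' Genomic to transcript-relative coordinates
#'
#' Inverse of [rel_to_genomic()].
#'
#' @param pos0 0-based genomic positions.
#' @inheritParams rel_to_genomic
#' @return Transcript-relative positions.
#' @export
genomic_to_rel <- function(pos0, strand, stop_codon_ref) {
  n <- length(pos0)
  strand <- rep_len(strand, n)
  stop_codon_ref <- rep_len(stop_codon_ref, n)
  ifelse(strand == "+", pos0 - stop_codon_ref, stop_codon_ref - 1L - pos0)
}

# region label from transcript-relative position
region_of_rel <- function(rel_pos, utr3_len) {
  ifelse(rel_pos >= 0L & rel_pos < utr3_len, "utr3",
         ifelse(rel_pos < 0L, "body", "downstream"))
}

unit_row <- function(units, id) {
  i <- match(id, units$unit_id)
  if (is.na(i)) stop("unknown unit id: ", id)
  units[i, , drop = FALSE]
}
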