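#' Load a genome from FASTA
#'
#' Reads a (typically synthetic) genome into a `DNAStringSet`. Sequence names
#' are truncated at the first whitespace, bases are upper-cased, and duplicate
#' names or non-IUPAC characters are rejected.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one entry per chromosome.
#' @export
load_genome <- function(fasta_path) {
  x <- withCallingHandlers(
    Biostrings::readDNAStringSet(fasta_path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("non-IUPAC characters in FASTA: ", fasta_path)
      invokeRestart("muffleWarning")
    })
  if (length(x) == 0L) stop("FASTA file contains no sequences: ", fasta_path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence names in FASTA: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (any(Biostrings::width(x) == 0L)) stop("empty sequence in FASTA")
  s <- toupper(as.character(x))
  if (any(grepl("[^ACGTRYSWKMBDHVN]", s)))
    stop("non-IUPAC characters in FASTA sequence")
  Biostrings::DNAStringSet(s)
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome A `DNAStringSet` (or a named object accepted as-is if it is
#'   already a named integer vector).
#' @return Named integer vector of chromosome lengths.
#' @export
genome_seqlengths <- function(genome) {
  if (is.numeric(genome) && !is.null(names(genome)))
    return(stats::setNames(as.integer(genome), names(genome)))
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Extract sense-strand sequence
#'
#' Returns the sequence of the genomic interval `[start0, end0)` read in
#' transcription direction: the top strand for `+`, the reverse complement
#' for `-`.
#'
#' @param genome A `DNAStringSet`.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start0,end0 0-based half-open genomic interval.
#' @return A single character string.
#' @export
sense_sequence <- function(genome, chrom, strand, start0, end0) {
  stopifnot(length(chrom) == 1L, strand %in% c("+", "-"),
            start0 >= 0, end0 > start0)
  len <- genome_seqlengths(genome)[[chrom]]
  if (end0 > len) stop("interval [", start0, ",", end0, ") exceeds length of ",
                       chrom, " (", len, ")")
  s <- Biostrings::subseq(genome[[chrom]], start = start0 + 1L, end = end0)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

# reverse-complement of plain character vectors (element-wise)
revcomp_chr <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}
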