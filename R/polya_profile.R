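#' Poly(A)-site profiles
#'
#' A poly(A) profile is a `data.frame` with one row per polyadenylation site:
#' columns `chrom`, `pos0` (0-based genomic coordinate of the 3'-most
#' templated base), `strand`, `count` (poly(A)-supporting reads), and - once
#' annotated against transcription units - `unit_id` and `rel_pos`
#' (nt downstream of the stop codon, 0-based).
#'
#' @param path Tab-delimited file with columns `chrom, pos0, strand, count`.
#' @param units Optional unit `data.frame`; when supplied, sites are annotated
#'   with `unit_id`/`rel_pos` (see [annotate_polya_units()]).
#' @return Poly(A) profile `data.frame`.
#' @export
load_polya_profile <- function(path, units = NULL) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos0", "strand", "count")
  if (!all(need %in% names(df)))
    stop("poly(A) profile must have columns: ", paste(need, collapse = ", "))
  if (any(df$count < 0)) stop("negative poly(A) read count")
  if (!is.null(units)) df <- annotate_polya_units(df, units)
  df
}

#' Write a poly(A) profile to TSV
#'
#' @param profile Poly(A) profile `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polya_profile <- function(profile, path) {
  utils::write.table(profile[, c("chrom", "pos0", "strand", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign poly(A) sites to transcription-unit 3' UTR windows
#'
#' Each site is mapped to the unit (same chromosome and strand) whose 3' UTR
#' window contains it; `rel_pos` is its distance downstream of the stop codon.
#' Sites falling in no window keep `unit_id = NA` and are flagged
#' `outside_window`.
#'
#' @param profile Poly(A) profile `data.frame` (genomic coordinates).
#' @param units Unit `data.frame`.
#' @return The profile with `unit_id`, `rel_pos` and `outside_window` columns.
#' @export
annotate_polya_units <- function(profile, units) {
  profile$unit_id <- NA_character_
  profile$rel_pos <- NA_integer_
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    sel <- profile$chrom == u$chrom & profile$strand == u$strand &
      profile$pos0 >= u$utr_start & profile$pos0 < u$utr_end
    if (!any(sel)) next
    profile$unit_id[sel] <- u$unit_id
    profile$rel_pos[sel] <-
      genomic_to_rel(profile$pos0[sel], u$strand, u$stop_codon_ref)
  }
  profile$outside_window <- is.na(profile$unit_id)
  profile
}
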