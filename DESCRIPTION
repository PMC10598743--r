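Package: utrpause
Title: Pol II Pausing and Polyadenylation Analysis in 3' UTRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nucleotide-resolution analysis of RNA polymerase II pausing in
    3' untranslated regions from NET-seq 3'-end coverage. Calls pauses against
    a local negative-binomial background, generates shuffled-pause nulls,
    scores trinucleotide sequence preferences, identifies poly(A) sites from
    3'READS reads with a genomic-A internal-priming filter, quantifies the
    spatial coupling between pauses and upstream poly(A) sites, and classifies
    pauses from genomic feature tracks with a random forest. A synthetic-data
    generator with planted ground truth supports end-to-end validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    randomForest,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
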