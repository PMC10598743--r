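---
title: "Methods: pause calling, poly(A) coupling, and classification in 3' UTRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pause calling, poly(A) coupling, and classification in 3' UTRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrpause)
```

## Scope and data model

`utrpause` analyses RNA polymerase II pausing in the 400 nt downstream of
stop codons ("3' UTR windows") from NET-seq data, and its relationship to
polyadenylation measured by 3'READS. The package works from four inputs:

* a genome (`FASTA`, any genome — typically synthetic here),
* transcription units (`BED6`/`GFF3`), each extended by a 3' UTR window of
  `utr3_len` nt (default 400) downstream of its stop-codon anchor,
* strand-specific single-nucleotide 3'-end coverage (one bedGraph per
  strand) giving Pol II position at nucleotide resolution,
* per-nucleotide poly(A)-site read counts, either supplied as TSV or called
  from raw 3'READS reads by this package.

All internal coordinates are 0-based half-open genomic, matching BED.
Transcript-relative position 0 is the first nucleotide downstream of the
stop codon, and "upstream"/"downstream" always follow transcription
direction — on the minus strand, downstream means decreasing genomic
coordinate. Units whose 3' UTR window would leave the chromosome are
excluded rather than truncated, so every unit contributes a full-length
window to metagene averages.

## Pause calling

Coverage from biological replicates is summed (`track1 + track2`) before
any thresholding, because single-replicate nucleotide-level counts are
dominated by counting noise. Units are kept when their mean coverage over
the unit-plus-window range is at least `min_gene_coverage` (default 2
reads/nt).

A pause is a nucleotide whose count

* is at least `min_pause_reads` (default 2), and
* strictly exceeds `mean + z * sd` (default `z = 3`) of a negative-binomial
  background fitted to the surrounding `2 * local_halfwidth` nucleotides
  (default 200 nt).

Numerical choices worth stating explicitly, since each one matters in
degenerate inputs:

* **Method of moments, not maximum likelihood.** Only the fitted mean and
  sd are consumed, and a moment fit is exact for those; an ML fit would add
  iteration without changing the decision rule.
* **The focal nucleotide is excluded from its own window.** A tall spike
  would otherwise inflate its own threshold.
* **Poisson variance floor.** The fitted variance is
  `max(sample variance, mean)`: an NB requires variance >= mean, and
  without the floor a locally constant window (variance 0) would make
  every nucleotide exceed its threshold.
* **Strict inequality.** Uniform coverage is never called, even at zero
  variance.
* **Edge handling.** Windows shrink at unit boundaries; positions with
  fewer than 50 nt of combined flanking context are not callable.

The per-nucleotide false-call rate of this rule on pause-free NB
background is set by the discrete upper tail beyond `mean + 3 sd`. For a
mean of 4 reads/nt it is between 0.3% and 1% depending on dispersion
(0.28% even in the Poisson limit), which is worth keeping in mind when
interpreting pause counts in sparsely covered regions: a 3-sd cut on a
skewed count distribution is not a 0.1% normal tail.

Shuffled control pauses are drawn uniformly without replacement within the
same unit (and, by default, the same region — gene body vs 3' UTR) with the
same per-unit counts, and carry the read counts of their source records so
read-weighted statistics remain comparable. Seeds are mandatory arguments.

## Sequence preferences

The pause trinucleotide is the sense-strand context at offsets (-1, 0, +1)
around the pause (minus-strand pauses are reverse-complemented), with
flanking windows up to (-4..+4) available through `offset_start`. The
normalized preference of a trinucleotide is the count of real pauses with
that context divided by the count among shuffled pauses; a pseudocount
(default 1, configurable to 0 for exact-count work) guards the ratio, and
non-finite log2 entries are flagged rather than dropped. Real and shuffled
sets are size-matched per unit, so raw counts stand in for frequencies.
Region contrasts subtract raw UTR ratios from gene-body ratios;
cross-condition similarity is the Pearson correlation over the 64 ratios.

## Poly(A)-site calling from 3'READS reads

Reverse transcription through the poly(A) tail leaves a 5' T-stretch on R1.
The caller counts and trims the leading Ts (reads not starting with T are
discarded), maps the next 17 bases — reverse-complemented into transcript
sense — by exact, genome-wide-unique matching on either strand, and then
applies the internal-priming filter: a read is retained only when its
T count strictly exceeds the genomic A-run starting immediately downstream
of the mapped 3'-most templated base. Reads whose Ts are fully templated
are artifacts of priming inside genomic A-runs and removed. The site is
assigned at the last templated base (not shifted past the A-run; the read
cannot testify about positions inside the run).

Exact-match unique mapping takes the place of a short-read aligner; with
disallowed mismatches and discarded multi-mappers the two are equivalent,
and on the synthetic genomes used here 17-mers are essentially unique.
Users with real data can bypass mapping by supplying pre-mapped positions.

The simulator commits to the same convention from the other side: an
annotated poly(A) site always rests on a non-A templated base (sites drawn
on an A are slid upstream), because tail Ts and templated As are
indistinguishable on the read — this is also how nucleotide-resolution
poly(A) maps are defined in practice. Genuine simulated reads carry
`t_count = downstream_A_run + extra` with `extra >= 1`, so they always
survive the filter; internal-priming reads are anchored inside genomic
A-runs with all Ts templated, so they never do.

## Spatial coupling of pauses and poly(A) sites

Three statistics quantify the tendency of poly(A) sites to lie just
upstream of pauses:

* per-pause counts of sites in half-open 10-nt bins covering 0-50 nt
  upstream (`d = pause - site`, with `d = 0` in the first bin: co-located
  events count as distance zero, our convention for a case the assay leaves
  ambiguous);
* a two-sample Kolmogorov-Smirnov comparison of those per-pause count
  distributions between real and shuffled pauses;
* the ratio of mean distance to the nearest upstream site, real over
  shuffled, with a delta-method standard error; pauses with no upstream
  site in the window are excluded symmetrically from both sets.

Per-pause counts are small tied integers, and the asymptotic two-sample KS
p-value is conservative under heavy ties. `ks_real_vs_shuffled()` therefore
also offers a Monte-Carlo permutation p-value for the same D statistic,
which is exact under exchangeability regardless of ties. The conservative
asymptotic value is appropriate when demonstrating an effect (it only
understates significance); the permutation value is the one to use when
checking calibration under the null, and it is what the package's own null
calibration uses.

Metagene profiles report, per relative position, the percentage of units
with at least one event there; events are unweighted indicators (a
read-weighted variant is a one-line change on the input `data.frame`).

## Random-forest classification

`extract_features()` builds one row per candidate position (real and
shuffled pauses) with categories matching the assay's feature families:
distance to the nearest upstream poly(A) site (sentinel `utr3_len` when
none exists — rows are kept, since dropping them would leak the label
through missingness), site counts in the five upstream bins, one-hot
sense-strand nucleotides at offsets -4..+4, and one column per supplied
per-position genomic track (DNA shape, chromatin, CTD phosphorylation, or
any other named track). Shuffled counts per unit are similar but not equal
to real counts after region restriction; stratified splitting handles the
imbalance and AUC is imbalance-robust, so no resampling is done.

The forest uses `mtry = 5` and `ntrees = 2000` with a stratified 75/25
train/test split; AUC is computed on the held-out quarter. Terminal nodes
default to 10 observations: vote fractions of fully grown trees are noisy
as ranking scores, and a moderate node size is the standard smoothing for
probability forests. Cross-strain cells train on all rows of one strain and
test on all rows of another; diagonal cells use the within-strain split.
Strain-level PCA encodes each strain as a centered binary vector over the
union of 3' UTR pause positions.

## The synthetic-data generator

The generator is first-class, tested code; every downstream stage is
validated against its planted truth. Its defaults describe one fixed set of
study conditions:

* 50 units of 1000 nt body plus a 400-nt UTR window, alternating strands on
  a uniform-random genome with 200-nt gaps;
* background coverage i.i.d. NB(mean 4, size 10) per nucleotide — 4
  reads/nt is a well-expressed gene just past the coverage filter, and
  size 10 (variance/mean 1.4) reflects the modest residual overdispersion
  of replicate-summed counts within high-coverage genes. Counts are
  independent across positions, matching the marginal-NB background model
  of the caller; autocorrelated backgrounds are out of scope;
* planted pauses at 5/kb with counts of `20 x mean`, far above threshold so
  that recall measures the caller, not the effect size;
* poly(A) sites either coupled — one site per UTR pause, a uniform 5-45 nt
  upstream, the measurement direction used throughout — or uniform over the
  window (about 3 sites/unit), with reads per site `1 + Poisson(4)`;
* 3'READS tails with `1 + Poisson(3)` non-templated Ts beyond the genomic
  A-run, and an `internal_priming_frac` dial between fully clean (0) and
  fully artifactual (1) libraries;
* feature tracks = standard Gaussian noise plus `snr` times a triangular
  smoothing (0.5, 1, 0.5) of the planted-pause indicator; `snr = 0` is pure
  noise.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: realistic yeast base composition and motif
structure, autocorrelated Pol II occupancy, copy-number and mappability
artifacts, sequencing error, and mechanistic Pol II kinetics. The
simulations validate the statistical machinery, not biological effect
sizes.

## Null calibration of the classifier

A useful control mirrors the trick used for sequence preferences: feed the
classifier two *independently drawn* shuffled-position sets from the same
strain with zero-SNR tracks and an uncoupled poly(A) profile
(`rfc_null_baseline()`). The expected AUC is 0.5. Measured over ten seeds
the package obtains about 0.46 — slightly *below* chance. The deficit is
real and instructive: two independent draws of 1000 positions from the same
pool of 20,000 share ~50 exact positions and many near-neighbours with
identical poly(A)-geometry features but opposite labels, and a forest that
memorizes them anti-generalizes on the held-out quarter. Drawing the two
classes disjointly removes the effect entirely (mean 0.497 in the same
setup). The overlapping-draw protocol is kept because it is the faithful
analogue of comparing two independently generated shuffled-pause sets; the
~0.04 pessimistic bias is the price of that fidelity and is well within the
tolerance used to declare the classifier unbiased.

## Problem sizes used by the test suite

The packaged checks run at deliberately desk-friendly scales, chosen to
give each statistic comfortable power while keeping the suite fast: 50
units for caller-oracle equivalence, recall and false-call measurement;
500 units (~1000 UTR pauses) for coupling detection; 200 seeds of 40 units
for null calibration of the KS test and distance ratio; 2000 rows for the
classifier baseline (ten seeds); 5000 rows for the Gaussian closed-form
check. Headline numbers from the original strain panel (pause counts per
strain, cross-strain correlation ranges, per-category AUC values) depend on
the deposited datasets and are not reproduced by the synthetic conditions.
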