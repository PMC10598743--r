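# utrpause

Nucleotide-resolution analysis of RNA polymerase II pausing in 3′ UTRs and
its spatial relationship to polyadenylation.

NET-seq maps the 3′ end of nascent RNA, so a single-nucleotide coverage
track reads out Pol II position; nucleotides where coverage rises far above
the local background are pause sites, interpreted as elevated polymerase
dwell time. Because Pol II must transcribe past a poly(A) site before
cleavage and polyadenylation can occur, pause sites and poly(A) sites can be
spatially coupled, and that coupling — along with the sequence and chromatin
features that predict pausing — is what this package quantifies. It is aimed
at analysts of nascent-transcription (NET-seq/PRO-seq-style) and 3′-end
(3′READS-style) sequencing data, and every stage can be exercised end-to-end
on seeded synthetic data with planted ground truth.

## What it computes

* **Pause calling.** Within transcription units passing a coverage filter
  (≥ 2 reads/nt over the unit plus its 400-nt 3′ UTR window), a nucleotide
  with count *x* is a pause when *x* ≥ 2 and *x* > μ + 3σ, where (μ, σ) come
  from a method-of-moments negative-binomial fit to the surrounding 200 nt
  (focal nucleotide excluded, variance floored at the mean).
* **Shuffled nulls.** Size-matched control pauses drawn uniformly within the
  same units and regions; all enrichment statistics are normalized against
  them.
* **Trinucleotide preferences.** Sense-strand contexts at offsets (−1, 0, +1)
  (and flanks out to ±4); preference = real count / shuffled count, compared
  across conditions by Pearson correlation of the 64 ratios.
* **Poly(A)-site calling (3′READS).** 5′ T-stretch counting and trimming,
  exact unique 17-mer mapping, and the internal-priming filter: a read is
  kept only if its T count strictly exceeds the genomic A-run downstream of
  its last templated base.
* **Spatial coupling.** Per-pause poly(A)-site counts in 10-nt bins 0–50 nt
  upstream, Kolmogorov–Smirnov real-vs-shuffled comparisons (asymptotic or
  permutation), and the real/shuffled ratio of mean distance to the nearest
  upstream site with a delta-method standard error.
* **Random-forest classification.** Real-vs-shuffled pause classification
  from grouped feature categories (poly(A) distances, sequence context, and
  arbitrary per-position tracks such as DNA shape, chromatin, or CTD marks)
  with mtry = 5, 2000 trees, stratified 75/25 split, held-out ROC AUC;
  cross-strain AUC matrices and strain-level PCA over shared pause
  positions.
* **Synthetic data.** A seeded generator for genomes, units, NB background
  coverage with planted pauses, optionally pause-coupled poly(A) profiles,
  raw 3′READS reads with poly(A)-tail T-stretches and internal-priming
  artifacts, and feature tracks with tunable signal-to-noise.

## Worked example

```r
library(utrpause)

cfg  <- sim_config(seed = 42, n_units = 50)        # NB(4) background, coupled poly(A)
sim  <- simulate_netseq(cfg)                       # genome, units, coverage, truth
calls <- call_pauses(sim$coverage, sim$units, pause_params())
shuf  <- shuffle_pauses(calls, sim$units, seed = 1)
pa    <- simulate_polya(sim$units, sim$truth, cfg, genome = sim$genome)

real_utr <- calls[calls$region == "utr3", ]
shuf_utr <- shuf[shuf$region == "utr3", ]
distance_ratio(real_utr, shuf_utr, pa)
ks_real_vs_shuffled(rowSums(upstream_bin_counts(real_utr, pa)),
                    rowSums(upstream_bin_counts(shuf_utr, pa)))
```

Output for this seed:

```
units: 50   planted pauses: 342   called pauses: 576
recall of planted pauses: 1
distance ratio (real/shuffled): 0.617 +/- 0.093
KS real vs shuffled (sites 0-50 nt upstream): D = 0.32, p = 2.37e-08
mean 3'UTR pause density (pauses/kb): 8.9
```

Reading this: all 342 planted pauses are recovered (the extra calls are the
expected discrete-tail background of a 3σ rule on NB counts — roughly 0.5–1%
of nucleotides at this coverage). Because the generator coupled each poly(A)
site 5–45 nt upstream of a pause, real pauses sit much closer to their
nearest upstream poly(A) site than shuffled ones (ratio 0.62, far below 1),
and the per-pause upstream site counts differ strongly from the shuffled
null (KS p ≈ 2 × 10⁻⁸). With `polya_coupling = "uniform"` the ratio is
statistically indistinguishable from 1.

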