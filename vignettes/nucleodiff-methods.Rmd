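---
title: "Comparing nucleosome maps between strains: models and choices"
author: "nucleodiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing nucleosome maps between strains: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleodiff)
```

# The problem

MNase digestion of chromatin leaves ~147 bp nucleosome-protected fragments
whose ends are sequenced as short single-end reads. Comparing such maps
between a wild-type strain and a chromatin-regulator deletion asks, for
each nucleosome: did it move, did its occupancy change, did it disappear,
did it delocalize? `nucleodiff` answers these questions per nucleosome and
aggregates them into genome-wide statistics. This vignette explains the
model behind each stage, the tunable parameters, the numerical choices,
and what the synthetic validation does and does not establish.

# From reads to tracks

Every read is reduced to its 5'-end coordinate and strand. Because each
sequenced end sits a fixed distance from the fragment center, the
**fragment length** can be estimated from the data themselves: forward- and
reverse-strand 5' densities are smoothed (Gaussian sd 10 bp), local maxima
with at least `min_peak_reads` (default 10) raw reads of local support are
paired forward-to-nearest-downstream-reverse, and the median of
`reverse − forward + 1` over pairs is the estimate. Fewer than 50 pairs
triggers a low-confidence warning; zero pairs is an error asking for an
explicit `fragment_length` — at very low coverage (a few reads per
nucleosome) there are no usable peaks, and pretending otherwise would be
worse than asking.

Each read then contributes one **fragment center**: `p + (L-1)/2` for a
forward read at `p`, `q - (L-1)/2` for a reverse read at `q`. For even `L`
the center is assigned to the left-of-middle basepair (forward `p + L/2`,
reverse `q - L/2 + 1`), so the forward and reverse conversions of the two
ends of one fragment agree exactly; tests pin this convention. Centers
pushed off a chromosome end are clipped and counted, and the conservation
`sum(track) = reads used − clipped` is asserted throughout.

Two per-bp signals derive from the center counts:

* **Occupancy**: the number of centers within ±73 bp — equivalently, the
  number of implied 147 bp fragments covering the basepair. Implemented as
  an exact cumulative-sum boxcar, verified against brute-force interval
  stabbing.
* **Nucleosome score**: the center counts convolved with a discrete
  Gaussian, sd 25 bp. A description of such a kernel as "a window of 50 bp"
  is ambiguous between total width 50 and half-width 50; truncating a
  sd-25 kernel at ±25 discards ~32% of its mass and visibly distorts peak
  shape, so the kernel here is truncated at ±50 (±2 sd) and renormalized
  to unit mass. Both `kernel_sd` and `kernel_halfwidth` are exposed in the
  configuration.

For cross-sample comparability, score tracks are **quantile-normalized**
genome-wide (rank-r values replaced by the across-sample mean of rank-r
values, ties sharing their rank-range mean), via
`limma::normalizeQuantiles`. Occupancy is deliberately *not* quantile
normalized: occupancy fold-changes instead use a single global scaling
factor, the ratio of total fragment-center counts, so that genuine local
occupancy differences are not flattened away.

# Calling nucleosomes

Nucleosome centers are called as score peaks that are (i) not among the
lowest-scoring 10% of raw local maxima and (ii) not within 100 bp of a
higher-scoring peak. Implementation details that the definition leaves
open, fixed here for determinism:

* plateaus resolve to their leftmost basepair;
* the 10% quantile is computed per chromosome over all raw maxima before
  suppression (`low_score_quantile`, configurable);
* suppression processes peaks in descending score, ties broken by leftmost
  coordinate, so the output is independent of input ordering — a property
  test asserts this.

Each call records its **supporting reads** (fragment centers within
±73 bp). The fraction of the genome covered by call ±73 bp footprints is
reported as a calibration diagnostic; at the defaults on realistic
synthetic data it lands near 0.77, consistent with genome-wide maps in
which called nucleosomes account for roughly 80% of nucleosomal DNA.

**Ordinals**: in gene orientation, +1 is the first call at or downstream
of the TSS, counting up to the stop codon; −1 is the first call upstream,
through a 1 kb promoter window. Gene-body assignment beats another gene's
promoter claim; contested promoter calls go to the nearest TSS. All
metrics work in gene orientation, and ±-strand twin tests assert strand
invariance.

# Classifying between-strain differences

Calls from the two samples are paired by **mutual nearest neighbors**
within 100 bp (matching the caller's minimum spacing, so a call has at
most one plausible partner). When two calls contend for one partner the
nearer wins and the loser becomes a loss/gain candidate.

One further rule guards the pairing: a call supported by fewer than
`min_reads` (8) fragment centers is not accepted as evidence that a
nucleosome is present. A pair formed by a real nucleosome and a weak
background peak — which otherwise masks an eviction as a mere occupancy
change — is therefore demoted, its well-supported side re-entering the
loss/gain pathway. The eight-read floor is the same one the loss/gain
detector itself applies, used symmetrically.

* **Shifts**: centers differing by ≥ `min_shift` (15 bp) with a two-sided
  t-test p < 0.05 comparing the fragment-center positions within
  `read_window` (30 bp) of each sample's own call center. Welch's
  unequal-variance form is the default (`shift_test = "student"`
  available); the positions are integers, and when both windows are
  degenerate (zero variance) the p-value is 0 for unequal means and 1
  otherwise, flagged rather than crashed. Pairs with fewer than 3 centers
  on either side are an insufficient-data outcome, never a call. Raw
  signed estimates are retained for *all* pairs — the decomposition below
  needs the sub-threshold ones too.
* **Occupancy changes**: mean occupancy over call ±30 bp (single-bp
  occupancy is noisier; the window is configurable), depth-corrected fold
  ≥ 2 or ≤ 0.5.
* **Loss/gain**: unpaired call, ≥ 2-fold depth-corrected occupancy in the
  retaining strain, ≥ 8 supporting reads.
* **Strand-split confirmation**: the entire analysis is re-run twice, once
  per strand. A change is confirmed only if a change of the same class
  (and, for shifts, the same direction) passes all thresholds in both
  single-strand analyses with call centers within 10 bp (shifts) or 30 bp
  (others) of the combined analysis. Single-end sampling puts roughly half
  the reads in each strand, so confirmation operates at half depth — this
  is what makes the biological-repeat null clean.

Raw p-values with the 15 bp effect floor and strand confirmation are used
as published; an optional Benjamini–Hochberg switch is deliberately left
off by default so that results remain comparable with the original
procedure.

Comparing two biological repeats of the same strain through the identical
machinery gives the empirical null; on synthetic repeat pairs the
confirmed change rate is well below 0.1% of called nucleosomes.

# Gene-level statistics

* **Fuzziness**: the percentage of gene-body fragment centers (start to
  stop codon) within 20 bp of the nearest called center. A strain is
  flagged fuzzier at a gene when its percentage is ≥ 5 points below every
  other strain *and* the number of predicted nucleosomes in the gene is
  unchanged — the count precondition excludes changes explained by a lost
  or gained nucleosome rather than delocalization. Genes failing the
  precondition are reported as unclassifiable rather than silently
  unflagged; under heavy jitter roughly 10% of genes change their call
  count (peak merges and splits), which is a property of peak calling at
  finite depth, not of the classifier.
* **Directionality**: fraction of shifts with positive (upstream)
  gene-oriented sign, with a two-sided exact binomial test against 0.5.
* **Propagation**: per gene, the maximally shifted nucleosome and the
  signed shifts of its ordinal ±1 neighbors (0 when unshifted), averaged
  across genes — asymmetric remodeling shows up as unequal neighbor means.
* **Linkers**: center-to-center distances between selected nucleosomes and
  their upstream neighbors, with the fractions below 147 bp and 137 bp;
  distances under the 147 bp footprint imply vanishing or invaded linkers.
* **TSS profile**, **positional enrichment** along the normalized gene
  body (promoter calls excluded from that view), **covariate-stratified
  shift means** (downstream shifts enter negatively by default,
  `mode = "upstream_only"` zeroes them), and per-gene **region occupancy
  log-ratios** (250 bp promoter / first 500 bp coding, pseudocount 1
  recorded in output metadata).
* **Shift decomposition**: assuming the remodeler only shifts nucleosomes
  upstream and that estimation error is symmetric, the downstream half of
  the observed shift-size histogram estimates the error component:
  per 5 bp magnitude bin, error = min(upstream, downstream), activity =
  max(upstream − downstream, 0), and the shifted-gene fraction is
  Σ activity / N. The input is all per-gene estimates at the ordinal,
  including zeros and sub-threshold values; bins where downstream exceeds
  upstream are clamped at zero activity and the clamped mass reported.
  A total-count variant (upstream minus downstream totals) can be derived
  from the returned histograms; the per-bin form is the default because it
  also reconstructs the error distribution's shape.

# The synthetic generator

The generator emulates the canonical gene-chromatin architecture: a
nucleosome-free region upstream of the TSS, a +1 nucleosome 73 bp
downstream of the TSS, a phased array at 165 bp spacing (the wild-type
median inter-nucleosome distance) decaying geometrically in occupancy
(5% per ordinal), and two upstream promoter nucleosomes beyond a 140 bp
NFR. Reads are sampled per nucleosome as Poisson(depth × weight) fragments
with normally jittered centers, one single-end read per fragment on a
random strand (both-end emission available for symmetric strand tests),
plus 5 uniform background reads per kb — enough that read-support
thresholds are exercised rather than vacuous.

Defaults the underlying study does not determine were fixed once at
realistic values for the organism: mean gene length 1,500 bp, mean
intergenic gap 700 bp, 36 bp reads from 151 bp fragments, and a default
depth of 30 reads per nucleosome chosen for statistical power at desk
scale rather than fidelity to any particular library. Where two genes'
nucleosomes would collide across an intergenic gap (facing promoters),
the lighter center is dropped deterministically at map-build time, so the
returned map *is* the ground truth for every downstream comparison.

What the synthetic data does **not** emulate: MNase sequence preference,
GC bias, mappability gaps, digestion-degree differences between samples,
non-uniform background, or linker/sub-nucleosomal particles. Passing the
validation suite therefore demonstrates that the estimators recover the
phenomena they target under clean sampling noise — not that real libraries
are free of systematic artifacts; on real data the biological-repeat null
comparison is the appropriate control and is built into the same API.

# Validation sizes and determinism

The test suite validates each operation against independent oracles
(direct kernel evaluation, brute-force interval stabbing, closed-form
binomial and Welch formulas, hand-computed toy examples) and the pipeline
end-to-end on 300–500-gene genomes at depth 30: caller recovery ≥ 95%
within 10 bp under 15 bp jitter, shift sensitivity and size recovery for
20 bp injected shifts, the 50% shifted-gene fraction from the
decomposition, 165 → 150 bp linker compression for 15 bp shifts,
fuzziness flagging under 30 bp jitter, eviction detection under the
eight-read rule (with zero confirmed detections at depth 4, where support
is sub-threshold per strand), and a five-seed repeat-vs-repeat null below
1% confirmed changes per class. All randomness flows through explicit
integer seeds; identical seeds give byte-identical outputs, which the
suite also asserts.

# Known limitations

* Fragment length is constant per sample; length heterogeneity within a
  library blurs centers and is not modeled.
* The caller has no sub-nucleosome or fragile-nucleosome classes and does
  not estimate nucleosome width.
* Ordinal assignment is rank-based; a missed or spurious call inside a
  gene renumbers everything downstream of it, which is why cross-sample
  matching is positional, not ordinal.
* The decomposition assumes strictly one-sided true shifts and symmetric
  errors; a remodeler that genuinely shifts both ways will have its
  activity underestimated by the cancellation.
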