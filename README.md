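# nucleodiff

Differential nucleosome positioning from MNase-seq read maps.

Chromatin remodelers such as the yeast ISWI-family enzyme Isw1 reposition
nucleosomes along DNA. Comparing genome-wide nucleosome maps between a wild
type and a remodeler-deletion strain reveals where and how: individual
nucleosomes may **shift** along the DNA, change **occupancy**, be **lost or
gained**, or become **fuzzier** (delocalized across the cell population).
`nucleodiff` implements the full analysis path from mapped mono-nucleosome
read 5' positions to classified per-nucleosome changes and the downstream
genome-wide statistics, for anyone comparing MNase-seq maps between two
conditions.

## Method

Starting from strand-specific read 5' ends (BED6), per sample:

1. **Fragment length** `L` is estimated as the median distance between
   forward-strand read-density peaks and their nearest downstream
   reverse-strand peaks.
2. Each read is converted to its implied **fragment center** (forward read
   at `p` → `p + (L-1)/2`; reverse read at `q` → `q - (L-1)/2`).
3. **Occupancy** at basepair `x` counts fragment centers in `x ± 73`
   (147 bp mono-nucleosome footprint). **Nucleosome scores** are the center
   counts convolved with a discrete Gaussian (sd 25 bp, truncated at
   ±50 bp, unit mass); score tracks are quantile-normalized across samples.
4. **Nucleosome calls** are score peaks that are (i) not among the 10%
   lowest-scoring peaks and (ii) not within 100 bp of a higher-scoring
   peak. Calls get gene-relative ordinals (+1 = first nucleosome downstream
   of the TSS; −1, −2 in the 1 kb promoter).

Between two samples, calls are paired by mutual nearest neighbors
(≤ 100 bp) and classified:

- **Shift** — call centers differ by ≥ 15 bp and a two-sided Welch t-test
  on the fragment-center positions within ±30 bp of each sample's call
  center gives p < 0.05. Signs are gene-oriented (positive = upstream,
  toward the gene 5' end, in sample B).
- **Occupancy** — mean occupancy over call ±30 bp differs ≥ 2-fold after
  global depth correction.
- **Loss / gain** — an unpaired call with ≥ 2-fold depth-corrected
  occupancy in the retaining strain and ≥ 8 supporting reads.
- All changes are **strand-split confirmed**: the analysis is repeated with
  forward-only and reverse-only reads, and a change must pass all
  thresholds in both, with call centers within 10 bp (shifts) or 30 bp
  (other classes) of the combined analysis.

Downstream statistics: per-gene **fuzziness** (% of gene-body fragment
centers within 20 bp of a called center) and its cross-sample
classification; shift **directionality** (exact binomial test of the
upstream fraction); **propagation** to neighboring nucleosomes; inter-
nucleosome **linker distances**; TSS-aligned profiles; normalized-position
enrichment; covariate-stratified shift means; and a **mixture
decomposition** of the observed shift-size distribution into
positioning-error and remodeler-activity components (error per magnitude
bin = min(upstream, downstream) counts; activity = max(upstream −
downstream, 0); shifted fraction = Σ activity / N genes).

A synthetic MNase-seq generator (`generateGenomeLayout`,
`buildNucleosomeMap`, `applyPerturbation`, `sampleReads`,
`generateCovariate`) produces phased nucleosome arrays (NFR + 165 bp
spacing, geometrically decaying occupancy) with injectable shifts,
evictions, occupancy scaling and positional jitter, so every stage can be
validated against ground truth.

## Worked example

```r
library(nucleodiff)

## simulate a wild type and a mutant with 20 bp upstream shifts at the +5
## nucleosome of half of the genes
gl  <- generateGenomeLayout(50, seed = 1)
map <- buildNucleosomeMap(gl$genes)
g5  <- unique(map$gene_id[map$ordinal == 5])
spec <- perturbationSpec(
  shift_targets = data.frame(gene_id = g5[seq(1, length(g5), 2)], ordinal = 5),
  shift_size = 20, shift_direction_bias = 1)
mut <- applyPerturbation(map, spec, seed = 1)
wt_reads  <- sampleReads(map,     gl$seqlengths, depth = 30, seed = 2, sample_id = "wt")
mut_reads <- sampleReads(mut$map, gl$seqlengths, depth = 30, seed = 3, sample_id = "mut")

cmp <- compareStrains(wt_reads, mut_reads, gl$genes)
cmp
#> StrainComparison: 579 vs 573 nucleosome calls
#>   shift       24  (24 confirmed)
#>   occupancy   18  (2 confirmed)
#>   loss         0
#>   gain         0

ch <- changeTable(cmp)
mean(ch$signed_shift[ch$class == "shift" & ch$ordinal == 5], na.rm = TRUE)
#> [1] 20.08333
```

All 24 injected +5 shifts are detected, strand-confirmed, and their mean
estimated size (20.1 bp) matches the injected 20 bp; the unconfirmed
occupancy rows are sampling noise rejected by strand splitting.

A command-line wrapper with `simulate | tracks | call | compare | metrics |
run-all` subcommands is installed at
`system.file("scripts", "nucleodiff", package = "nucleodiff")`.

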