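---
title: "Detecting chromatin-loop rewiring and compartment changes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chromatin-loop rewiring and compartment changes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopRewire)
```

loopRewire quantifies how acute perturbation of a chromatin protein rewires
three-dimensional genome organization. It compares two conditions (for
example a vehicle control against a few hours of targeted protein
degradation) across three layers: focal chromatin loops in cis Hi-C contact
maps, megabase-scale A/B compartments, and protein occupancy or chromatin
accessibility measured as fragment coverage (CUT&RUN, ATAC). This vignette
explains each model, the tunable parameters, the numerical choices, and what
the synthetic-data tests do and do not demonstrate about real data.

## Coordinate and data conventions

All intervals are 0-based, half-open `[start, end)`; bin `b` of a binned map
covers `[b*bin_size, (b+1)*bin_size)`. A `contact_map` is a symmetric
per-chromosome matrix that distinguishes *observed zero* from *missing*: any
bin with zero marginal coverage is masked, and every cell touching a masked
bin is `NA`. This distinction matters because the smoothing stage imputes
missing cells but must not invent signal where a zero was genuinely
observed.

## Loop detection

**O/E normalization.** Contact frequency decays steeply with genomic
distance, so all loop statistics operate on the observed-over-expected
matrix: each cell is divided by the mean of defined cells at its distance
(`oe_normalize()`). Far diagonals with fewer than `min_cells = 10` defined
cells are pooled with progressively farther diagonals so every expected
value rests on a minimal sample; without pooling, a single far-diagonal
cell would always be forced to O/E = 1.

**Smoothing and imputation.** Fragment- or fine-bin-resolution maps are
sparse. `smooth_impute()` replaces model-based imputation with a masked
Gaussian kernel: each cell's neighbourhood mean `K` (Chebyshev radius 2,
kernel sd `sigma = 1` bin) fills missing cells, and defined cells are
blended as `alpha*obs + (1-alpha)*K` with `alpha = 0.5`. A constant matrix
is a fixed point, and `alpha = 1` degenerates to pure gap-filling. This is
a deliberate simplification: it is validated against planted truth, not
against any external imputation tool, and it cannot propagate information
further than two bins.

**Donut scoring.** A candidate pixel `(i, j)` is scored as the mean O/E of
its peak window divided by the strongest of four local backgrounds — donut,
horizontal stripe, vertical stripe, and the lower-left quadrant toward the
diagonal (`loop_score()`). Requiring the *maximum* background makes the
score conservative against stripe artifacts and diagonal bleed-through.
Defaults: peak half-width `p = 1`, outer half-width `w = 5`, at least
`m_min = 3` defined cells per component, distance band 3–200 bins, score
cutoff 2.0. Calling (`call_loops()`) applies greedy non-maximum suppression
with Chebyshev radius `p`, ties broken deterministically by ascending
`(i, j)`.

A known limitation at desk-scale depth: in the sparse long-range regime
(beyond roughly 100 bins at the standard simulated depth) chance
fluctuations occasionally exceed score 2, producing rare spurious calls
(about 0.1% of scored pixels, none below 100 bins in the bundled tests). A
production analysis on deep data should either restrict `d_max` to the
distance range its depth supports or raise `score_min` for far candidates.

## Differential loops

Per-sample loop calls are pooled into a union of candidate pixels; every
candidate is re-scored in every sample, candidates unscorable in any sample
are dropped, and scores are z-normalized within each sample across the
union (population standard deviation — this is a normalization, not an
inference step). For conditions 1 and 2 with `R1` and `R2` replicates,
difference scores `DS = z_1x - z_2y` are formed over the full replicate
cross product (`k = R1*R2`; an index-matched mode is provided), and the
meta score is the Stouffer combination

$$Z(i,j) = \frac{1}{\sqrt{k}} \sum_{DS} \left( z_{1x}(i,j) - z_{2y}(i,j) \right)$$

with a two-sided normal p-value; `p < 0.05` candidates are directional
(`Z > 0`: weaker in the treatment, "lost"; `Z < 0`: "gained"). Both
directions occur in practice, which is why the p-value is two-sided.

**Calibration caveat (important).** The `DS` elements share replicates, so
they are not independent: `sum(DS) = R2*sum(z_1) - R1*sum(z_2)`, giving
`Var(Z) = (R1+R2)(1-v)` where `v` is the fraction of z-variance shared
across samples (true candidate-level structure). The statistic is therefore
well calibrated only where candidate heterogeneity dominates replicate
noise (`v` near `1 - 1/(R1+R2)`). On a loop-free map `v` is essentially
zero and `Var(Z)` approaches `R1+R2`, so nominal p-values are strongly
anticonservative; the package characterizes this by a permutation
experiment (reported by `scripts/acceptance.R` as
`loopfree_permuted_significant_fraction`, about 0.31 under the standard
conditions) rather than correcting it, because the statistic is defined by
the combination rule above. Practical readings of the output should treat
`Z` as a ranking score and rely on the planted-truth/permutation
characterization — or on an explicit permutation null — rather than on the
nominal significance level. The same mechanism means a strong loop present
in *both* conditions can occasionally reach `p < 0.05` by replicate noise
alone.

Downstream summaries (`interaction_change_summary()`,
`locus_rearrangement_enrichment()`) count significant loops per chromosome,
rank promoters by overlapping significant anchors (ties broken by gene
name), rank sliding hotspot windows (width 1 Mb, step half-width, anchors
counted when fully contained), and compare per-locus rearrangement counts
between a locus subset and a reference set with Welch's unequal-variance t
test; loci are matched by a ±25 kb window around their centres.

## A/B compartments

`compartment_pc1()` computes the leading eigenvector of the Pearson
correlation matrix of the O/E columns over valid bins (50 kb bins by
convention). The eigenvector sign is arbitrary, so it is oriented by TSS
density: the sign class with more TSS per bin becomes positive (the A
compartment). Exact ties leave the vector unflipped with a deterministic
canonical sign and an `ambiguous` flag.

`saddle_analysis()` removes the `ceiling(1%)` lowest-coverage bins per
chromosome, ranks the rest by PC1 descending, partitions them into 100
contiguous rank groups (remainder spread over the leading groups; a
chromosome with fewer than 100 usable bins is skipped with a message
rather than up-sampled), and averages O/E between group pairs. Chromosome
matrices are averaged unweighted — with a single desk-scale chromosome the
choice is moot, and for genome-wide use it weights each chromosome's
compartment structure equally rather than by size. `AA`, `BB`, `AB` are
the top-left, bottom-right and top-right quarter-block means;
`saddle_diff()` returns the element-wise log2 ratio with non-positive or
undefined cells masked, and `switching_fraction()` reports sign
disagreement between two oriented tracks over their common valid bins.

## Fragment coverage: normalization and differential occupancy

Fragments shorter than 120 bp (TF CUT&RUN) or 150 bp (ATAC) select the
nucleosome-free signal; histone-mark and ChIP samples are not size-filtered
(`assay_size_filter()`). Normalization is background-based: all samples'
fragments are pooled; enriched regions are called by tiling the genome into
500 bp windows, assigning fragments by midpoint, testing window counts
against the uniform Poisson background with BH correction, and merging
significant windows separated by at most one window; each peak contributes
a left and right flank of 5,000 bp, clipped to the chromosome and with all
peak overlap subtracted. Flank counts per sample feed the DESeq-style
median-of-ratios estimator, and each sample is then independently thinned
at `min(sf)/sf_j` so the relatively deepest sample is down-sampled to the
shallowest and no retention rate exceeds 1. The flank width and window size
are package defaults, configurable; the 5 kb flank needs roughly 25+
background fragments per flank region for the median-of-ratios estimator to
concentrate — at much lower counts the geometric mean's small-count bias
(about `1/(2*lambda)`) dominates the closure error.

Differential occupancy re-uses the pooled catalog: counts per region per
sample, normalized by size factors, are tested with a moment-based Wald
statistic. The per-region dispersion is estimated from group-centred
residuals and floored at the catalog-median dispersion — per-region moment
estimates from three-replicate groups are far too noisy on their own, and
underestimates directly inflate the Wald statistic; sharing the catalog
median is the simplest form of the information-sharing that
negative-binomial frameworks use. The log2 fold change carries a 0.5
pseudocount on group means so zero-count regions stay finite. Direction
calls gate on the BH-adjusted p-value by default (`gate = "p"` mimics
looser raw-p thresholds).

## Integration statistics

Differential peaks map to genes within 25 kb of the TSS (peak midpoint,
inclusive boundary): a peak near `n` genes contributes `(1/n) *
(-10*log10 p)` to each, a PHRED-like score that splits evidence between
nearby genes; `p = 0` is clamped at `1e-300`. Loop anchors are classified
promoter (any TSS ±2 kb) with precedence over enhancer (any H3K27ac-like
peak). Gain/loss bias per anchor category is the ratio of significant
gained to lost loops with a qualifying anchor (undefined, not infinite,
when losses are zero); category pairs are compared on per-anchor net change
(gained minus lost) with a one-sided Wilcoxon rank-sum test under the
normal approximation with tie correction, BH-adjusted across the requested
comparisons. Overlaps between differential region sets use the one-sided
hypergeometric test on a shared region catalog, which keeps the
exchangeability assumption honest (region-level, not base-pair-level).

## Synthetic data: what it emulates, and what it does not

`simulate_hic_experiment()` draws Poisson counts around an expectation with
power-law distance decay `(1+d)^-gamma` (`gamma = 1`), a compartment
checkerboard (`1+s` within, `1-s` across; `s = 0.3`, 40-bin blocks),
planted loops as a multiplicative `fc` over a 3x3 window matching the
default peak half-width, per-replicate depth factors (0.8–1.25), and 3% of
bins depleted to 5% expectation to mimic unmappable or low-coverage
regions. TSS positions are drawn at 1.5 per A-bin vs 0.15 per B-bin so the
orientation rule has signal to work with. The standard experiment is one
4 Mb chromosome at 10 kb (400 bins) with `base_level = 150` — chosen by
scaling a 400-million-read experiment down to a 4 Mb segment of a mouse
genome (~640k cis reads; with `sum((1+d)^-1)` over the matrix near
`4800`, the distance-0 expectation is ~133, rounded) — and three
replicates per condition. Compartment analyses use a 20 Mb chromosome at
50 kb so the 100-group saddle is well-defined.

`simulate_fragment_experiment()` draws uniform background fragment
midpoints at 0.01 per bp (the density of a typical ATAC library of tens of
millions of fragments) plus per-peak Poisson counts (`intensity = 400`
expected fragments per peak at depth 1) with condition-specific
multipliers, and fragment lengths from a two-component normal mixture
(70 ± 15 and 200 ± 30 bp) emulating nucleosome-free and mono-nucleosome
modes.

Not emulated: restriction-fragment spacing, trans contacts, copy-number
structure, GC/mappability biases, overdispersion beyond depth factors,
TADs/insulation, duplicate reads, and correlated replicate artifacts.
Passing the bundled tests therefore demonstrates the *correctness of the
computations* and sensible behaviour under idealized noise — not that any
threshold generalizes to a particular real dataset.

## Problem sizes and reproducibility

The bundled demo and the test suite use the problem sizes above (400-bin
loop maps, 400-bin compartment maps, 10 Mb fragment genomes, 1,000-region
count simulations); the whole pipeline runs in well under a minute on one
core. Every stochastic stage takes an explicit seed, and the pipeline
expands its single configuration seed into fixed per-stage substreams so
stages rerun in isolation reproduce the full run; manifests carry MD5
checksums so reruns can be compared byte-for-byte. The pipeline runner
accepts simulation blocks in its configuration; analyses of on-disk
matrices and fragment files enter through the module functions
(`read_contact_map()`, `read_intervals()`) directly.
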