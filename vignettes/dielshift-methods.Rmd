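---
title: "Methods: comparative diel rhythmicity and network rewiring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative diel rhythmicity and network rewiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its statistical machinery:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the design was genuinely
open. It states no empirical result that the test suite and the acceptance
script do not themselves compute.

## The design being analysed

The pipeline targets parallel two-condition diel timecourses: expression in
TPM for each gene, sampled every 2 h over 24 h (zeitgeber times ZT0–ZT22,
lights-on at ZT0 in a 12:12 photoperiod), with three biological replicates
per timepoint, under a well-watered (`WW`, C3) and a drought (`DR`,
CAM-cycling) condition. Whole replicates may be missing (the motivating
study lost one WW ZT22 replicate and two DR ZT0 replicates;
`sedum_missing()` encodes exactly that). Missing individual cells are
rejected — only whole dropped replicates are supported, which keeps the
rank statistics below well-defined.

Genes are pre-filtered jointly across both conditions: total TPM ≥ 5 and
zero-fraction < 25%. Both thresholds follow the motivating analysis and are
exposed in `default_config()`.

## Rhythm detection

### Statistic and exact null

For a candidate period P (default: only 24 h) and every lag φ on the
sampling grid, the reference template is c(t) = cos(2π(t − φ)/P), expanded
to one value per replicate sample. The test statistic is Kendall's S
between the observed series and the template; template-tied pairs
contribute nothing, and observed ties contribute 0 (standard Kendall
convention).

Under the null hypothesis of exchangeable continuous observations, the
concordance count J = (S + M)/2 (M = number of template-untied pairs) has
the Jonckheere–Terpstra null distribution determined entirely by the
template's tie-group sizes. Its probability mass function factorises into
independent Mann–Whitney components — one per tie group, each with a
Gaussian-binomial generating function — which the package builds exactly
and convolves (`kendall_s_null()`). Counts stay below 2^53 for the series
lengths this design produces (≤ 36 observations), so the arithmetic is
exact in doubles; the test suite checks the DP distribution against
exhaustive permutation enumeration for all n ≤ 8 and several tie
structures. Two-sided p-values are exact tail sums P(|S_null| ≥ |S_obs|).
The null conditions on the template's tie structure only; with observed
ties the test is slightly conservative, which we accept for its
determinism.

### Multiple testing

Two corrections are applied, both Bonferroni and both deliberately
conservative:

* **within gene**, the minimal p over templates is multiplied by the number
  of distinct template vectors tested (12 for the default grid; a template
  and its negation are counted separately, matching the conservative
  convention of rank-based rhythm detectors). Toggleable via
  `bonferroni_templates`.
* **across genes**, adjusted p = min(1, p × n_genes) per condition, cycling
  ⇔ adjusted p strictly below α = 0.05.

Because the exact null is discrete, realised family-wise error rates sit
well below the nominal level; the acceptance suite verifies control on
2,000 white-noise genes × 200 runs.

### Phase and amplitude

The reported phase is the best template's lag (grid-resolved, so ±2 h at
this design's sampling). Phase is only reported for genes called cycling.
Amplitude is estimated by least squares at the detected lag,
x(t) = m + A·cos(2π(t − φ)/24) with A constrained ≥ 0. The motivating
analysis never defines "amplitude"; this estimator was chosen because it is
deterministic, unit-preserving (TPM) and comparable across conditions,
which the amplitude-difference classification requires. Replicates are
scanned replicate-expanded against a replicate-expanded template rather
than pre-averaged (pre-averaging is available via `pre_average`); the
period set is {24 h} because a single-day design cannot distinguish nearby
periods — both choices are configuration, not hard-coded.

## Rhythm-change classification

Genes cycling in one condition only are `WW_only` / `DR_only`; in neither,
`arrhythmic`; in both, the amplitude difference Δ = A_WW − A_DR splits them
into `both_equal` (|Δ| < 3 TPM), `both_WW_gt_DR` (Δ ≥ 3) and
`both_DR_gt_WW` (Δ ≤ −3). The source text says "difference less than 3"
without an absolute value; the absolute value is required for the two
"greater" categories to be symmetric under condition swap, and the test
suite asserts that symmetry. The circular phase shift is
min(|Δφ|, 24 − |Δφ|) ∈ [0, 12]; a gene is flagged `phase_changed` when the
shift is at least the `phase_threshold` of 2 h — one sampling interval, the
smallest detectable shift; "a change in phase" is never defined in the
source, so the smallest detectable value is the least arbitrary default.
(The source's own printed phase-change count and percentage are mutually
inconsistent; the package reports both raw count and percentage and targets
neither.)

Phase enrichment uses integer phase bins 0–23 even though the default grid
is 2-hourly (empty odd bins simply return p = 1), one-sided hypergeometric
per bin, Bonferroni over the 24 bins, enriched ⇔ adjusted p ≤ 0.05.

## Promoter cis-element analysis

Promoters of 500/1000/2000 bp (default 2,000, the length the motivating
category analysis used) are taken immediately 5′ of the annotated start (+
strand) or the reverse complement immediately 3′ of the annotated end (−
strand), truncated at contig edges with a log line.

The enrichment statistic is **gene presence**, not site count: a promoter
either contains an element or it does not, and foreground versus background
presence counts enter a one-sided hypergeometric test. This matches
ELEMENT-style analyses where long promoters would otherwise let site counts
be driven by a few repetitive outliers. Both strands are scanned and each
k-mer is collapsed with its reverse complement to a canonical element
(promoters are double-stranded regulatory DNA; the source is silent on
strandedness). Palindromic sites are deduplicated by position so they are
not counted twice. The raw p < 0.05 cutoff of the source is reproduced as
the `enriched` flag; Benjamini–Hochberg q-values over the full 3–8-mer
family (~2.7 × 10⁴ canonical elements) are emitted as a clearly separate
column because the raw cutoff is anticonservative at that family size.

The known-motif catalog ships the published patterns (ME `CCACAC`, G-box
`CACGTG`, EE `AATATCT`, GATA `GGATA`, TBX `AAACCCT`, SBX `AAGCCC`, PBX
`ATGGGCC`, ABRE `YACGTGGC`, ABRE-like `BACGTGKM`, MYB `MACCWAMC`). No MYC2
consensus is published in the source; the catalog defaults MYC2 to the
G-box (the core MYC2 binding site in the literature) and the pattern is an
argument, not a constant. The novel drought/CAM elements of the motivating
study live in unreleased supplementary data; the pipeline *discovers*
enriched elements rather than hard-coding any.

## Network comparison

### Co-expression modules

Per condition, on replicate-averaged profiles: biweight midcorrelation
(median/MAD weights, Pearson fallback for zero-MAD profiles), signed
adjacency a_ij = ((1 + bicor)/2)^β with the published soft powers (β = 7
WW, β = 10 DR), signed topological overlap, average-linkage clustering of
1 − TOM, a **fixed-height cut**, minimum module size, and iterative merging
of modules whose eigengenes (first principal component of member profiles)
correlate above 1 − mergeHeight (0.01 WW, 0.15 DR, as published). The
dynamic tree cut of the reference implementation is deliberately simplified
to a fixed cut: the analytic output of interest is cross-condition module
*overlap*, not precise module boundaries. The default cut height of 0.85 on
the 1 − TOM scale was chosen once from the geometry of the measure at this
design's sample counts: within-module TOM dissimilarities of coherent
modules concentrate below ~0.8 while merges across unrelated modules occur
above ~0.9. Module overlap between conditions is tested per module pair
with a one-sided Fisher exact test, which the suite verifies equals the
hypergeometric tail oracle to machine precision.

### Interaction networks

The reference pipeline used a part-mutual-information tool whose estimator
is defined in its own publication; the package implements a documented
**stand-in** that reproduces the *differencing logic*, not that tool's edge
scores: normalized mutual information (equal-frequency binning into
⌈√n⌉ bins, MI normalised by √(H_x·H_y) to [0, 1]), a score threshold, and
ARACNE-style data-processing-inequality pruning (drop edge (i, j) when some
k has min(score(i,k), score(k,j)) > score(i,j) × 1.1). The published
thresholds 0.47/0.52 are honoured as defaults but their scale is this
estimator's own — they are configuration, and with only 12 per-condition
samples the small-n caveat is logged. Activators/suppressors of a target
are plain set differences of its neighbor sets between the DR and WW
networks; identical networks provably give empty lists.

## The synthetic-data generator

The generator is a stated world, not a tuning dial. It emulates: the exact
sampling design (including the study's missing replicates on request);
cosine diel signals value = max(0, baseline + A·cos(2π(t − phase)/24) + ε)
with additive Gaussian noise on the TPM scale truncated at zero (a
lognormal multiplicative mode is available for heavier tails — the source
does not state its noise structure, so these are assumptions, not
inferences); promoters as i.i.d. backgrounds at a chosen GC content with
motifs overwritten at known offsets; and correlation-structured network
data (latent-factor cliques for exchangeable blocks, Markov chains along
spanning trees so that indirect correlations decay and DPI pruning has
something real to remove). Benchmark defaults — baseline 20 TPM, amplitude
10 TPM, noise sd = amplitude/3, the 200/200/300/300 class layout with 150
phase-shifted genes — follow the stated recovery benchmark; where no value
was stated (baseline, amplitude) they were fixed once at magnitudes typical
of moderately expressed diel genes and not revisited.

What it does **not** emulate: read-count sampling noise, library-size or
length normalisation, correlated noise across genes, dampening of rhythms
across the day, or realistic promoter base composition beyond GC content. A
green recovery test therefore establishes that the algorithms are correct
on data satisfying their assumptions — not that real tissue data satisfies
those assumptions.

## Numerical and degenerate-input choices

* Template values are rounded to 9 decimals before tie grouping and sign
  computation, so symmetric cosine values tie exactly.
* Zero-variance series: p = 1, τ = 0, never cycling.
* Constant gene profiles: module label 0 (unassigned) with a warning in
  networks; excluded with a warning in interaction networks.
* Bonferroni boundaries are strict: adjusted p exactly equal to α is *not*
  cycling; phase enrichment uses ≤ as published.
* Hypergeometric tails are computed with `phyper` and cross-checked in the
  suite against direct summation and `fisher.test`.
* `ks_to_time(ks, rate)` = ks/(2·rate) requires the substitution rate
  explicitly: the published divergence time implies an unstated rate, and
  the package refuses to guess it.
* Orthogroup expansion/contraction compares the focal species against
  *every* comparator carrying the family ("uniquely changed" semantics);
  `mode = "any"` relaxes this. Zero-count comparators are excluded from the
  ratio (division by zero) and reported.

## Known limitations

* The exact-null engine assumes a shared template tie structure per scan;
  heavily unbalanced replicate loss changes M per gene only through the
  column set actually present, which is handled, but cell-level missingness
  is not supported.
* Phase resolution equals the sampling interval (2 h); sub-grid phase
  shifts are invisible by construction.
* The interaction-network stand-in is not the published estimator; its
  absolute scores (and therefore thresholds) are not comparable to that
  tool's, only the WW/DR differencing logic is.
* With 12 samples per condition, both bicor and NMI estimates are noisy;
  module and edge calls on real data of this size should be read as
  hypotheses, which is how the motivating study used them.
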