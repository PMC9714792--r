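---
title: "Methods and design of the vascell analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the vascell analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`vascell` implements the quantitative core of a pulmonary-artery remodeling
study: single-cell QC and cluster statistics, ligand–receptor communication
scoring with a permutation null, and transverse vessel-image quantification.
This vignette records the models, the parameters that matter, and the design
choices made where the methods left room, so that results can be interpreted
and the implementation maintained.

## Quality control

A cell is removed when any of three rules fires:

1. **Mitochondrial fraction** above `max_mito_fraction` (default 0.05).
   Mitochondrial genes are recognised by the `MT-` identifier prefix or an
   explicit list; if none are found the rule is skipped with a warning and
   the skip is recorded in the report.
2. **Too few detected genes**: fewer than `min_genes` (default 200) genes
   with non-zero counts.
3. **Too many detected genes**: more than `median + mad_multiplier × MAD`
   (default multiplier 3) of the per-cell detected-gene counts. The MAD is
   the *raw* median absolute deviation, without the 1.4826 normal-consistency
   factor — the most literal reading of a "3 times the MAD" rule — and the
   cutoff is computed within each sample when sample labels are supplied,
   mirroring per-sample processing before integration. Whether the original
   toolchain computed this per sample or on merged data is not documented;
   per-sample is this package's recorded choice.

The upper cutoff is an *estimated* parameter of the dataset. It is written to
the QC report, and `qc_filter(upper_cutoff=)` re-applies recorded cutoffs, so
a second pass over the kept cells removes nothing. Re-estimating the cutoff
on already-filtered output would keep shaving the upper tail (removing the
tail lowers both the median and the MAD), which is why idempotence is defined
with respect to the recorded cutoffs.

Normalization is the ecosystem default: counts scaled to `scale` (10⁴) per
cell, then `log(1 + x)`. The scale factor and pseudocount are carried as
attributes for provenance.

## Marker statistics

`find_markers` contrasts one population against all other cells. Genes are
pre-filtered on detection (`max(pct_in, pct_out) ≥ 0.25`) and effect size
(|log₂FC| ≥ 0.25), then tested with a two-sided Wilcoxon rank-sum test and
Bonferroni-corrected over the genes actually tested. Fold change is computed
on the de-logged mean scale with a pseudocount of 1:
`log2((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`, which bounds fold
changes for dropout-heavy genes; the pseudocount is configurable.

The rank-sum p-value uses exact enumeration (via the null rank-sum
distribution) when both groups have ≤ 25 observations and the gene has no
ties, and otherwise the normal approximation with tie correction and
continuity correction — numerically identical to `stats::wilcox.test` in the
same regimes, as the test suite verifies. The same machinery runs in a
vectorized form inside the permutation engine.

Under permuted-label nulls the raw p-values are calibrated (the significance
fraction at α = 0.05 sits within binomial error of 0.05 for continuous
expression); with heavily tied count data the test is conservative, which is
inherited from the rank test itself.

## Signature (module) scores

A cell's score for a gene set is the mean normalized expression of the set
minus the mean of a matched control set. Genes are ranked by dataset-mean
expression and divided into 24 equal-size bins; each signature gene draws 100
controls uniformly from its own bin. Two details matter:

- **Controls exclude the signature.** If a planted or real program elevated
  the signature genes, contaminated controls would absorb part of the signal.
- **Controls are pooled with multiplicity.** Each signature gene contributes
  an equal-weight draw from its own bin. Deduplicating the pool would
  re-weight bins by their number of distinct controls and bias the baseline
  whenever signature genes cluster in a few bins.

The binning is computed on the observed dataset means, so a program expressed
in a large fraction of cells shifts its genes' bins slightly upward and the
recovered score under-estimates a planted shift by roughly
`δ × (population fraction)`; at a 5% population the bias is negligible.
Scores are deterministic given the seed. Cell-cycle phases follow the usual
rule: G1 if both S and G2M scores are ≤ 0, otherwise the larger score's
phase.

## Proportion tests

For each population, per-sample proportions are transformed with
`asin(sqrt(p))` (variance-stabilizing for proportions; endpoints map 0 → 0
and 1 → π/2) and the two conditions are compared with a two-tailed,
pooled-variance two-sample t test. With three samples per condition Welch
degrees of freedom are unstable, hence the equal-variance default
(`var_equal = FALSE` is available). Conditions are ordered alphabetically so
the sign of `t` is well-defined. Simulations in the test suite confirm the
null p-values are close to uniform at n = 3 + 3 samples with a few hundred
cells per sample.

## Ligand–receptor communication

The communication score between populations is deliberately simple and
additive. For a database pair (L, R) with weight `w_db ∈ [0, 1]`:

- L must qualify as *enriched* in the source population and R in the target:
  log₂FC ≥ 0.25 against all other cells and Bonferroni-adjusted Wilcoxon
  p < 0.05 over the gene panel. Negative fold changes never contribute — an
  "expression weight" for a depleted gene is not meaningful. Autocrine edges
  are allowed.
- The edge weight is `w_ligand + w_db + w_receptor`, the enrichment log₂ fold
  changes plus the database weight. Related published methods propagate
  weights along network paths; this package implements exactly the additive
  three-term sum, not path propagation.

Significance is assessed by permuting population labels *within each sample*
(preserving per-sample composition and population sizes; the permutation
unit is not prescribed by the method description, and within-sample
shuffling is the conservative choice) and re-scoring. The p-value is the
add-one estimator `(1 + #{permuted ≥ observed}) / (1 + n_perm)`, which is
never zero; edges whose ligand or receptor fails admission in a permutation
count as not exceeding. The reference setting is 100,000 permutations;
simulation studies in this package use 1,000, which resolves p down to
~0.001.

Per permutation only the rank-sum statistics and group means are recomputed:
gene ranks over cells do not depend on labels, so they are computed once and
group sums are obtained by matrix products. The test suite verifies this is
*exactly* equivalent to naive recomputation. Network summaries restrict to
significant edges; a population's ligand (receptor) score is the sum of the
ligand (receptor) components over its outgoing (incoming) significant edges,
and pairwise edge counts are tallied both over all and over significant
edges.

## Vessel-image quantification

Images are represented as named channel matrices (row/col, 0-based, pixel
centers at integer coordinates); z-stacks are reduced by maximum-intensity
projection first.

**Segmentation.** The wall channels are combined by per-pixel maximum and
thresholded with Otsu (the vessel-shape step names no method; Otsu is the
standard default and is configurable). The largest connected component is the
wall, its filled hull the outer mask, and the largest interior hole the
lumen. The lumen's center of mass seeds 32 evenly spaced radial probes.

**Radial profiles.** Each probe is sampled by bilinear interpolation from its
lumen-boundary crossing to its outer-boundary crossing and resampled onto 100
positions of a normalized [0, 1] axis; "rescaling to a common baseline" is
interpreted as this per-probe length normalization only — intensities are
never rescaled, because the profile is meant to show wall composition from
the lumen outward. Probes that fail to cross both boundaries are dropped
(error if more than half fail). Whether probes should start at the lumen
center or the lumen boundary is ambiguous in prose; boundary-to-boundary is
the package's documented choice, since the wall — not the lumen interior —
is the object of interest. A display-contrast saturation setting used for
published figures is a rendering parameter only and is not applied to any
quantification.

**Thresholding.** `yen_threshold` maximizes Yen's maximum-correlation
criterion over a 256-bin histogram; the test suite checks it against an
exhaustive search at every level on random 8-bit images. Yen assumes a
foreground class exists: on a background-only channel the cut lands inside
the noise mode. Two safeguards make masks robust (`binarize`):

- if the automatic cut labels more than half the image foreground — only
  possible when the cut fell below the background mode — the threshold falls
  back to the robust background ceiling `median + 5 × MAD`;
- the thresholded mask is despeckled by morphological opening with a 5-pixel
  disc, the standard post-threshold cleanup of imaging macros. Isolated
  noise pixels and few-pixel clusters vanish; nuclei (radius ≥ 5 px at the
  synthetic scale) and wall rings (≥ 6 px wide) pass through. Structures
  thinner than the brush would be lost; the brush is configurable.

**Nuclei and positivity.** The nuclear channel is thresholded (Yen), holes
filled, touching nuclei split by watershed on the distance transform, and
objects below a minimum area (default `π(5/2)²`, half the default synthetic
nucleus diameter) discarded. A nucleus is *medial* when the ACTA2 mask,
dilated by a 2-px disc (the dilation radius is not documented in the source
method; 2 px at the synthetic pixel scale is the package default, exposed in
config), overlaps it while no VWF signal lies within it — the medial set is
monotone non-decreasing in the dilation radius. Marker positivity per nucleus
is the fraction of its area covered by the thresholded marker channel; a
vessel's summary is the percentage of medial nuclei at or above
`positivity_cutoff` (default 0.1 of nucleus area; the original macro reports
per-nucleus fractions and leaves the dichotomization rule unstated). Groups
of vessels are compared with the two-sided Wilcoxon rank-sum test; note the
exact test's smallest two-sided p at 3 vs 3 vessels is 0.1, so comparisons at
that size are indicative rather than confirmatory.

## The synthetic-data generator

**Expression.** Counts are negative-binomial with mean/dispersion
parameterization (`variance = μ + μ²/dispersion`); `dispersion = Inf` or
`poisson = TRUE` switches to the Poisson limit. The default design mirrors
the study shape: 14 populations, 2 conditions × 3 samples, 400 cells per
sample, 2,000 genes at baseline mean 0.3 counts/cell with dispersion 2 —
typical magnitudes for droplet scRNA-seq — 10 marker genes per population
elevated 2^2-fold, 50 condition genes elevated 2-fold, and per-cell expected
mitochondrial fractions drawn from [0.01, 0.04] and planted by rescaling an
`MT-`-prefixed gene block so the QC stage's mito detection is exercised end
to end. Per-population cell counts of the original samples are not published
beyond totals, so default proportions are uniform and shifts are planted
explicitly. Active ligand–receptor channels elevate the ligand in the source
and the receptor in the target population. The generator does *not* simulate
ambient RNA, doublets, batch effects, or spliced/unspliced layers — passing
recovery tests therefore demonstrates correctness of the statistics under
the stated noise model, not robustness to those artifacts.

**Images.** A vessel is rendered as concentric rings around the image
center: lumen (radius 40 px by default), a thin VWF-lined intima (to 46 px),
an ACTA2 media (to 80 px), and an adventitia (to 105 px) in a 256-px field.
Nuclei (radius 5 px) are placed in the media by rejection sampling with a
non-overlap constraint and a 1,000-retry cap (explicit failure rather than
unbounded runtime); a planted fraction of them carries marker signal. With
finite `channel_snr` every channel receives a camera background baseline
(0.1) plus Gaussian read noise of standard deviation `1/channel_snr`,
clipped to [0, 1]; `channel_snr = Inf` emits exact 0/1 indicators for
geometric ground-truth tests. The default SNR of 20 is a conservatively
noisy setting — positivity recovery is exact across seeds from SNR 10 to
100 under the safeguards above.

## Problem sizes and determinism

Simulation-based tests use deliberately modest sizes chosen to give stable
statistical behavior: null calibration at 100–200 permuted scans of 1,000
genes × 120 cells, channel recovery at 20 seeds × 1,500 cells × 1,000
permutations, image recovery at 20 seeded vessels. Every stochastic function
takes a seed, restores the caller's RNG state, and derives stage-specific
sub-seeds in the pipeline, so reruns are byte-identical. Pipeline outputs
carry a provenance header (config hash excluding output paths, seed, stage).

## Known limitations

- Population labels are an input; clustering, embedding, and integration are
  out of scope, as are MAST-style DEG models and path-propagating
  communication scores.
- The Wilcoxon exact path is limited to ≤ 25 per group without ties; beyond
  that the tie-corrected normal approximation is used.
- One vessel per image is assumed (the largest component wins); multi-vessel
  fields are not handled.
- The despeckling brush bounds the smallest detectable structure; quantifying
  sub-5-px puncta would require a smaller brush and a cleaner channel.
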