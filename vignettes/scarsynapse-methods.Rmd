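---
title: "Methods: MMEJ deletion scars, immune synapse proximity and outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MMEJ deletion scars, immune synapse proximity and outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarsynapse)
```

This vignette documents the statistical models behind `scarsynapse`, the
choices that were genuinely open when the package was designed, and what
the synthetic generators do and do not emulate.

## 1. The MMEJ Deletion Footprint

Microhomology-mediated end joining (MMEJ) is a POLQ-dependent
double-strand-break repair pathway that leaves short deletions at
microhomology sites. Its genomic scar is a per-tumor excess of somatic
deletions in the 6–20 bp size range, which the package quantifies as the
MMEJ Deletion Footprint.

**Definition.** Deletion lengths are the reference-minus-alternate allele
length for every deleted allele (`parse_deletions()`; multi-allelic VCF
records are split first, insertions and length-preserving substitutions
are excluded). Lengths are counted into the closed bins
[1, 5], [6, 13], [14, 20], [21, 50]; lengths above 50 bp are kept in a QC
overflow column but excluded from the statistic, since 50 bp is the upper
edge of the largest bin. The raw MDF is the 6–13 plus 14–20 bin count.
The footprint is purely size-based: no microhomology sequence context is
checked, so the statistic is computable from any variant table.

**Standardization.** Raw MDF counts are z-scored across the cohort using
the sample (n−1) standard deviation — cohorts here are small, and the
sample sd is the conventional default. The "shifted" value subtracts the
cohort minimum so the smallest score maps to 0; the shift is affine and
display-oriented, and the package tests that Pearson correlations and
rank statistics are identical on raw, z and shifted scales. Quartiles are
cut from the z-scores with linear-interpolation (type 7) empirical
quantiles at 0.25/0.5/0.75, with values exactly at a boundary assigned to
the lower quartile; the `mdf_high` flag marks tumors strictly above the
cohort median. A zero-variance cohort yields all-zero z-scores with a
warning; a single-tumor "cohort" is an error, since standardization is
undefined.

**Cohort scope.** The standardization cohort is exactly the set of tumors
in one invocation. Whether discovery and validation series should be
standardized jointly or separately is a scientific choice the package
leaves to the caller's manifest: both are supported, neither is imposed.

## 2. MDF–neoantigen coupling

Neoantigen prediction is consumed as a per-tumor count, never computed.
The coupling analysis uses Pearson correlation by default (Spearman is
exposed), computed within a DDR subgroup — the coupling is a property of
HRD biology and pooling subgroups confounds it with the class difference
itself.

**TMB adjustment.** To ask whether MDF tracks neoantigens beyond sheer
mutation quantity, neoantigen burden is regressed on tumor mutational
burden by OLS on `log10(x + 1)` scales — both quantities are
conventionally displayed and modeled on log10 axes, and the +1 keeps
zero counts finite — and the residuals are correlated with MDF. The
residuals satisfy the usual OLS identities (zero sum, orthogonality to
the regressor), which the tests assert. With zero-variance TMB the
residuals degrade gracefully to the centered transformed burden, with a
warning.

**Group comparisons** use two-sided Mann–Whitney U tests: exact
enumeration when both groups have n ≤ 8 and no ties, otherwise the
tie-corrected normal approximation with continuity correction. Pairwise
subgroup contrasts report raw p-values; Benjamini–Hochberg adjustment is
available as a flag but is off by default, since no particular
multiplicity procedure is canonical for these panels. Contingency
analyses use the Pearson chi-square without continuity correction.

## 3. The spatial immune-synapse test

On a spatially resolved single-cell table (coordinates in μm, curated
cell-type labels, log1p-normalized expression), an *APC-like macrophage*
is a macrophage with strictly positive HLA-DRA **and** CD74. The observed
statistic is the fraction of CD8⁺ T cells within 20 μm (inclusive —
"within a radius" and the ≤ 20 μm stratification convention are applied
consistently) of at least one APC-like macrophage, in Euclidean distance.

**Null model.** Tissue geometry is held fixed: every cell keeps its
position, and the APC-like labels are reassigned uniformly at random
among all macrophages, preserving the APC count — the single natural
reading of label reassignment among macrophages. 500 permutations are
drawn by default and the empirical p-value is the literal proportion of
permuted fractions ≥ the observed one, so p can be exactly 0; the
strictly positive `(k+1)/(n+1)` estimator is available by option for
users who prefer the conservative convention. Each sample is analyzed
independently; nothing is pooled across samples.

**Implementation.** Distances are double precision with no grid
discretization of the *statistic*. The neighbor search buckets reference
points into radius-sized grid cells and inspects the 3×3 neighborhood of
each query — an exact algorithm, tested for identity with brute-force
all-pairs distances on random configurations. The CD8 × macrophage
in-radius adjacency is computed once per sample; each permutation is then
a sparse matrix–vector product, so all 500 permutations are evaluated in
a single multiply. Because permuted and observed fractions are computed
by the identical arithmetic (counts over the same denominator), the ≥
comparison involves no floating-point tolerance.

**Expression stratification** compares *all* macrophages (not only
APC-like ones) split at ≤ 20 μm to the nearest CD8 cell, per gene, by
two-sided Mann–Whitney U with the rank-biserial correlation
`2U/(n₁n₂) − 1` as effect size. An empty stratum skips the test with an
explicit status rather than erroring, since one-sided tissue sections
legitimately produce it.

## 4. The neoantigen-gradient trajectory

Immune cells pooled over tumors are ordered by (tumor neoantigen burden
ascending, tumor id, stable input order) and split into 30 contiguous
bins of near-equal size (the first `total mod 30` bins take one extra
cell). Each tumor contributes according to its cellular composition —
tumors are never reweighted.

This tumor-level ordering is the central interpretive decision of the
module: a per-cell latent ordering (diffusion pseudotime or similar)
could define the gradient instead, and the API deliberately isolates the
ordering step (`order_and_bin()` returns a plain bin assignment) so an
alternative ordering can be injected and summarized with the same
`summarize_bins()`. Equal cell-count bins were chosen over equal
gradient-width bins so every bin estimate has comparable precision.

Per bin, the package reports cell-type proportions, Shannon entropy in
bits (base 2 chosen so the maximum is `log2(#types)`, a readable bound;
`0·log 0 = 0`), mean module scores, and the mean tumor-level shifted MDF
of the cells in the bin. Module scores z-score each gene across **all
cells jointly** (not per tumor — per-tumor scaling would erase exactly
the between-tumor signal the trajectory is meant to expose; a
zero-variance gene contributes 0) and average over the genes of the set
that are present; curated gene sets are user-supplied, not shipped as
biological claims.

## 5. Outcomes

Kaplan–Meier estimation and the two-group log-rank test are delegated to
the `survival` package. The restricted mean survival time is the area
under the KM step function on [0, τ] with τ = 24 months by default. When
a group's follow-up ends in a censoring before τ, the last KM value is
carried flat to τ with a warning — the common convention of reference
RMST implementations; ending in an event needs no convention since the
curve is fully determined. The variance of each group's RMST is the
standard Greenwood-based plug-in
`Σ_j A_j² d_j / (n_j (n_j − d_j))` over event times `t_j ≤ τ`, where
`A_j` is the restricted area from `t_j` to τ; the package's estimate and
standard error are tested for equality with the restricted-mean summary
of `survival::survfit`, an independent implementation. The between-group
difference (first group level minus second) carries a normal 95% CI;
differences are unadjusted. Median splits for strata send ties to the
low stratum.

## 6. What the synthetic generators emulate

The cohort data this kind of analysis targets are controlled-access, so
the package ships generators that reproduce the *statistical structure*
the pipeline assumes, with recorded ground truth.

**Variant catalogs.** Each tumor is HRD with probability `hrd_fraction`;
deletion counts are Poisson(`lambda_del`); each deletion is drawn from a
discrete uniform on 6..20 bp with the class-specific MMEJ weight
(defaults 0.6 HRD / 0.05 HRP — the HRP weight is deliberately a free
parameter, since the low-level MMEJ signal in HR-proficient tumors has no
established distribution), otherwise uniform on 1..5 bp. Discrete
uniforms are the simplest shapes consistent with size-binned counting;
real deletion-length spectra are not uniform within bins, which is
irrelevant to any statistic the package computes from bins. A deletion is
frameshift iff its length is not a multiple of 3. Neoantigen burden is
Poisson (or negative binomial under overdispersion) with mean
`coupling_alpha × frameshift_count + baseline` (defaults 0.5 and 2);
missense counts are Poisson(`lambda_missense`, default 50), making TMB ≈
3 mutations/Mb at the assumed 30 Mb exome — a realistic figure for
pancreatic cancer; the exome size must be fixed somewhere and 30 Mb is a
standard denominator. One structural consequence worth knowing: under
these uniforms the per-deletion frameshift probability is *higher* in the
1–5 bp regime (4/5) than in the 6–20 bp regime (10/15), so at the pooled
cohort level HRP tumors accrue slightly more frameshifts per deletion and
coupling analyses belong within the HRD subgroup, where the shared
deletion process drives a positive MDF–neoantigen association.

**Spatial samples.** Planar windows only (the targeted assays are
sectioned tissue); macrophages uniform, a fixed fraction APC-like with
strictly positive co-expression (non-APC macrophages zero out at least
one gene, so the expression-based flag recovers the ground truth); CD8
cells uniform, or with probability `attraction` placed at a random
APC-like macrophage plus Gaussian(σ) displacement clipped to the window.
`attraction = 0` is the calibration null; 0.6 with σ = 5 μm is the
power alternative. An optional `expr_effect` adds expression to
CD8-proximal macrophages, giving an alternative for the stratification
test. Expression is generated directly on the log1p scale — downstream
only thresholds at zero and ranks, so a count layer would add nothing.

**Immune census.** Tumors receive increasing neoantigen burdens
(log-spaced 5..80, spanning the low-to-high range of predicted burdens);
composition interpolates linearly from 70% macrophage to 10% macrophage
(the remainder split over CD8T/CD4T/B/NKT/Treg) as burden rises, scaled
by `gradient_strength`; tumor-level shifted MDF rises with the gradient
plus Gaussian noise. **Survival** times are exponential by group with
rate `ln 2 / median` and independent exponential censoring.

What these generators do *not* emulate: real sequence context (no
microhomology sequences), read-level error, spatial segmentation
artifacts or doublets, 3D tissue, per-cell transcriptional manifolds
(cell types are labels, not clusters), and non-exponential survival
hazards. Passing tests therefore demonstrate the *procedures* are correct
and calibrated under the assumed structure — not that the biological
effect sizes in any real cohort will match.

## 7. Test and calibration scales

The suite exercises the permutation machinery at the scale a single
tissue sample warrants: 300 macrophages (30% APC-like) and 150 CD8 cells
on a 500 μm square with 500 permutations; calibration uses 200 null
samples (Kolmogorov–Smirnov against U(0,1) at α = 0.01, plus an exact
binomial band on the rejection rate at p ≤ 0.05) and power uses 100
alternative samples. Coupling recovery runs 100 replicate 30+30-tumor
cohorts; the RMST closed-form check uses 500 replicates of n = 200
exponential cohorts against `(1 − e^{−λτ})/λ`. These sizes give the
binomial and KS bounds quoted in the tests their intended resolution
while keeping the whole suite fast.

Numerical edge cases are handled explicitly throughout: empirical
permutation p-values may be exactly 0 under the literal definition;
zero-variance genes score 0; zero-variance cohorts z-score to 0 with a
warning; an all-APC macrophage population makes every permutation
reproduce the observed configuration (p = 1, warned); ties at exactly the
20 μm radius are counted as proximal on both the statistic and the
stratification, and tied null fractions count against the observed value
via ≥.

## 8. Known limitations

* MDF is size-based only; a sequence-aware microhomology check would
  require aligned reads or flanking sequence, both out of scope.
* The trajectory's tumor-level ordering collapses within-tumor
  heterogeneity in burden; injectable orderings mitigate but do not
  remove this.
* RMST differences are unadjusted; no Cox modeling is provided.
* The permutation null conditions on the observed APC count; it does not
  model uncertainty in the APC-like definition itself.
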