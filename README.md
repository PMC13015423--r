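# scarsynapse

Pancreatic cancers with homologous recombination deficiency (HRD) repair
double-strand breaks through the error-prone, POLQ-dependent
microhomology-mediated end joining (MMEJ) pathway, which leaves a
characteristic scar: short somatic deletions concentrated in the 6–20 bp
size range. These deletions are frequently frameshifting, and frameshift
indels are a rich source of predicted neoantigens — so the deletion scar
connects a tumor's DNA-repair genotype to its immunogenicity.

`scarsynapse` is an R package for analysts working with somatic variant
calls, spatially resolved single-cell data and survival tables who want to
quantify that connection:

* **MMEJ Deletion Footprint (MDF).** For tumor *i*, deletions are binned
  by size (1–5, 6–13, 14–20, 21–50 bp) and

  `MDF_i = #deletions in [6,13] + #deletions in [14,20]`,

  z-scored across the cohort, `z_i = (MDF_i − mean)/sd` (sample sd),
  shifted so the cohort minimum is 0, and cut into quartiles.
* **MDF–neoantigen coupling**, with Pearson/Spearman correlation and a
  TMB adjustment: OLS of `log10(neoantigen+1)` on `log10(TMB+1)`, then
  correlation of the residuals with MDF.
* **Spatial immune-synapse test.** The fraction of CD8⁺ T cells within
  20 μm of an APC-like macrophage (a macrophage with HLA-DRA > 0 and
  CD74 > 0, log1p scale) is compared against a geometry-preserving null
  in which APC-like labels are reshuffled among macrophages (500
  permutations; empirical p = proportion of permuted fractions ≥
  observed). Macrophages are also stratified into CD8-proximal (≤20 μm)
  vs CD8-distal and compared per gene by two-sided Mann–Whitney U.
* **Neoantigen-gradient trajectory.** Immune cells pooled across tumors
  are ordered by tumor-level neoantigen burden, split into 30 contiguous
  near-equal bins, and summarized by cell-type composition, Shannon
  entropy (bits), curated program scores and mean tumor-level MDF.
* **Outcomes.** Kaplan–Meier curves, log-rank tests, and restricted mean
  survival time, `RMST = ∫₀^τ Ŝ(t) dt` with τ = 24 months, with a
  Greenwood-based variance and normal CI on the between-group difference.
* **Synthetic generators** for every input (variant catalogs, spatial
  point patterns, immune census, survival), seeded and with recorded
  ground truth, so the whole pipeline is testable without access data.

## Worked example

Simulate a small cohort, bin the deletions and compute MDF scores:

```r
library(scarsynapse)

cfg     <- genomic_sim_config(n_tumors = 6, lambda_del = 20, seed = 101)
catalog <- simulate_variant_catalogs(cfg)
dels    <- catalog$variants[catalog$variants$Variant_Type == "DEL", ]
spectra <- bin_spectrum(data.frame(
             tumor_id = dels$Tumor_Sample_Barcode,
             deletion_length = nchar(dels$Reference_Allele)),
           tumors = catalog$truth$tumor_id)
scores  <- compute_mdf(spectra)
merge(spectra, scores, by = "tumor_id")
#>   tumor_id b1_5 b6_13 b14_20 b21_50 overflow_gt50 raw_mdf      z_mdf shifted_mdf quartile mdf_high
#> 1     T001    6     6      8      0             0      14  0.9230995    2.181872        4     TRUE
#> 2     T002    8     6      7      0             0      13  0.7552632    2.014035        4     TRUE
#> 3     T003   24     1      0      0             0       1 -1.2587720    0.000000        1    FALSE
#> 4     T004   21     0      1      0             0       1 -1.2587720    0.000000        1    FALSE
#> 5     T005    9     5      5      0             0      10  0.2517544    1.510526        2    FALSE
#> 6     T006   12     6      6      0             0      12  0.5874270    1.846199        3     TRUE
```

The two tumors with raw MDF 1 are the two simulated HRP tumors
(`catalog$truth$class` is `HRD HRD HRP HRP HRD HRD`): their deletions sit
almost entirely in the 1–5 bp bin, while the HRD tumors carry the 6–20 bp
scar. `parse_deletions()` produces the same records directly from VCF or
MAF files, and `mdf_from_manifest()` runs file → spectrum → score for a
whole cohort manifest.

The spatial test on a simulated sample with CD8→APC attraction:

```r
cells <- simulate_spatial_sample(spatial_sim_config(attraction = 0.6, seed = 7))
permutation_null_test(cells, n_perm = 500, seed = 8)
#> CD8-APC proximity (sample S1): fraction 0.753 within 20 um
#>   150 CD8, 300 macrophages (90 APC-like); 500 permutations
#>   empirical p = 0
```

75.3% of CD8 cells sit within 20 μm of an APC-like macrophage; none of
the 500 label permutations reaches that fraction, so the enrichment is
significant at the resolution of the permutation null (the strictly
positive `(k+1)/(n+1)` estimator is available via `add_one = TRUE`).
`stratify_and_compare_expression(cells)` then shows CD8-proximal
macrophages with higher HLA-DRA and CD74 (Mann–Whitney p = 1.6e-3 and
8.9e-7 for this seed), because proximity is enriched for the APC-like
state.

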