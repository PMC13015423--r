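Package: scarsynapse
Title: MMEJ Deletion Footprint, Immune Synapse Proximity and Outcome
    Analysis for HR-Deficient Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the MMEJ Deletion Footprint (MDF), a per-tumor count
    of somatic deletions in the 6-20 bp microhomology-mediated end-joining
    size range, from VCF or MAF somatic variant calls, with cohort z-score
    standardization and quartiles.  Couples MDF to predicted neoantigen
    burden with TMB adjustment, tests CD8+ T-cell proximity to APC-like
    macrophages in spatial single-cell data against a label-permutation
    null, summarizes immune composition and program activity along a
    neoantigen-ordered trajectory, and compares strata by Kaplan-Meier,
    log-rank and restricted mean survival time.  Includes seeded synthetic
    generators for every input so each stage is testable with known ground
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    survival,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
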