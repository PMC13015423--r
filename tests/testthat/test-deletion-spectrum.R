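test_that("VCF deletions are extracted by allele-length comparison", {
  path <- write_test_vcf(data.frame(
    chrom = "1", pos = c(100L, 200L, 300L),
    ref = c("ACGTACGT", "AC", "A"),
    alt = c("A", "A", "AT")))
  recs <- parse_deletions(path, "vcf", tumor_id = "T1")
  expect_equal(recs$deletion_length, c(7L, 1L))
  expect_equal(recs$frameshift, c(TRUE, TRUE))
  expect_equal(recs$tumor_id, rep("T1", 2))  # insertion excluded
})

test_that("multi-allelic VCF records are split before comparison", {
  path <- write_test_vcf(data.frame(
    chrom = "1", pos = 500L, ref = "ACGT", alt = "A,ACGTT"))
  recs <- parse_deletions(path, "vcf", tumor_id = "T1")
  expect_equal(nrow(recs), 1L)       # deletion kept, insertion dropped
  expect_equal(recs$deletion_length, 3L)
  expect_false(recs$frameshift)
})

test_that("malformed VCF records are skipped with a warning and counted", {
  path <- write_test_vcf(data.frame(
    chrom = "1", pos = c(10L, 20L),
    ref = c("ACGT", "ACG"), alt = c("<DEL>", "A")))
  expect_warning(recs <- parse_deletions(path, "vcf", tumor_id = "T1"),
                 "skipped 1 malformed")
  expect_equal(attr(recs, "n_skipped"), 1L)
  expect_equal(recs$deletion_length, 2L)
  expect_error(parse_deletions(tempfile(), "vcf"), "not found")
})

test_that("MAF dialect handles '-' alleles and classification flags", {
  maf <- data.frame(
    Tumor_Sample_Barcode = c("T1", "T1", "T2", "T2"),
    Chromosome = "1", Start_Position = c(10L, 20L, 30L, 40L),
    Reference_Allele = c("ACGTACG", "ACT", "-", "AAAA"),
    Tumor_Seq_Allele2 = c("-", "-", "ACG", "A"),
    Variant_Type = c("DEL", "DEL", "INS", "DEL"),
    Variant_Classification = c("Frame_Shift_Del", "In_Frame_Del", "", ""),
    stringsAsFactors = FALSE)
  recs <- parse_deletions(write_test_maf(maf), "maf")
  expect_equal(recs$deletion_length, c(7L, 3L, 3L))
  # classification overrides the mod-3 rule when present
  expect_equal(recs$frameshift, c(TRUE, FALSE, FALSE))
  expect_equal(recs$tumor_id, c("T1", "T1", "T2"))
})

test_that("size bins are closed with lengths > 50 sent to overflow", {
  r <- records_from_lengths(c(3, 7, 15, 25), "A")
  s <- bin_spectrum(r)
  expect_equal(unlist(s[1, c("b1_5", "b6_13", "b14_20", "b21_50",
                             "overflow_gt50")], use.names = FALSE),
               c(1L, 1L, 1L, 1L, 0L))
  s2 <- bin_spectrum(records_from_lengths(c(6, 13, 14, 20), "A"))
  expect_equal(s2$b6_13, 2L); expect_equal(s2$b14_20, 2L)
  s3 <- bin_spectrum(records_from_lengths(55, "A"))
  expect_equal(s3$overflow_gt50, 1L)
  expect_equal(s3$b21_50, 0L)
  # bins + overflow account for every parsed deletion
  lens <- sample(1:80, 200, replace = TRUE)
  s4 <- bin_spectrum(records_from_lengths(lens, "A"))
  expect_equal(sum(s4[1, -1]), 200L)
})

test_that("manifest tumors with zero deletions get all-zero spectra", {
  r <- records_from_lengths(c(7, 8), "A")
  s <- bin_spectrum(r, tumors = c("A", "B"))
  expect_equal(s$tumor_id, c("A", "B"))
  expect_equal(s$b6_13, c(2L, 0L))
  expect_equal(sum(s[2, -1]), 0L)
})

test_that("MDF z-scores use the sample sd and quartiles follow raw order", {
  spectra <- data.frame(tumor_id = paste0("T", 1:4),
                        b6_13 = c(2L, 4L, 6L, 8L), b14_20 = 0L)
  m <- compute_mdf(spectra)
  expect_equal(m$raw_mdf, c(2L, 4L, 6L, 8L))
  # oracle: direct mean / sample-sd arithmetic
  expect_equal(m$z_mdf, c(-1.161895, -0.387298, 0.387298, 1.161895),
               tolerance = 1e-6)
  expect_equal(m$shifted_mdf, c(0, 0.774597, 1.549193, 2.323790),
               tolerance = 1e-6)
  expect_equal(min(m$shifted_mdf), 0)
  expect_equal(mean(m$z_mdf), 0, tolerance = 1e-9)
  expect_equal(stats::sd(m$z_mdf), 1, tolerance = 1e-9)
  expect_true(all(diff(m$quartile[order(m$raw_mdf)]) >= 0))
})

test_that("zero-variance cohorts and single tumors are handled", {
  spectra <- data.frame(tumor_id = paste0("T", 1:3), b6_13 = 5L, b14_20 = 0L)
  expect_warning(m <- compute_mdf(spectra), "zero")
  expect_equal(m$z_mdf, rep(0, 3))
  expect_equal(m$quartile, rep(1L, 3))
  expect_error(compute_mdf(spectra[1, ]), "at least 2")
})

test_that("MDF scores are invariant to cohort order", {
  spectra <- data.frame(tumor_id = paste0("T", 1:6),
                        b6_13 = c(3L, 0L, 4L, 6L, 0L, 5L), b14_20 = 0L)
  m1 <- compute_mdf(spectra)
  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)
  m2 <- compute_mdf(spectra[perm, ])
  expect_equal(m2[order(m2$tumor_id), ], m1[order(m1$tumor_id), ],
               ignore_attr = TRUE)
})

test_that("standardization is affine: correlations agree on raw, z, shifted", {
  set.seed(11)
  spectra <- data.frame(tumor_id = paste0("T", 1:20),
                        b6_13 = rpois(20, 8), b14_20 = rpois(20, 3))
  m <- compute_mdf(spectra)
  y <- rnorm(20)
  r_raw <- correlate(m$raw_mdf, y)$estimate
  expect_equal(correlate(m$z_mdf, y)$estimate, r_raw, tolerance = 1e-12)
  expect_equal(correlate(m$shifted_mdf, y)$estimate, r_raw,
               tolerance = 1e-12)
  expect_equal(cor(m$z_mdf, y, method = "spearman"),
               cor(m$raw_mdf, y, method = "spearman"))
})

test_that("MDF ignores insertions and SNVs in the input file", {
  base <- data.frame(chrom = "1", pos = c(10L, 50L),
                     ref = c("ACGTACGTA", "ACGTACGTACGTACGT"),
                     alt = c("A", "A"))
  noise <- data.frame(chrom = "1", pos = c(70L, 90L, 110L),
                      ref = c("A", "C", "A"),
                      alt = c("ATTTT", "G", "ACG"))
  r1 <- parse_deletions(write_test_vcf(base), "vcf", tumor_id = "T1")
  r2 <- parse_deletions(write_test_vcf(rbind(base, noise)), "vcf",
                        tumor_id = "T1")
  expect_equal(bin_spectrum(r1), bin_spectrum(r2))
})

test_that("manifest pipeline joins spectra, scores and subgroups", {
  f1 <- write_test_vcf(data.frame(chrom = "1", pos = c(1L, 2L),
                                  ref = c("ACGTACGT", "ACGTACGTACGTACG"),
                                  alt = c("A", "A")))
  f2 <- write_test_vcf(data.frame(chrom = "1", pos = 1L, ref = "AC",
                                  alt = "A"))
  manifest <- data.frame(tumor_id = c("T1", "T2"), file = c(f1, f2),
                         subgroup = c("HRD", "HRP"),
                         stringsAsFactors = FALSE)
  out <- mdf_from_manifest(manifest, "vcf")
  expect_equal(out$tumor_id, c("T1", "T2"))
  expect_equal(out$raw_mdf, c(2L, 0L))
  expect_equal(out$subgroup, c("HRD", "HRP"))
  expect_equal(min(out$shifted_mdf), 0)
})
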