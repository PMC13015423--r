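test_that("generators are pure functions of their config including seed", {
  cfg <- genomic_sim_config(n_tumors = 8, seed = 3)
  expect_identical(simulate_variant_catalogs(cfg),
                   simulate_variant_catalogs(cfg))
  sc <- spatial_sim_config(n_macrophages = 50, n_cd8 = 20, seed = 4)
  expect_identical(simulate_spatial_sample(sc), simulate_spatial_sample(sc))
  expect_identical(simulate_immune_census(4, 50, 0.5, seed = 5),
                   simulate_immune_census(4, 50, 0.5, seed = 5))
  expect_identical(simulate_survival(20, c(a = 10, b = 20), 0.05, seed = 6),
                   simulate_survival(20, c(a = 10, b = 20), 0.05, seed = 6))
  # and the caller's RNG stream is left untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_variant_catalogs(cfg))
  expect_identical(runif(1), before)
})

test_that("configs reject invalid rates, proportions and windows", {
  expect_error(genomic_sim_config(lambda_del = -1), "lambda_del")
  expect_error(genomic_sim_config(hrd_fraction = 1.2), "hrd_fraction")
  expect_error(genomic_sim_config(mmej_weight_hrd = Inf), "mmej_weight_hrd")
  expect_error(spatial_sim_config(width = 0), "area")
  expect_error(spatial_sim_config(attraction = 2), "attraction")
  expect_error(simulate_spatial_sample(
    spatial_sim_config(apc_fraction = 0, attraction = 0.5, seed = 1)),
    "APC-like")
  expect_error(simulate_immune_census(1, seed = 1), "at least 2")
  expect_error(simulate_immune_census(5, gradient_strength = 2, seed = 1),
               "gradient_strength")
  expect_error(simulate_survival(10, c(a = 0)), "positive")
})

test_that("equal class weights collapse the two deletion-length regimes", {
  tr <- simulate_variant_catalogs(genomic_sim_config(
    n_tumors = 300, lambda_del = 20, mmej_weight_hrd = 0.3,
    mmej_weight_hrp = 0.3, seed = 8))$truth
  # with equal mmej weights the binned spectra are exchangeable by class
  hrd <- colSums(tr[tr$class == "HRD", c("b1_5", "b6_13", "b14_20")])
  hrp <- colSums(tr[tr$class == "HRP", c("b1_5", "b6_13", "b14_20")])
  p <- composition_chisq(rbind(hrd, hrp))$p_value
  expect_gt(p, 0.01)
})

test_that("coupling_alpha = 0 decouples neoantigens from frameshifts", {
  tr <- simulate_variant_catalogs(genomic_sim_config(
    n_tumors = 2000, lambda_del = 10, lambda_missense = 5,
    coupling_alpha = 0, neoantigen_baseline = 8, seed = 9))$truth
  r <- correlate(tr$frameshift_deletions, tr$neoantigen_burden)$estimate
  expect_lt(abs(r), 0.1)
})

test_that("truth table is internally consistent with the variant table", {
  out <- simulate_variant_catalogs(genomic_sim_config(n_tumors = 12,
                                                      seed = 10))
  tr <- out$truth
  expect_equal(tr$b1_5 + tr$b6_13 + tr$b14_20 + tr$b21_50, tr$n_deletions)
  expect_equal(tr$tmb, (tr$n_missense + tr$n_deletions) / 30)
  dels <- out$variants[out$variants$Variant_Type == "DEL", ]
  expect_equal(as.vector(table(factor(dels$Tumor_Sample_Barcode,
                                      levels = tr$tumor_id))),
               tr$n_deletions)
  # frameshift classification matches the mod-3 rule on the allele length
  expect_equal(dels$Variant_Classification == "Frame_Shift_Del",
               nchar(dels$Reference_Allele) %% 3 != 0)
})

test_that("uniform CD8 placement matches the area-fraction expectation", {
  # oracle: E[fraction] for uniform points = mean over replicates of the
  # hit probability 1 - (1 - pi r^2 / A)^n_apc, up to boundary clipping
  n_apc <- 60
  cfg <- function(s) spatial_sim_config(
    width = 1000, height = 1000, n_macrophages = 200,
    apc_fraction = 0.3, n_cd8 = 100, attraction = 0, seed = s)
  fr <- sapply(1:200, function(s) {
    cells <- simulate_spatial_sample(cfg(s))
    cd8_proximity_fraction(cells, apc = cells$is_apc_truth %in% TRUE)
  })
  expected <- 1 - (1 - pi * 20^2 / 1e6)^n_apc
  expect_lt(abs(mean(fr) - expected), 0.01)
})

test_that("zero CD8 cells give a valid table with undefined downstream fraction", {
  cells <- simulate_spatial_sample(spatial_sim_config(n_cd8 = 0, seed = 2))
  expect_equal(sum(cells$cell_type == "CD8T"), 0)
  expect_error(cd8_proximity_fraction(cells), "no CD8")
})

test_that("APC-like ground truth matches the expression-based flag", {
  cells <- simulate_spatial_sample(spatial_sim_config(seed = 12))
  mac <- cells$cell_type == "Macrophage"
  expect_equal(flag_apc_macrophages(cells)[mac], cells$is_apc_truth[mac])
})

test_that("census composition is flat without a gradient and shifts with one", {
  ps <- sapply(1:20, function(s) {
    cen <- simulate_immune_census(6, 200, 0, seed = 8000 + s)
    composition_chisq(table(cen$cells$cell_type,
                            cen$cells$tumor_id))$p_value
  })
  expect_gte(sum(ps > 0.01), 18)
  # gradient 1: macrophage share falls with burden rank in every seed
  slopes <- sapply(1:10, function(s) {
    cen <- simulate_immune_census(10, 500, 1, seed = 8100 + s)
    prop <- tapply(cen$cells$cell_type == "Macrophage",
                   cen$cells$tumor_id, mean)
    coef(lm(prop[cen$tumors$tumor_id] ~
              rank(cen$tumors$neoantigen_burden)))[2]
  })
  expect_true(all(slopes < 0))
})

test_that("survival generator respects censoring and group medians", {
  d0 <- simulate_survival(1000, c(a = 12), censor_rate = 0, seed = 14)
  expect_true(all(d0$event == 1))
  d <- simulate_survival(2000, c(a = 12), censor_rate = 0.05, seed = 15)
  expect_true(any(d$event == 0))
  expect_true(all(d$time > 0))
  # empirical median of uncensored exponential draws near the target
  expect_lt(abs(median(d0$time) - 12), 3)
})
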