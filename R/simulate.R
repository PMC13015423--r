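#' Configuration for the somatic variant-catalog generator
#'
#' Holds the parameters of the two-regime deletion-length model.  Each
#' tumor is HRD with probability `hrd_fraction`, carries
#' `Poisson(lambda_del)` somatic deletions, and each deletion falls in the
#' microhomology-associated 6-20 bp regime (discrete uniform on 6..20)
#' with the class-specific weight, otherwise in the 1-5 bp regime
#' (discrete uniform on 1..5).  Predicted neoantigen burden is Poisson
#' with mean `coupling_alpha * frameshift_count + neoantigen_baseline`
#' (negative-binomial when `neoantigen_noise > 0`, with dispersion
#' `size = 1/neoantigen_noise`).
#'
#' @param n_tumors number of tumors.
#' @param hrd_fraction probability a tumor is HRD (vs HRP).
#' @param lambda_del expected somatic deletions per tumor.
#' @param mmej_weight_hrd,mmej_weight_hrp probability that a deletion in an
#'   HRD (resp. HRP) tumor is drawn from the 6-20 bp regime.
#' @param coupling_alpha expected neoantigens contributed per frameshift
#'   deletion.
#' @param neoantigen_baseline baseline expected neoantigens independent of
#'   frameshift deletions.
#' @param lambda_missense expected missense mutations per tumor.
#' @param neoantigen_noise overdispersion of the neoantigen count; 0 gives
#'   a pure Poisson.
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return a list of class `genomic_sim_config`.
#' @export
genomic_sim_config <- function(n_tumors = 60,
                               hrd_fraction = 0.5,
                               lambda_del = 40,
                               mmej_weight_hrd = 0.6,
                               mmej_weight_hrp = 0.05,
                               coupling_alpha = 0.5,
                               neoantigen_baseline = 2,
                               lambda_missense = 50,
                               neoantigen_noise = 0,
                               seed = NULL) {
  cfg <- list(
    n_tumors = .check_count(n_tumors, "n_tumors"),
    hrd_fraction = .check_prop(hrd_fraction, "hrd_fraction"),
    lambda_del = .check_rate(lambda_del, "lambda_del"),
    mmej_weight_hrd = .check_prop(mmej_weight_hrd, "mmej_weight_hrd"),
    mmej_weight_hrp = .check_prop(mmej_weight_hrp, "mmej_weight_hrp"),
    coupling_alpha = .check_rate(coupling_alpha, "coupling_alpha"),
    neoantigen_baseline = .check_rate(neoantigen_baseline, "neoantigen_baseline"),
    lambda_missense = .check_rate(lambda_missense, "lambda_missense"),
    neoantigen_noise = .check_rate(neoantigen_noise, "neoantigen_noise"),
    seed = seed)
  class(cfg) <- "genomic_sim_config"
  cfg
}

#' Simulate per-tumor somatic variant catalogs with known ground truth
#'
#' Generates a MAF-like variant table (deletions plus missense SNVs) and a
#' truth table recording every latent quantity: tumor class, binned
#' deletion counts, frameshift-deletion count, neoantigen burden and TMB.
#' TMB is `(missense + indels) / 30` mutations per Mb for an assumed 30 Mb
#' exome.
#'
#' @param config a [genomic_sim_config()].
#' @return list with elements `variants` (MAF-like data frame with columns
#'   Tumor_Sample_Barcode, Chromosome, Start_Position, Reference_Allele,
#'   Tumor_Seq_Allele2, Variant_Type, Variant_Classification) and `truth`
#'   (one row per tumor).
#' @export
simulate_variant_catalogs <- function(config) {
  stopifnot(inherits(config, "genomic_sim_config"))
  with_rng_seed(config$seed, {
    n <- config$n_tumors
    tumor_id <- sprintf("T%03d", seq_len(n))
    class <- ifelse(stats::runif(n) < config$hrd_fraction, "HRD", "HRP")
    w <- ifelse(class == "HRD", config$mmej_weight_hrd, config$mmej_weight_hrp)
    n_del <- stats::rpois(n, config$lambda_del)
    n_mis <- stats::rpois(n, config$lambda_missense)

    per_tumor <- vector("list", n)
    truth <- data.frame(
      tumor_id = tumor_id, class = class, n_deletions = n_del,
      b1_5 = 0L, b6_13 = 0L, b14_20 = 0L, b21_50 = 0L,
      frameshift_deletions = 0L, n_missense = n_mis,
      neoantigen_burden = 0L, tmb = 0,
      stringsAsFactors = FALSE)

    for (i in seq_len(n)) {
      k <- n_del[i]
      mmej <- stats::runif(k) < w[i]
      len <- integer(k)
      len[mmej]  <- sample(6:20, sum(mmej),  replace = TRUE)
      len[!mmej] <- sample(1:5,  sum(!mmej), replace = TRUE)
      fs <- len %% 3L != 0L
      truth$b1_5[i]   <- sum(len >= 1 & len <= 5)
      truth$b6_13[i]  <- sum(len >= 6 & len <= 13)
      truth$b14_20[i] <- sum(len >= 14 & len <= 20)
      truth$b21_50[i] <- sum(len >= 21 & len <= 50)
      truth$frameshift_deletions[i] <- sum(fs)
      mu <- config$coupling_alpha * sum(fs) + config$neoantigen_baseline
      truth$neoantigen_burden[i] <- if (config$neoantigen_noise > 0) {
        stats::rnbinom(1L, size = 1 / config$neoantigen_noise, mu = mu)
      } else {
        stats::rpois(1L, mu)
      }
      truth$tmb[i] <- (n_mis[i] + k) / 30

      dels <- data.frame(
        Tumor_Sample_Barcode = rep(tumor_id[i], k),
        Chromosome = as.character(sample(1:22, k, replace = TRUE)),
        Start_Position = sample.int(1e8L, k, replace = TRUE),
        Reference_Allele = strrep("A", len),
        Tumor_Seq_Allele2 = rep("-", k),
        Variant_Type = rep("DEL", k),
        Variant_Classification = ifelse(fs, "Frame_Shift_Del", "In_Frame_Del"),
        stringsAsFactors = FALSE)
      m <- n_mis[i]
      snvs <- data.frame(
        Tumor_Sample_Barcode = rep(tumor_id[i], m),
        Chromosome = as.character(sample(1:22, m, replace = TRUE)),
        Start_Position = sample.int(1e8L, m, replace = TRUE),
        Reference_Allele = rep("A", m),
        Tumor_Seq_Allele2 = rep("T", m),
        Variant_Type = rep("SNP", m),
        Variant_Classification = rep("Missense_Mutation", m),
        stringsAsFactors = FALSE)
      per_tumor[[i]] <- rbind(dels, snvs)
    }
    list(variants = do.call(rbind, c(per_tumor, list(make.row.names = FALSE))),
         truth = truth)
  })
}

#' Configuration for the spatial point-pattern generator
#'
#' Null/alternative models for CD8 T-cell attraction to APC-like
#' macrophages on a planar window.  Macrophages are uniform on the window;
#' `apc_fraction` of them are APC-like (both HLA-DRA and CD74 strictly
#' positive on the log1p scale; the rest have at least one gene at 0).
#' Each CD8 cell is placed, with probability `attraction`, at a random
#' APC-like macrophage plus an isotropic Gaussian displacement of scale
#' `sigma` (clipped to the window), otherwise uniformly.  After placement,
#' macrophages within 20 um of any CD8 cell receive `+expr_effect` on both
#' genes.
#'
#' @param width,height window dimensions in micrometers.
#' @param n_macrophages,n_cd8 cell counts.
#' @param apc_fraction fraction of macrophages that are APC-like.
#' @param attraction probability a CD8 cell is attracted; 0 gives uniform
#'   CD8 placement.
#' @param sigma Gaussian displacement scale (um) for attracted CD8 cells.
#' @param expr_effect additive log1p expression increment for CD8-proximal
#'   macrophages; 0 makes expression independent of geometry.
#' @param seed RNG seed.
#' @return a list of class `spatial_sim_config`.
#' @export
spatial_sim_config <- function(width = 500, height = 500,
                               n_macrophages = 300, apc_fraction = 0.3,
                               n_cd8 = 150, attraction = 0, sigma = 5,
                               expr_effect = 0, seed = NULL) {
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0)
    stop("window area must be positive", call. = FALSE)
  cfg <- list(
    width = width, height = height,
    n_macrophages = .check_count(n_macrophages, "n_macrophages"),
    apc_fraction = .check_prop(apc_fraction, "apc_fraction"),
    n_cd8 = .check_count(n_cd8, "n_cd8"),
    attraction = .check_prop(attraction, "attraction"),
    sigma = .check_rate(sigma, "sigma"),
    expr_effect = .check_rate(expr_effect, "expr_effect"),
    seed = seed)
  class(cfg) <- "spatial_sim_config"
  cfg
}

#' Simulate a spatially resolved single-cell sample
#'
#' @param config a [spatial_sim_config()].
#' @param sample_id sample label stored in the table.
#' @return data frame with columns cell_id, sample_id, x_um, y_um,
#'   cell_type (`Macrophage` / `CD8T`), is_apc_truth (ground-truth
#'   APC-like flag, `NA` for CD8 cells), `HLA-DRA`, `CD74`.
#' @export
simulate_spatial_sample <- function(config, sample_id = "S1") {
  stopifnot(inherits(config, "spatial_sim_config"))
  n_apc <- round(config$n_macrophages * config$apc_fraction)
  if (config$attraction > 0 && n_apc == 0)
    stop("attraction > 0 requires at least one APC-like macrophage",
         call. = FALSE)
  with_rng_seed(config$seed, {
    nm <- config$n_macrophages
    mx <- stats::runif(nm, 0, config$width)
    my <- stats::runif(nm, 0, config$height)
    is_apc <- rep(FALSE, nm)
    if (n_apc > 0) is_apc[sample.int(nm, n_apc)] <- TRUE

    # strictly positive co-expression for APC-like; at least one zero gene
    # for the others so the ground truth matches the expression-based flag
    dra <- cd74 <- numeric(nm)
    dra[is_apc]  <- 0.2 + stats::rexp(n_apc, 1.5)
    cd74[is_apc] <- 0.2 + stats::rexp(n_apc, 1.5)
    zero_mode <- sample(3L, nm - n_apc, replace = TRUE)  # 1: DRA=0, 2: CD74=0, 3: both
    others <- which(!is_apc)
    dra[others]  <- ifelse(zero_mode == 2L, stats::rexp(nm - n_apc, 2), 0)
    cd74[others] <- ifelse(zero_mode == 1L, stats::rexp(nm - n_apc, 2), 0)

    nc <- config$n_cd8
    cx <- stats::runif(nc, 0, config$width)
    cy <- stats::runif(nc, 0, config$height)
    if (config$attraction > 0 && nc > 0) {
      pull <- stats::runif(nc) < config$attraction
      k <- sum(pull)
      if (k > 0) {
        anchor <- sample(which(is_apc), k, replace = TRUE)
        cx[pull] <- pmin(pmax(mx[anchor] + stats::rnorm(k, 0, config$sigma), 0),
                         config$width)
        cy[pull] <- pmin(pmax(my[anchor] + stats::rnorm(k, 0, config$sigma), 0),
                         config$height)
      }
    }

    if (config$expr_effect > 0 && nc > 0 && nm > 0) {
      nbr <- radius_neighbors(mx, my, cx, cy, radius = 20)
      prox <- lengths(nbr) > 0
      dra[prox] <- dra[prox] + config$expr_effect
      cd74[prox] <- cd74[prox] + config$expr_effect
    }

    out <- data.frame(
      cell_id = sprintf("c%05d", seq_len(nm + nc)),
      sample_id = sample_id,
      x_um = c(mx, cx), y_um = c(my, cy),
      cell_type = c(rep("Macrophage", nm), rep("CD8T", nc)),
      is_apc_truth = c(is_apc, rep(NA, nc)),
      stringsAsFactors = FALSE, check.names = FALSE)
    out[["HLA-DRA"]] <- c(dra, rep(0, nc))
    out[["CD74"]] <- c(cd74, rep(0, nc))
    out
  })
}

# immune cell types used by the census generator
.census_types <- c("Macrophage", "CD8T", "CD4T", "B", "NKT", "Treg")
.census_genes <- c("HLA-DRA", "CD74", "B2M", "IFNG", "STAT1", "GZMB", "PRF1")

#' Simulate a single-nucleus-style immune census along a neoantigen gradient
#'
#' Tumors receive increasing neoantigen burdens (log-spaced 5..80).  The
#' cell-type composition interpolates from a macrophage-dominant state
#' (70% macrophage, the remainder split over CD8T/CD4T/B/NKT/Treg) to an
#' immune-diverse state (10% macrophage) as burden rises;
#' `gradient_strength` in [0, 1] scales the interpolation (0 freezes the
#' composition at the macrophage-dominant state for every tumor).
#' Tumor-level shifted MDF rises with burden plus Gaussian noise.
#' Expression for a small program-gene panel is generated on the log1p
#' scale with cell-type effects (antigen presentation genes higher in
#' macrophages, cytolytic genes higher in CD8T/NKT) plus a gradient
#' effect.
#'
#' @param n_tumors number of tumors (>= 2).
#' @param cells_per_tumor cells per tumor.
#' @param gradient_strength in [0, 1].
#' @param seed RNG seed.
#' @return list with `cells` (cell_id, tumor_id, cell_type, gene columns)
#'   and `tumors` (tumor_id, neoantigen_burden, shifted_mdf).
#' @export
simulate_immune_census <- function(n_tumors, cells_per_tumor = 500,
                                   gradient_strength = 1, seed = NULL) {
  n_tumors <- .check_count(n_tumors, "n_tumors")
  if (n_tumors < 2) stop("need at least 2 tumors", call. = FALSE)
  cells_per_tumor <- .check_count(cells_per_tumor, "cells_per_tumor")
  if (!is.numeric(gradient_strength) || length(gradient_strength) != 1L ||
      !is.finite(gradient_strength) || gradient_strength < 0 ||
      gradient_strength > 1)
    stop("gradient_strength must be in [0, 1]", call. = FALSE)
  with_rng_seed(seed, {
    tumor_id <- sprintf("T%02d", seq_len(n_tumors))
    u <- (seq_len(n_tumors) - 1) / (n_tumors - 1)
    burden <- round(exp(log(5) + u * (log(80) - log(5))))
    shifted_mdf <- pmax(0, 0.2 + 2.5 * u + stats::rnorm(n_tumors, 0, 0.2))

    cells <- vector("list", n_tumors)
    for (i in seq_len(n_tumors)) {
      m_share <- 0.7 - gradient_strength * u[i] * 0.6
      probs <- c(m_share, rep((1 - m_share) / 5, 5))
      type <- sample(.census_types, cells_per_tumor, replace = TRUE,
                     prob = probs)
      expr <- matrix(pmax(0, stats::rnorm(cells_per_tumor *
                                            length(.census_genes), 1, 0.3)),
                     nrow = cells_per_tumor,
                     dimnames = list(NULL, .census_genes))
      apc_genes <- c("HLA-DRA", "CD74", "B2M")
      cyt_genes <- c("GZMB", "PRF1")
      expr[type == "Macrophage", apc_genes] <-
        expr[type == "Macrophage", apc_genes] + 0.8
      expr[type %in% c("CD8T", "NKT"), cyt_genes] <-
        expr[type %in% c("CD8T", "NKT"), cyt_genes] + 0.8
      expr <- expr + gradient_strength * u[i] * 0.5
      df <- data.frame(tumor_id = tumor_id[i], cell_type = type,
                       stringsAsFactors = FALSE)
      cells[[i]] <- cbind(df, as.data.frame(expr, check.names = FALSE))
    }
    cells <- do.call(rbind, c(cells, list(make.row.names = FALSE)))
    cells <- cbind(cell_id = sprintf("c%06d", seq_len(nrow(cells))), cells,
                   stringsAsFactors = FALSE)
    list(cells = cells,
         tumors = data.frame(tumor_id = tumor_id,
                             neoantigen_burden = burden,
                             shifted_mdf = shifted_mdf,
                             stringsAsFactors = FALSE))
  })
}

#' Simulate grouped survival data with exponential event and censoring times
#'
#' Event times are exponential with rate `log(2) / median`; censoring
#' times are independent exponential with rate `censor_rate` (0 means no
#' censoring).  Observed time is the minimum; the event indicator is 1
#' when the event precedes censoring.
#'
#' @param n_per_group subjects per group (recycled over groups).
#' @param median_by_group named numeric vector of median event times
#'   (months) per group; names become group labels.
#' @param censor_rate exponential censoring rate per month.
#' @param seed RNG seed.
#' @return data frame with subject_id, time, event, group.
#' @export
simulate_survival <- function(n_per_group, median_by_group, censor_rate = 0,
                              seed = NULL) {
  if (any(!is.finite(median_by_group)) || any(median_by_group <= 0))
    stop("medians must be positive", call. = FALSE)
  censor_rate <- .check_rate(censor_rate, "censor_rate")
  groups <- names(median_by_group)
  if (is.null(groups)) groups <- paste0("g", seq_along(median_by_group))
  n_per_group <- rep_len(n_per_group, length(median_by_group))
  with_rng_seed(seed, {
    out <- lapply(seq_along(median_by_group), function(i) {
      n <- n_per_group[i]
      ev <- stats::rexp(n, rate = log(2) / median_by_group[i])
      cs <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
      data.frame(group = groups[i],
                 time = pmin(ev, cs),
                 event = as.integer(ev <= cs),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    cbind(subject_id = sprintf("s%04d", seq_len(nrow(out))),
          out[c("time", "event", "group")], stringsAsFactors = FALSE)
  })
}
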