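#' Parse somatic deletions from a VCF or MAF file
#'
#' Extracts one record per deleted allele by comparing reference and
#' alternate allele lengths.  Multi-allelic VCF records are split before
#' the comparison; insertions and length-preserving substitutions are
#' excluded.  Complex substitutions where the reference is longer than the
#' alternate are kept as deletions of the net length difference.
#'
#' For the MAF dialect, rows with `Variant_Type == "DEL"` and
#' `Tumor_Seq_Allele2 == "-"` have deletion length equal to
#' `nchar(Reference_Allele)`; other rows are compared by allele length
#' (with `-` counting as length 0).  The frameshift flag comes from
#' `Variant_Classification` (`Frame_Shift_Del`) when that column is
#' present, otherwise from `length %% 3 != 0`.
#'
#' Malformed records are skipped with a warning and counted in the
#' `n_skipped` attribute; a file that does not parse at all is an error.
#'
#' @param variant_file path to a VCF 4.x file (optionally bgzipped) or a
#'   MAF TSV.
#' @param dialect `"vcf"` or `"maf"`.
#' @param tumor_id tumor identifier for VCF input (defaults to the first
#'   sample name in the VCF, or the file basename when the VCF carries no
#'   samples).  Ignored for MAF, which carries `Tumor_Sample_Barcode`.
#' @return data frame of deletion records: tumor_id, chrom, pos, ref_len,
#'   alt_len, deletion_length, frameshift; attribute `n_skipped` counts
#'   malformed records.
#' @export
parse_deletions <- function(variant_file, dialect = c("vcf", "maf"),
                            tumor_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(variant_file))
    stop("file not found: ", variant_file, call. = FALSE)
  if (dialect == "vcf") {
    .parse_deletions_vcf(variant_file, tumor_id)
  } else {
    .parse_deletions_maf(variant_file)
  }
}

.empty_deletions <- function() {
  data.frame(tumor_id = character(), chrom = character(), pos = integer(),
             ref_len = integer(), alt_len = integer(),
             deletion_length = integer(), frameshift = logical(),
             stringsAsFactors = FALSE)
}

.parse_deletions_vcf <- function(path, tumor_id) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("failed to parse VCF: ",
                                           conditionMessage(e), call. = FALSE))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (is.null(tumor_id)) {
    samples <- colnames(vcf@gt)
    samples <- setdiff(samples, "FORMAT")
    tumor_id <- if (length(samples) >= 1) samples[1] else
      sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  if (nrow(fix) == 0) return(.empty_deletions())

  n_skipped <- 0L
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix$REF[i]; alt <- fix$ALT[i]
    pos <- suppressWarnings(as.integer(fix$POS[i]))
    if (is.na(ref) || is.na(alt) || is.na(pos) ||
        !grepl("^[ACGTNacgtn]+$", ref)) {
      n_skipped <- n_skipped + 1L
      next
    }
    alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
    ok <- grepl("^[ACGTNacgtn]+$", alts)
    n_skipped <- n_skipped + sum(!ok)
    alts <- alts[ok]
    dl <- nchar(ref) - nchar(alts)
    keep <- dl > 0
    if (!any(keep)) next
    rows[[i]] <- data.frame(
      tumor_id = tumor_id, chrom = fix$CHROM[i], pos = pos,
      ref_len = nchar(ref), alt_len = nchar(alts[keep]),
      deletion_length = dl[keep],
      frameshift = dl[keep] %% 3L != 0L,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  if (is.null(out)) out <- .empty_deletions()
  if (n_skipped > 0)
    warning(sprintf("skipped %d malformed record(s) in %s", n_skipped,
                    basename(path)), call. = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

.parse_deletions_maf <- function(path) {
  maf <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop("failed to parse MAF: ", conditionMessage(e),
                             call. = FALSE))
  needed <- c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
              "Reference_Allele", "Tumor_Seq_Allele2")
  if (!all(needed %in% names(maf)))
    stop("MAF is missing required columns: ",
         paste(setdiff(needed, names(maf)), collapse = ", "), call. = FALSE)
  if (nrow(maf) == 0) return(.empty_deletions())

  allele_len <- function(a) ifelse(is.na(a) | a == "-" | a == "", 0L, nchar(a))
  ref_len <- allele_len(maf$Reference_Allele)
  alt_len <- allele_len(maf$Tumor_Seq_Allele2)
  dl <- ref_len - alt_len
  bad <- is.na(dl) | is.na(maf$Start_Position)
  keep <- !bad & dl > 0
  n_skipped <- sum(bad)
  fs <- dl %% 3L != 0L
  if ("Variant_Classification" %in% names(maf)) {
    vc <- maf$Variant_Classification
    fs <- ifelse(!is.na(vc) & vc %in% c("Frame_Shift_Del", "In_Frame_Del"),
                 vc == "Frame_Shift_Del", fs)
  }
  out <- data.frame(
    tumor_id = maf$Tumor_Sample_Barcode[keep],
    chrom = as.character(maf$Chromosome[keep]),
    pos = as.integer(maf$Start_Position[keep]),
    ref_len = ref_len[keep], alt_len = alt_len[keep],
    deletion_length = as.integer(dl[keep]),
    frameshift = fs[keep],
    stringsAsFactors = FALSE)
  if (n_skipped > 0)
    warning(sprintf("skipped %d malformed record(s) in %s", n_skipped,
                    basename(path)), call. = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Bin somatic deletions by size per tumor
#'
#' Counts deletions in the closed size bins 1-5, 6-13, 14-20 and 21-50 bp;
#' lengths above 50 bp go to an overflow column kept for QC only and never
#' enter the MDF.  Tumors listed in `tumors` but absent from `records`
#' receive an all-zero spectrum.
#'
#' @param records deletion records from [parse_deletions()] (possibly
#'   concatenated across tumors).
#' @param tumors optional character vector of cohort tumor ids (the
#'   manifest); defaults to the tumors present in `records`.
#' @return data frame with columns tumor_id, b1_5, b6_13, b14_20, b21_50,
#'   overflow_gt50.
#' @export
bin_spectrum <- function(records, tumors = NULL) {
  if (is.null(tumors)) tumors <- unique(records$tumor_id)
  out <- data.frame(tumor_id = tumors, b1_5 = 0L, b6_13 = 0L, b14_20 = 0L,
                    b21_50 = 0L, overflow_gt50 = 0L, stringsAsFactors = FALSE)
  if (!is.null(records) && nrow(records) > 0) {
    stopifnot(all(records$deletion_length >= 1))
    b <- findInterval(records$deletion_length, c(1, 6, 14, 21, 51))
    tab <- table(factor(records$tumor_id, levels = tumors),
                 factor(b, levels = 1:5))
    out$b1_5 <- as.integer(tab[, 1]); out$b6_13 <- as.integer(tab[, 2])
    out$b14_20 <- as.integer(tab[, 3]); out$b21_50 <- as.integer(tab[, 4])
    out$overflow_gt50 <- as.integer(tab[, 5])
  }
  out
}

#' Compute the MMEJ Deletion Footprint for a cohort
#'
#' The raw MDF is the summed deletion count in the 6-13 and 14-20 bp bins.
#' Raw counts are standardized across the cohort with a z-score (sample
#' standard deviation) and shifted so the cohort minimum maps to zero; the
#' shift is affine, so downstream correlations and rank statistics are
#' identical on raw, z or shifted values.  Quartiles are assigned from the
#' standardized values using linear-interpolation empirical quantiles at
#' probabilities 0.25/0.5/0.75, with values at a boundary going to the
#' lower quartile.  `mdf_high` flags tumors strictly above the cohort
#' median.
#'
#' @param spectra output of [bin_spectrum()] for >= 2 tumors.
#' @return data frame with tumor_id, raw_mdf, z_mdf, shifted_mdf,
#'   quartile, mdf_high.
#' @export
compute_mdf <- function(spectra) {
  stopifnot(all(c("tumor_id", "b6_13", "b14_20") %in% names(spectra)))
  if (nrow(spectra) < 2)
    stop("MDF standardization needs a cohort of at least 2 tumors",
         call. = FALSE)
  raw <- spectra$b6_13 + spectra$b14_20
  s <- stats::sd(raw)
  if (s == 0) {
    warning("cohort MDF standard deviation is zero; all z-scores set to 0",
            call. = FALSE)
    z <- rep(0, length(raw))
  } else {
    z <- (raw - mean(raw)) / s
  }
  q <- stats::quantile(z, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  quartile <- 1L + (z > q[1]) + (z > q[2]) + (z > q[3])
  data.frame(tumor_id = spectra$tumor_id,
             raw_mdf = as.integer(raw),
             z_mdf = z,
             shifted_mdf = z - min(z),
             quartile = as.integer(quartile),
             mdf_high = z > q[2],
             stringsAsFactors = FALSE)
}

#' Deletion spectra and MDF scores for a cohort manifest
#'
#' Convenience wrapper: parses every file in the manifest, bins the
#' deletions (tumors with no deletions get all-zero spectra) and computes
#' cohort MDF scores.  The standardization cohort is exactly the set of
#' tumors in the manifest; pooling discovery and validation cohorts is the
#' caller's choice of manifest.
#'
#' @param manifest data frame with columns tumor_id, file and optionally
#'   subgroup.
#' @param dialect `"vcf"` or `"maf"`.
#' @return data frame joining the spectrum and MDF columns (plus subgroup
#'   when present in the manifest).
#' @export
mdf_from_manifest <- function(manifest, dialect = c("vcf", "maf")) {
  dialect <- match.arg(dialect)
  stopifnot(all(c("tumor_id", "file") %in% names(manifest)))
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- parse_deletions(manifest$file[i], dialect,
                         tumor_id = manifest$tumor_id[i])
    if (nrow(r) > 0) r$tumor_id <- manifest$tumor_id[i]
    r
  })
  recs <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  spectra <- bin_spectrum(recs, tumors = manifest$tumor_id)
  scores <- compute_mdf(spectra)
  out <- merge(spectra, scores, by = "tumor_id", sort = FALSE)
  if ("subgroup" %in% names(manifest))
    out <- merge(out, manifest[c("tumor_id", "subgroup")], by = "tumor_id",
                 sort = FALSE)
  out[match(manifest$tumor_id, out$tumor_id), , drop = FALSE]
}
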