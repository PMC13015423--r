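#' Order immune cells along a tumor-level neoantigen gradient and bin them
#'
#' Pools the cells of all tumors, sorts them by (tumor neoantigen burden
#' ascending, tumor_id, stable input order) and splits the sorted sequence
#' into `n_bins` contiguous blocks of near-equal size: the first
#' `total %% n_bins` bins receive one extra cell.  Each tumor contributes
#' according to its cellular composition; tumors are never reweighted.
#'
#' @param cells cell table with a `tumor_id` column.
#' @param burden named numeric vector of neoantigen burdens (names =
#'   tumor ids), or a data frame with columns tumor_id and
#'   neoantigen_burden.
#' @param n_bins number of trajectory bins (>= 1, <= number of cells).
#' @return integer vector of bin indices (1..n_bins), one per row of
#'   `cells`, in the original row order.
#' @export
order_and_bin <- function(cells, burden, n_bins = 30) {
  if (is.data.frame(burden)) {
    stopifnot(all(c("tumor_id", "neoantigen_burden") %in% names(burden)))
    burden <- stats::setNames(burden$neoantigen_burden, burden$tumor_id)
  }
  missing <- setdiff(unique(cells$tumor_id), names(burden))
  if (length(missing) > 0)
    stop("no neoantigen burden for tumor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  total <- nrow(cells)
  if (n_bins < 1 || n_bins > total)
    stop("n_bins must be between 1 and the number of cells", call. = FALSE)
  ord <- order(burden[cells$tumor_id], cells$tumor_id, seq_len(total))
  base <- total %/% n_bins
  extra <- total %% n_bins
  sizes <- rep.int(base, n_bins) + c(rep.int(1L, extra),
                                     rep.int(0L, n_bins - extra))
  bin_sorted <- rep.int(seq_len(n_bins), sizes)
  bins <- integer(total)
  bins[ord] <- bin_sorted
  bins
}

#' Module score for a curated gene set
#'
#' Each gene's expression is z-scored across all cells (a zero-variance
#' gene contributes 0) and the per-cell score is the mean over the genes
#' of the set present in the table.  Absent genes are dropped with a
#' warning; an empty intersection is an error.
#'
#' @param cells cell table with one column per gene.
#' @param gene_set character vector of gene names.
#' @return numeric score per cell.
#' @export
module_score <- function(cells, gene_set) {
  present <- intersect(gene_set, names(cells))
  absent <- setdiff(gene_set, names(cells))
  if (length(present) == 0)
    stop("none of the genes in the set are present in the table",
         call. = FALSE)
  if (length(absent) > 0)
    warning("dropping absent gene(s): ", paste(absent, collapse = ", "),
            call. = FALSE)
  z <- vapply(present, function(g) {
    v <- cells[[g]]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }, numeric(nrow(cells)))
  if (is.null(dim(z))) z <- matrix(z, ncol = length(present))
  rowMeans(z)
}

#' Shannon entropy of a proportion vector, in bits
#'
#' `H = -sum(p * log2(p))` with the `0 * log 0 = 0` convention.
#'
#' @param p proportions (need not be normalized; normalized internally).
#' @return entropy in bits.
#' @export
shannon_entropy <- function(p) {
  p <- p[p > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Summarize trajectory bins: composition, entropy, programs, mean MDF
#'
#' For every bin: the number of cells, the cell-type proportions (over the
#' types present in the whole table), Shannon entropy of the composition
#' in bits, the mean module score of each program (scores are z-scored
#' across all cells jointly, then averaged within bin), and the mean
#' tumor-level shifted MDF over the cells of the bin.
#'
#' @param bins integer bin assignment from [order_and_bin()].
#' @param cells the cell table the assignment was computed on.
#' @param mdf named numeric vector of tumor-level shifted MDF (names =
#'   tumor ids), or a data frame with columns tumor_id and shifted_mdf.
#' @param programs named list of gene sets (program name -> character
#'   vector); may be empty.
#' @return data frame with one row per bin: bin_index, n_cells, one
#'   `prop_<type>` column per cell type, entropy_bits, one
#'   `score_<program>` column per program, mean_mdf.
#' @export
summarize_bins <- function(bins, cells, mdf = NULL, programs = list()) {
  stopifnot(length(bins) == nrow(cells))
  if (is.data.frame(mdf)) {
    stopifnot(all(c("tumor_id", "shifted_mdf") %in% names(mdf)))
    mdf <- stats::setNames(mdf$shifted_mdf, mdf$tumor_id)
  }
  types <- sort(unique(cells$cell_type))
  n_bins <- max(bins)
  scores <- lapply(programs, function(gs) module_score(cells, gs))
  rows <- lapply(seq_len(n_bins), function(b) {
    idx <- which(bins == b)
    comp <- as.vector(table(factor(cells$cell_type[idx], levels = types)))
    comp <- comp / length(idx)
    row <- data.frame(bin_index = b, n_cells = length(idx))
    for (k in seq_along(types)) row[[paste0("prop_", types[k])]] <- comp[k]
    row$entropy_bits <- shannon_entropy(comp)
    for (nm in names(programs))
      row[[paste0("score_", nm)]] <- mean(scores[[nm]][idx])
    row$mean_mdf <- if (is.null(mdf)) NA_real_ else
      mean(mdf[cells$tumor_id[idx]])
    row
  })
  do.call(rbind, rows)
}
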