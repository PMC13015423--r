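#' Radius neighbors between two planar point sets
#'
#' For each query point, returns the indices of reference points within
#' `radius` (inclusive) in Euclidean distance.  The default grid method
#' buckets reference points into radius-sized cells and inspects the 3x3
#' cell neighborhood of each query; it returns exactly the same inclusion
#' sets as the brute-force all-pairs method, which is retained for
#' cross-checking.
#'
#' @param qx,qy query coordinates (um).
#' @param rx,ry reference coordinates (um).
#' @param radius inclusive search radius (um).
#' @param method `"grid"` or `"brute"`.
#' @return list (length = number of queries) of integer index vectors into
#'   the reference set.
#' @export
radius_neighbors <- function(qx, qy, rx, ry, radius,
                             method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(radius > 0, length(qx) == length(qy), length(rx) == length(ry))
  nq <- length(qx); nr <- length(rx)
  if (nq == 0) return(list())
  if (nr == 0) return(rep(list(integer(0)), nq))
  r2 <- radius^2
  if (method == "brute") {
    return(lapply(seq_len(nq), function(i) {
      which((rx - qx[i])^2 + (ry - qy[i])^2 <= r2)
    }))
  }
  cell <- function(x, y) paste(floor(x / radius), floor(y / radius))
  buckets <- split(seq_len(nr), cell(rx, ry))
  cxi <- floor(qx / radius); cyi <- floor(qy / radius)
  lapply(seq_len(nq), function(i) {
    keys <- as.vector(outer(cxi[i] + (-1:1), cyi[i] + (-1:1), paste))
    cand <- unlist(buckets[keys], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0) return(integer(0))
    cand <- sort(cand)
    cand[(rx[cand] - qx[i])^2 + (ry[cand] - qy[i])^2 <= r2]
  })
}

.get_gene <- function(cells, gene) {
  if (!gene %in% names(cells))
    stop("expression column missing: ", gene, call. = FALSE)
  cells[[gene]]
}

#' Flag APC-like macrophages
#'
#' A macrophage is APC-like when it co-expresses HLA-DRA and CD74, i.e.
#' both genes strictly positive on the log1p scale.  Non-macrophage cells
#' are never flagged regardless of expression.
#'
#' @param cells spatial cell table with columns cell_type and one column
#'   per gene.
#' @param genes the two co-expression genes.
#' @return logical vector, one entry per row of `cells`.
#' @export
flag_apc_macrophages <- function(cells, genes = c("HLA-DRA", "CD74")) {
  is_mac <- cells$cell_type == "Macrophage"
  g1 <- .get_gene(cells, genes[1]); g2 <- .get_gene(cells, genes[2])
  if (any(is_mac & (is.na(g1) | is.na(g2))))
    stop("macrophage rows with missing expression for ",
         paste(genes, collapse = "/"), call. = FALSE)
  is_mac & g1 > 0 & g2 > 0
}

#' Fraction of CD8 T cells within a radius of an APC-like macrophage
#'
#' The observed spatial statistic: the fraction of CD8 cells whose
#' distance to the nearest APC-like macrophage is at most `radius_um`
#' (inclusive boundary).
#'
#' @param cells spatial cell table.
#' @param radius_um search radius in micrometers.
#' @param apc logical APC-like flag per row; computed from expression via
#'   [flag_apc_macrophages()] when `NULL`.
#' @param method neighbor-search method passed to [radius_neighbors()].
#' @return the observed fraction in [0, 1].
#' @export
cd8_proximity_fraction <- function(cells, radius_um = 20, apc = NULL,
                                   method = c("grid", "brute")) {
  method <- match.arg(method)
  cd8 <- which(cells$cell_type == "CD8T")
  if (length(cd8) == 0)
    stop("no CD8 cells: proximity fraction undefined", call. = FALSE)
  if (is.null(apc)) apc <- flag_apc_macrophages(cells)
  idx <- which(apc)
  if (length(idx) == 0) {
    warning("no APC-like macrophages; fraction is 0", call. = FALSE)
    return(0)
  }
  nbr <- radius_neighbors(cells$x_um[cd8], cells$y_um[cd8],
                          cells$x_um[idx], cells$y_um[idx],
                          radius = radius_um, method = method)
  mean(lengths(nbr) > 0)
}

#' Permutation null test of CD8 to APC-like macrophage proximity
#'
#' Tests whether the observed CD8-near-APC fraction exceeds chance under a
#' geometry-preserving null: every cell keeps its position and the
#' APC-like labels are reassigned uniformly at random among all
#' macrophages, preserving the APC count.  The empirical p-value is the
#' proportion of permuted fractions greater than or equal to the observed
#' one (`add_one = TRUE` uses the strictly positive (k+1)/(n+1)
#' estimator instead).
#'
#' @param cells spatial cell table for one sample.
#' @param radius_um radius in micrometers.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @param add_one use the (k+1)/(n+1) p-value estimator.
#' @return object of class `proximity_result`: sample_id,
#'   observed_fraction, n_cd8, n_macrophage, n_apc, radius_um,
#'   null_fractions, empirical_p, seed.
#' @export
permutation_null_test <- function(cells, radius_um = 20, n_perm = 500,
                                  seed = NULL, add_one = FALSE) {
  stopifnot(n_perm >= 1)
  mac <- which(cells$cell_type == "Macrophage")
  cd8 <- which(cells$cell_type == "CD8T")
  if (length(cd8) == 0)
    stop("no CD8 cells: proximity statistic undefined", call. = FALSE)
  apc <- flag_apc_macrophages(cells)
  n_apc <- sum(apc)
  if (n_apc == 0)
    stop("no APC-like macrophages: permutation null undefined", call. = FALSE)
  if (n_apc == length(mac))
    warning("all macrophages are APC-like; every permutation reproduces ",
            "the observed configuration and p = 1", call. = FALSE)

  # in-radius adjacency of every CD8 cell to every macrophage, computed
  # once; each permutation is then a sparse matrix-vector product
  nbr <- radius_neighbors(cells$x_um[cd8], cells$y_um[cd8],
                          cells$x_um[mac], cells$y_um[mac],
                          radius = radius_um)
  deg <- lengths(nbr)
  adj <- Matrix::sparseMatrix(
    i = rep.int(seq_along(cd8), deg),
    j = unlist(nbr, use.names = FALSE),
    x = 1, dims = c(length(cd8), length(mac)))

  apc_in_mac <- apc[mac]
  observed <- mean(as.vector(adj %*% apc_in_mac) > 0)

  null_fractions <- with_rng_seed(seed, {
    perms <- matrix(0, nrow = length(mac), ncol = n_perm)
    for (p in seq_len(n_perm))
      perms[sample.int(length(mac), n_apc), p] <- 1
    Matrix::colMeans(adj %*% perms > 0)
  })

  k <- sum(null_fractions >= observed)
  res <- list(sample_id = if ("sample_id" %in% names(cells))
                cells$sample_id[1] else NA_character_,
              observed_fraction = observed,
              n_cd8 = length(cd8), n_macrophage = length(mac),
              n_apc = n_apc, radius_um = radius_um,
              null_fractions = as.numeric(null_fractions),
              empirical_p = if (add_one) (k + 1) / (n_perm + 1) else k / n_perm,
              seed = seed)
  class(res) <- "proximity_result"
  res
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf(
    "CD8-APC proximity (sample %s): fraction %.3f within %g um\n",
    x$sample_id, x$observed_fraction, x$radius_um))
  cat(sprintf("  %d CD8, %d macrophages (%d APC-like); %d permutations\n",
              x$n_cd8, x$n_macrophage, x$n_apc, length(x$null_fractions)))
  cat(sprintf("  empirical p = %.4g\n", x$empirical_p))
  invisible(x)
}

#' Compare expression between CD8-proximal and CD8-distal macrophages
#'
#' Stratifies all macrophages (not only APC-like) by distance to the
#' nearest CD8 T cell: proximal when <= `threshold_um`, distal otherwise.
#' Each gene is compared between strata with a two-sided Mann-Whitney U
#' test; the rank-biserial correlation `2U/(n1 n2) - 1` is reported as the
#' effect size.  A gene is skipped with status `"skipped"` when a stratum
#' is empty.
#'
#' @param cells spatial cell table for one sample.
#' @param threshold_um proximity threshold in micrometers.
#' @param genes genes to compare.
#' @return data frame with gene, n_proximal, n_distal, statistic, p_value,
#'   median_proximal, median_distal, rank_biserial, status.
#' @export
stratify_and_compare_expression <- function(cells, threshold_um = 20,
                                            genes = c("HLA-DRA", "CD74")) {
  mac <- which(cells$cell_type == "Macrophage")
  cd8 <- which(cells$cell_type == "CD8T")
  if (length(cd8) == 0) stop("no CD8 cells to stratify against",
                             call. = FALSE)
  if (length(mac) == 0) stop("no macrophages", call. = FALSE)
  nbr <- radius_neighbors(cells$x_um[mac], cells$y_um[mac],
                          cells$x_um[cd8], cells$y_um[cd8],
                          radius = threshold_um)
  proximal <- lengths(nbr) > 0
  rows <- lapply(genes, function(g) {
    v <- .get_gene(cells, g)[mac]
    x <- v[proximal]; y <- v[!proximal]
    if (length(x) == 0 || length(y) == 0) {
      return(data.frame(gene = g, n_proximal = length(x),
                        n_distal = length(y), statistic = NA_real_,
                        p_value = NA_real_, median_proximal = NA_real_,
                        median_distal = NA_real_, rank_biserial = NA_real_,
                        status = "skipped", stringsAsFactors = FALSE))
    }
    exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
    wt <- stats::wilcox.test(x, y, exact = exact, correct = !exact)
    u <- unname(wt$statistic)
    data.frame(gene = g, n_proximal = length(x), n_distal = length(y),
               statistic = u, p_value = min(1, wt$p.value),
               median_proximal = stats::median(x),
               median_distal = stats::median(y),
               rank_biserial = 2 * u / (length(x) * length(y)) - 1,
               status = "ok", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
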