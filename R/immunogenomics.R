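#' Pairwise Mann-Whitney U comparisons across groups
#'
#' Two-sided Mann-Whitney U test for every pair of group labels.  The
#' exact null distribution is used when both groups have n <= 8 and there
#' are no ties; otherwise the tie-corrected normal approximation with
#' continuity correction.  Raw p-values are reported by default;
#' `p_adjust = TRUE` adds a Benjamini-Hochberg column.
#'
#' @param values numeric vector of per-tumor values.
#' @param groups group label per value.
#' @param p_adjust add a BH-adjusted column over the pairwise contrasts.
#' @return data frame with group1, group2, n1, n2, statistic (U for
#'   group1 vs group2), p_value (and p_adjusted when requested).
#' @export
group_compare <- function(values, groups, p_adjust = FALSE) {
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  labs <- unique(groups)
  if (any(table(groups) < 1) || length(labs) < 2)
    stop("need at least one observation in each of >= 2 groups",
         call. = FALSE)
  pairs <- utils::combn(labs, 2)
  rows <- apply(pairs, 2, function(gg) {
    x <- values[groups == gg[1]]; y <- values[groups == gg[2]]
    exact <- length(x) <= 8 && length(y) <= 8 &&
      !anyDuplicated(c(x, y))
    wt <- stats::wilcox.test(x, y, exact = exact, correct = !exact)
    data.frame(group1 = gg[1], group2 = gg[2],
               n1 = length(x), n2 = length(y),
               statistic = unname(wt$statistic),
               p_value = min(1, wt$p.value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Correlation between two continuous variables
#'
#' Pearson or Spearman correlation with a two-sided p-value from the
#' t-approximation.  Pearson is the package default for the MDF-neoantigen
#' coupling; Spearman is exposed for rank-based use.
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with estimate, p_value, n, method.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in input", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = length(x), method = method)
}

#' Residual neoantigen burden after TMB adjustment
#'
#' Ordinary least squares of `log10(neoantigen + 1)` on `log10(tmb + 1)`;
#' the residuals isolate neoantigen burden not explained by overall
#' mutation quantity.  With zero-variance TMB the residuals fall back to
#' the centered transformed neoantigen burden, with a warning.
#'
#' @param neoantigen,tmb non-negative numeric vectors, n >= 3.
#' @return numeric vector of residuals.
#' @export
tmb_adjusted_residuals <- function(neoantigen, tmb) {
  stopifnot(length(neoantigen) == length(tmb))
  if (length(neoantigen) < 3) stop("need n >= 3", call. = FALSE)
  ly <- log10(neoantigen + 1)
  lx <- log10(tmb + 1)
  if (stats::sd(lx) == 0) {
    warning("zero-variance TMB; returning centered neoantigen burden",
            call. = FALSE)
    return(ly - mean(ly))
  }
  unname(stats::residuals(stats::lm(ly ~ lx)))
}

#' Association of MDF with TMB-adjusted residual neoantigen burden
#'
#' @param neoantigen,tmb per-tumor counts and mutations/Mb.
#' @param mdf per-tumor MDF on any affine scale (raw, z or shifted).
#' @param method correlation method, Pearson by default.
#' @return list with residuals plus estimate, p_value, n, method.
#' @export
mdf_residual_association <- function(neoantigen, tmb, mdf,
                                     method = c("pearson", "spearman")) {
  res <- tmb_adjusted_residuals(neoantigen, tmb)
  out <- correlate(res, mdf, method = match.arg(method))
  out$residuals <- res
  out
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction; df = (r-1)(c-1).  Zero row or column sums and
#' non-positive expected counts are rejected.
#'
#' @param contingency matrix of counts.
#' @return list with statistic, df, p_value.
#' @export
composition_chisq <- function(contingency) {
  contingency <- as.matrix(contingency)
  if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0))
    stop("zero row or column sums in contingency table", call. = FALSE)
  expected <- outer(rowSums(contingency), colSums(contingency)) /
    sum(contingency)
  if (any(expected <= 0)) stop("non-positive expected counts", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(contingency, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}
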