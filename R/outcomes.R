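#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with right censoring; at tied times events are
#' handled before censorings.  Backed by [survival::survfit()].
#'
#' @param records data frame with columns time (> 0) and event (0/1).
#' @return data frame with time, n_risk, n_event, n_censor, surv.
#' @export
km_curve <- function(records) {
  stopifnot(nrow(records) >= 1, all(records$time > 0),
            all(records$event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' @param records data frame with columns time, event and group (exactly
#'   two labels).
#' @return list with statistic (chi-square, 1 df) and p_value.
#' @export
logrank <- function(records) {
  if (length(unique(records$group)) != 2)
    stop("log-rank comparison needs exactly two groups", call. = FALSE)
  if (sum(records$event) < 1)
    stop("log-rank needs at least one event", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

# restricted mean (area under KM on [0, tau]) and its Greenwood-type
# variance for one group
.rmst_one <- function(time, event, tau) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  if (max(time) < tau && fit$n.censor[length(fit$n.censor)] > 0)
    warning("follow-up ends before tau with a censoring; carrying the ",
            "Kaplan-Meier curve flat to tau", call. = FALSE)
  # knots: S(u) = ss[k] on [tt[k], tt[k+1]); last segment carried to tau
  tt <- c(0, fit$time[fit$time <= tau], tau)
  ss <- c(1, fit$surv[fit$time <= tau])
  area <- sum(diff(tt) * ss)

  # variance: sum over event times t_j <= tau of
  #   (area from t_j to tau)^2 * d_j / (n_j (n_j - d_j))
  ev <- fit$n.event > 0 & fit$time <= tau
  if (!any(ev)) return(list(rmst = area, se = 0))
  t_ev <- fit$time[ev]; d <- fit$n.event[ev]; n <- fit$n.risk[ev]
  tail_area <- vapply(t_ev, function(tj) {
    pos <- match(tj, tt)
    sum(diff(tt[pos:length(tt)]) * ss[pos:(length(tt) - 1)])
  }, numeric(1))
  denom <- n * (n - d)
  v <- sum(ifelse(denom > 0, tail_area^2 * d / denom, 0))
  list(rmst = area, se = sqrt(v))
}

#' Restricted mean survival time by group with between-group difference
#'
#' RMST is the area under the Kaplan-Meier curve on `[0, tau]`.  When a
#' group's follow-up ends in a censoring before `tau`, the curve is
#' carried flat to `tau` with a warning.  The variance of each group's
#' RMST uses the standard Greenwood-based plug-in for the restricted
#' area; the difference (first group level minus second) gets a normal
#' 95% confidence interval.
#'
#' @param records data frame with columns time, event and, for the
#'   difference, group with exactly two labels.
#' @param tau truncation time in the units of `time` (months in the
#'   intended use), default 24.
#' @param conf_level confidence level for the difference CI.
#' @return list with `by_group` (group, n, events, rmst, se) and, for two
#'   groups, `difference`, `ci_lower`, `ci_upper`, `groups` (the order of
#'   the subtraction).
#' @export
rmst <- function(records, tau = 24, conf_level = 0.95) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0)
    stop("tau must be a single positive number", call. = FALSE)
  if (!"group" %in% names(records)) records$group <- "all"
  groups <- unique(records$group)
  per <- lapply(groups, function(g) {
    r <- records[records$group == g, ]
    est <- .rmst_one(r$time, r$event, tau)
    data.frame(group = g, n = nrow(r), events = sum(r$event),
               rmst = est$rmst, se = est$se, stringsAsFactors = FALSE)
  })
  by_group <- do.call(rbind, per)
  out <- list(by_group = by_group, tau = tau)
  if (length(groups) == 2) {
    d <- by_group$rmst[1] - by_group$rmst[2]
    se <- sqrt(by_group$se[1]^2 + by_group$se[2]^2)
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    out$difference <- d
    out$ci_lower <- d - zq * se
    out$ci_upper <- d + zq * se
    out$groups <- groups
  }
  out
}

#' Split a numeric stratification variable at the cohort median
#'
#' Values at or below the median go to the low stratum (ties-to-lower).
#'
#' @param x numeric vector.
#' @param labels labels for the high and low strata.
#' @return character vector of stratum labels.
#' @export
median_split <- function(x, labels = c("high", "low")) {
  ifelse(x > stats::median(x), labels[1], labels[2])
}
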