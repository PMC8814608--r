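# Kaplan-Meier estimation, two-group log-rank comparison, and optimal
# dichotomisation of a continuous score by maximally selected rank
# statistics: every admissible observed score value is tried as a
# cutpoint, the standardized two-group log-rank statistic is computed at
# each, and the cutpoint maximising |statistic| is returned. p-values at
# the selected cutpoint are the unadjusted log-rank p; a
# Lausen-Schumacher-adjusted p is reported alongside as a diagnostic.

check_survival_records <- function(records) {
  stopifnot(all(c("time", "event") %in% names(records)))
  if (any(records$time <= 0)) stop("survival times must be > 0")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(records)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator via [survival::survfit()], returned as a tidy
#' step-function table with the risk set at each observed time.
#'
#' @param records data.frame with `time` (> 0) and `event` (0/1) columns.
#' @return data.table: `time`, `n_risk`, `n_event`, `n_censor`, `surv`
#'   (right-continuous, `S(0) = 1` implicitly); the underlying `survfit`
#'   object is attached as attribute `"fit"`.
#' @export
km_estimate <- function(records) {
  records <- data.table::as.data.table(records)
  if (nrow(records) == 0L) stop("need at least one record")
  check_survival_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  out <- data.table::data.table(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv)
  data.table::setattr(out, "fit", fit)
  out[]
}

# Pre-aggregate the event structure shared by every candidate split:
# distinct event times, events and at-risk counts at each.
logrank_structure <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  stime <- sort(time)
  n <- length(time)
  # at risk at t = #{time >= t}; left.open counts #{stime < t}
  n_risk <- n - findInterval(ut, stime, left.open = TRUE)
  d <- as.integer(table(factor(time[event == 1], levels = ut)))
  list(ut = ut, n_risk = n_risk, d = d, n = n)
}

# Standardized two-group log-rank statistic for the subset `in_high`
# (logical): z = (O1 - E1) / sqrt(V1) with the hypergeometric variance.
logrank_z <- function(time, event, in_high, structure = NULL) {
  if (is.null(structure)) structure <- logrank_structure(time, event)
  ut <- structure$ut; nj <- structure$n_risk; dj <- structure$d
  th <- sort(time[in_high])
  n1j <- length(th) - findInterval(ut, th, left.open = TRUE)
  teh <- time[in_high & event == 1]
  d1j <- as.integer(table(factor(teh, levels = ut)))
  O1 <- sum(d1j)
  E1 <- sum(dj * n1j / nj)
  vj <- ifelse(nj > 1,
               dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1), 0)
  V1 <- sum(vj)
  z <- if (V1 > 0) (O1 - E1) / sqrt(V1) else 0
  list(O1 = O1, E1 = E1, V1 = V1, z = z, chisq = z^2,
       p = stats::pchisq(z^2, df = 1, lower.tail = FALSE))
}

#' Log-rank test between survival groups
#'
#' Standard log-rank test: at each distinct event time, observed events
#' per group are compared with their hypergeometric expectation given the
#' risk sets; the statistic is chi-squared with (groups - 1) degrees of
#' freedom. Two groups are computed natively; more than two are delegated
#' to [survival::survdiff()].
#'
#' @param records data.frame with `time` and `event`.
#' @param group per-record group labels (>= 2 nonempty groups).
#' @return list: `statistic`, `df`, `p`, plus `observed`, `expected`,
#'   `variance` and `z` for the two-group case.
#' @export
logrank_test <- function(records, group) {
  records <- data.table::as.data.table(records)
  check_survival_records(records)
  group <- droplevels(factor(group))
  if (nlevels(group) < 2L) stop("need at least two nonempty groups")
  if (nlevels(group) == 2L) {
    lr <- logrank_z(records$time, records$event, group == levels(group)[2])
    return(list(statistic = lr$chisq, df = 1L, p = lr$p,
                observed = lr$O1, expected = lr$E1, variance = lr$V1,
                z = lr$z))
  }
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ g,
    data = data.frame(time = records$time, event = records$event, g = group))
  list(statistic = unname(sd$chisq), df = nlevels(group) - 1L,
       p = stats::pchisq(sd$chisq, df = nlevels(group) - 1L,
                         lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp, variance = NA_real_,
       z = NA_real_)
}

# Lausen-Schumacher approximation for the p-value of the maximally
# selected standardized statistic with group proportions in
# [minprop, 1 - minprop].
lausen_schumacher_p <- function(b, minprop) {
  if (!is.finite(b) || b <= 0) return(1)
  e1 <- minprop; e2 <- 1 - minprop
  p <- stats::dnorm(b) * (b - 1 / b) * log((e2 * (1 - e1)) / ((1 - e2) * e1)) +
    4 * stats::dnorm(b) / b
  min(max(p, 0), 1)
}

#' Optimal survival cutpoint by maximally selected rank statistics
#'
#' Scans every observed score value whose induced split (`score > c` vs
#' `score <= c`) leaves at least `minprop` of the samples on each side,
#' computes the standardized two-group log-rank statistic at each, and
#' returns the cutpoint maximising the absolute statistic (ties broken
#' toward the smaller cutpoint). The per-candidate table is returned in
#' full; the selected cutpoint's unadjusted log-rank p is
#' anti-conservative under the null because of the maximisation, so the
#' Lausen-Schumacher-adjusted p is reported alongside.
#'
#' @param records data.frame with `time`, `event` and `score` columns.
#' @param minprop minimum fraction of samples in each group (default 0.1).
#' @return list: `cutpoint`, `statistic` (standardized z at the cutpoint),
#'   `n_high`, `n_low`, `p_unadjusted`, `p_adjusted`, and `candidates`
#'   (data.table `cutpoint`, `n_high`, `n_low`, `z`, `abs_z`, `p`).
#' @export
optimal_cutpoint <- function(records, minprop = 0.1) {
  records <- data.table::as.data.table(records)
  check_survival_records(records)
  if (!"score" %in% names(records)) stop("records need a 'score' column")
  score <- records$score
  if (anyNA(score)) stop("missing scores")
  if (length(unique(score)) < 2L) stop("score is constant: no candidate cutpoint")
  n <- nrow(records)
  cands <- sort(unique(score))
  cands <- cands[-length(cands)]           # score > max(score) is empty
  n_high <- vapply(cands, function(c) sum(score > c), integer(1))
  ok <- n_high >= minprop * n & (n - n_high) >= minprop * n
  if (!any(ok)) stop("no admissible candidate cutpoint under minprop = ", minprop)
  cands <- cands[ok]; n_high <- n_high[ok]
  str <- logrank_structure(records$time, records$event)
  z <- vapply(cands, function(c)
    logrank_z(records$time, records$event, score > c, str)$z, numeric(1))
  tab <- data.table::data.table(
    cutpoint = cands, n_high = n_high, n_low = n - n_high, z = z,
    abs_z = abs(z),
    p = stats::pchisq(z^2, df = 1, lower.tail = FALSE))
  best <- which(tab$abs_z == max(tab$abs_z))[1]   # ties -> smaller cutpoint
  list(cutpoint = tab$cutpoint[best], statistic = tab$z[best],
       n_high = tab$n_high[best], n_low = tab$n_low[best],
       p_unadjusted = tab$p[best],
       p_adjusted = lausen_schumacher_p(tab$abs_z[best], minprop),
       candidates = tab[])
}

#' Dichotomize a score at a fixed threshold and compare survival
#'
#' The high group is `score > threshold` (strict), matching how cutpoints
#' from [optimal_cutpoint()] are applied.
#'
#' @param records data.frame with `time`, `event`, `score`.
#' @param threshold the dichotomisation threshold.
#' @return list: `n_high`, `n_low`, `test` (a [logrank_test()] result).
#' @export
dichotomize_and_compare <- function(records, threshold) {
  records <- data.table::as.data.table(records)
  check_survival_records(records)
  high <- records$score > threshold
  if (all(high) || !any(high)) {
    stop("threshold ", threshold, " leaves an empty arm")
  }
  list(n_high = sum(high), n_low = sum(!high),
       test = logrank_test(records, factor(ifelse(high, "high", "low"))))
}
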