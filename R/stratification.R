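#' Two-sample log-rank test
#'
#' Observed-minus-expected events under the hypergeometric null at each
#' event time, aggregated into a chi-square statistic on 1 df. Datasets
#' with no events at all give statistic 0 / p-value 1.
#'
#' @param time,event outcome vectors.
#' @param group two-level grouping (factor, character or logical).
#' @return list: `chisq`, `p_value`, `n_per_group`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.vector(group))
  if (nlevels(group) != 2L || any(table(group) == 0))
    stop("exactly two nonempty groups required", call. = FALSE)
  if (sum(event) == 0)
    return(list(chisq = 0, p_value = 1,
                n_per_group = as.vector(table(group))))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd_$chisq)
  list(chisq = chisq, p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
       n_per_group = as.vector(table(group)))
}

#' Log-rank-optimal risk cutpoint with a minimum group size
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' risk scores; candidates leaving either group below
#' `ceiling(min_frac * n)` members are discarded; among the admissible
#' candidates the one maximizing the log-rank chi-square is returned
#' (smaller threshold on ties). High risk means score strictly above the
#' threshold.
#'
#' @param risk risk scores.
#' @param time,event outcome vectors.
#' @param min_frac minimal fraction of the cohort per risk group.
#' @return list: `threshold`, `group` (factor `low`/`high`), `chisq`,
#'   `p_value`, `n_high`, `n_low`.
#' @export
find_cutpoint <- function(risk, time, event, min_frac = 0.33) {
  n <- length(risk)
  if (min_frac >= 0.5) stop("min_frac must be < 0.5", call. = FALSE)
  u <- sort(unique(risk))
  if (length(u) < 2L)
    stop("need at least 2 distinct risk values", call. = FALSE)
  mids <- (u[-1] + u[-length(u)]) / 2
  min_size <- ceiling(min_frac * n)
  best <- NULL
  for (thr in mids) {
    hi <- risk > thr
    if (sum(hi) < min_size || sum(!hi) < min_size) next
    lt <- logrank_test(time, event, ifelse(hi, "high", "low"))
    if (is.null(best) || lt$chisq > best$chisq + 1e-12)
      best <- list(threshold = thr, chisq = lt$chisq,
                   p_value = lt$p_value, n_high = sum(hi),
                   n_low = sum(!hi))
  }
  if (is.null(best))
    stop("no admissible cutpoint satisfies the minimum group size",
         call. = FALSE)
  best$group <- factor(ifelse(risk > best$threshold, "high", "low"),
                       levels = c("low", "high"))
  best
}

#' Kaplan-Meier curves per risk group
#'
#' Convenience accessor for plotting the stratified survival curves.
#'
#' @param time,event outcome vectors.
#' @param group risk-group factor (e.g. from [find_cutpoint()]).
#' @return named list of per-group step functions (`times`, `surv`,
#'   `n_risk`, `n_event`).
#' @export
km_curves <- function(time, event, group) {
  group <- as.factor(group)
  out <- lapply(levels(group), function(g) {
    sel <- group == g
    fit <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1)
    list(times = fit$time, surv = fit$surv, n_risk = fit$n.risk,
         n_event = fit$n.event)
  })
  names(out) <- levels(group)
  out
}
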