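#' Kaplan-Meier estimators of survival and censoring distributions
#'
#' Product-limit estimator of the survival function `S(t)` and, with events
#' and censorings swapped, of the censoring distribution `G(t)` (the
#' "reverse Kaplan-Meier" used by the IPCW concordance weights).
#'
#' @param time,event outcome vectors.
#' @return list with `S` and `G`, each a list of `times` and `surv` step
#'   values, and evaluator functions `S_at(t, left)` / `G_at(t, left)`
#'   (right-continuous by default; `left = TRUE` gives the left limit).
#' @export
km_estimator <- function(time, event) {
  if (any(time < 0)) stop("negative survival times", call. = FALSE)
  if (length(time) == 0L) stop("no observations", call. = FALSE)
  fit_s <- survival::survfit(survival::Surv(time, event) ~ 1)
  fit_g <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  step_eval <- function(times, surv) {
    force(times); force(surv)
    function(t, left = FALSE) {
      vapply(t, function(tt) {
        k <- if (left) sum(times < tt) else sum(times <= tt)
        if (k == 0L) 1 else surv[k]
      }, numeric(1))
    }
  }
  list(S = list(times = fit_s$time, surv = fit_s$surv),
       G = list(times = fit_g$time, surv = fit_g$surv),
       S_at = step_eval(fit_s$time, fit_s$surv),
       G_at = step_eval(fit_g$time, fit_g$surv))
}

# usable-pair structure shared by both concordance variants:
# pair (i, j) usable if event_i = 1 and (T_i < T_j, or T_i = T_j with j
# censored); event/event ties unusable.
concordance_core <- function(time, event, risk, tau = NULL, weights = NULL) {
  n <- length(time)
  stopifnot(length(event) == n, length(risk) == n)
  num <- 0; den <- 0; n_pairs <- 0
  ev_idx <- which(event == 1)
  if (!is.null(tau)) ev_idx <- ev_idx[time[ev_idx] < tau]
  for (i in ev_idx) {
    usable <- (time > time[i]) | (time == time[i] & event == 0)
    usable[i] <- FALSE
    m <- sum(usable)
    if (m == 0L) next
    conc <- sum(risk[i] > risk[usable]) + 0.5 * sum(risk[i] == risk[usable])
    w <- if (is.null(weights)) 1 else weights[i]
    num <- num + w * conc
    den <- den + w * m
    n_pairs <- n_pairs + m
  }
  list(num = num, den = den, n_pairs = n_pairs)
}

#' Harrell's concordance index
#'
#' Fraction of usable patient pairs whose risk ordering matches their
#' survival ordering. Usable pairs: the earlier time is an event (pairs
#' tied in time are usable when exactly one is an event; event/event ties
#' are not). Risk ties count 1/2.
#'
#' @param time,event outcome vectors.
#' @param risk risk scores (higher = worse prognosis).
#' @return list of class `radsurv_cindex`: `estimate`, `variant`, `tau`,
#'   `n_usable_pairs`.
#' @export
harrell_c <- function(time, event, risk) {
  cc <- concordance_core(time, event, risk)
  if (cc$n_pairs == 0L) stop("no usable pairs", call. = FALSE)
  structure(list(estimate = cc$num / cc$den, variant = "harrell",
                 tau = NULL, n_usable_pairs = cc$n_pairs),
            class = "radsurv_cindex")
}

#' Uno's IPCW concordance index
#'
#' Inverse-probability-of-censoring-weighted concordance: usable pairs as
#' in [harrell_c()], each pair weighted by `1 / G(T_i-)^2` where `G` is the
#' Kaplan-Meier estimate of the censoring distribution on the evaluation
#' set, evaluated just before the event time. With `tau` given, only pairs
#' whose event time is below `tau` contribute (truncated variant). With no
#' censoring all weights are 1 and the estimate equals Harrell's c exactly.
#'
#' @inheritParams harrell_c
#' @param tau optional truncation horizon in years.
#' @param km optional precomputed [km_estimator()] on the evaluation set.
#' @return list of class `radsurv_cindex` (see [harrell_c()]).
#' @export
uno_c <- function(time, event, risk, tau = NULL, km = NULL) {
  if (is.null(km)) km <- km_estimator(time, event)
  g <- km$G_at(time, left = TRUE)
  ev <- event == 1 & (if (is.null(tau)) TRUE else time < tau)
  if (any(ev & g == 0)) {
    bad <- time[ev & g == 0][1]
    stop(sprintf("censoring survival G is 0 at event time %g", bad),
         call. = FALSE)
  }
  w <- ifelse(g > 0, 1 / g^2, 0)
  cc <- concordance_core(time, event, risk, tau = tau, weights = w)
  if (cc$n_pairs == 0L) stop("no usable pairs below tau", call. = FALSE)
  structure(list(estimate = cc$num / cc$den, variant = "uno", tau = tau,
                 n_usable_pairs = cc$n_pairs),
            class = "radsurv_cindex")
}

#' @export
print.radsurv_cindex <- function(x, ...) {
  cat(sprintf("%s c-index%s: %.4f (%d usable pairs)\n", x$variant,
              if (!is.null(x$tau)) sprintf(" (tau = %g)", x$tau) else "",
              x$estimate, x$n_usable_pairs))
  invisible(x)
}

#' Bootstrap c-index distributions for one or more models
#'
#' Resamples the evaluation patients with replacement `B` times; the same
#' resample indices are applied to every model so the resulting
#' distributions are paired and can be compared with a signed-rank test.
#' Per resample, Uno's c (untruncated) and Uno's c at `tau` are computed.
#' Replicates whose resample contains no events are skipped and logged;
#' more than 10% skips is an error.
#'
#' @param time,event outcome vectors of the evaluation set.
#' @param risks named list of risk-score vectors, one per model.
#' @param B number of bootstrap replicates.
#' @param tau truncation horizon for the truncated variant (years).
#' @param seed integer seed for the resampling.
#' @return named list of `radsurv_boot` objects, each with `values`
#'   (untruncated), `values_tau`, `median`, `iqr`, `median_tau`, `iqr_tau`,
#'   `seed`, `n_skipped`, and the shared `indices` matrix.
#' @export
bootstrap_distribution <- function(time, event, risks, B = 1000, tau = 5,
                                   seed = 1) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  if (is.null(names(risks)) || any(names(risks) == ""))
    stop("`risks` must be a named list", call. = FALSE)
  n <- length(time)
  idx <- with_seed(seed,
    matrix(sample.int(n, n * B, replace = TRUE), nrow = B))
  keep <- vapply(seq_len(B), function(b) sum(event[idx[b, ]]) > 0,
                 logical(1))
  n_skipped <- sum(!keep)
  if (n_skipped > 0.1 * B)
    stop(sprintf("%d/%d bootstrap resamples had zero events", n_skipped, B),
         call. = FALSE)
  idx_kept <- idx[keep, , drop = FALSE]
  nb <- nrow(idx_kept)
  vals_m <- matrix(NA_real_, nb, length(risks))
  vals_tau_m <- matrix(NA_real_, nb, length(risks))
  for (b in seq_len(nb)) {
    ii <- idx_kept[b, ]
    km <- km_estimator(time[ii], event[ii])
    for (m in seq_along(risks)) {
      r <- risks[[m]]
      vals_m[b, m] <- uno_c(time[ii], event[ii], r[ii], km = km)$estimate
      vals_tau_m[b, m] <- tryCatch(
        uno_c(time[ii], event[ii], r[ii], tau = tau, km = km)$estimate,
        error = function(e) NA_real_)
    }
  }
  out <- lapply(seq_along(risks), function(m) {
    vals <- vals_m[, m]; vals_tau <- vals_tau_m[, m]
    structure(list(values = vals, values_tau = vals_tau,
                   median = median(vals),
                   iqr = unname(quantile(vals, 0.75) - quantile(vals, 0.25)),
                   median_tau = median(vals_tau, na.rm = TRUE),
                   iqr_tau = unname(quantile(vals_tau, 0.75, na.rm = TRUE) -
                                    quantile(vals_tau, 0.25, na.rm = TRUE)),
                   seed = seed, n_skipped = n_skipped,
                   indices = idx_kept),
              class = "radsurv_boot")
  })
  names(out) <- names(risks)
  out
}

#' Paired comparison of two bootstrap c-index distributions
#'
#' Wilcoxon signed-rank test on the paired differences of two bootstrap
#' distributions built from the same resample indices. Zero differences are
#' dropped; if every difference is zero the p-value is 1 by convention.
#'
#' @param a,b `radsurv_boot` objects from one [bootstrap_distribution()]
#'   call (same resample indices).
#' @param which `"uno"` (untruncated) or `"uno_tau"`.
#' @return list: `statistic`, `p_value`, `n_nonzero`.
#' @export
compare_distributions <- function(a, b, which = c("uno", "uno_tau")) {
  which <- match.arg(which)
  if (!identical(dim(a$indices), dim(b$indices)) ||
      !identical(a$indices, b$indices))
    stop("distributions are not paired (different resample indices)",
         call. = FALSE)
  va <- if (which == "uno") a$values else a$values_tau
  vb <- if (which == "uno") b$values else b$values_tau
  ok <- !is.na(va) & !is.na(vb)
  d <- va[ok] - vb[ok]
  nz <- d[d != 0]
  if (length(nz) == 0L)
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L))
  wt <- suppressWarnings(wilcox.test(nz, exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_nonzero = length(nz))
}
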