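#' Z-score normalization of a feature table
#'
#' Each column is centered and scaled by its own mean and standard deviation
#' computed within the supplied set of rows. The study protocol normalizes
#' training and test sets separately (each with its own statistics); pass
#' the two sets through this function independently to follow it, or reuse
#' training statistics via `center`/`scale`.
#'
#' @param table data.frame or matrix of numeric features (rows = patients).
#' @param center,scale optional named vectors of precomputed statistics; if
#'   given, they are used instead of the set's own.
#' @return data.frame of normalized features; attribute `constant_columns`
#'   lists columns with zero variance (set to 0).
#' @export
zscore_normalize <- function(table, center = NULL, scale = NULL) {
  tab <- as.data.frame(table)
  if (nrow(tab) < 2L && is.null(center))
    stop("z-score normalization needs at least 2 rows", call. = FALSE)
  mu <- if (is.null(center)) vapply(tab, mean, numeric(1)) else
    center[names(tab)]
  sdv <- if (is.null(scale)) vapply(tab, sd, numeric(1)) else
    scale[names(tab)]
  const <- names(tab)[!is.na(sdv) & sdv == 0]
  out <- tab
  for (j in names(tab)) {
    if (j %in% const) out[[j]] <- rep(0, nrow(tab))
    else out[[j]] <- (tab[[j]] - mu[[j]]) / sdv[[j]]
  }
  attr(out, "constant_columns") <- const
  attr(out, "center") <- mu
  attr(out, "scale") <- sdv
  out
}

#' Variance screen (stage 1 of the selection cascade)
#'
#' Removes features whose variance is strictly below `threshold`. Applied to
#' the raw (pre-normalization) feature values: after z-scoring every
#' non-constant feature has unit variance, which would make the threshold
#' vacuous, so the screen is read as a near-constancy filter on raw values.
#'
#' @param table data.frame of raw feature values (training rows).
#' @param threshold variance threshold; strict `<` removal.
#' @return list with `keep` and `removed` character vectors.
#' @export
variance_filter <- function(table, threshold = 0.01) {
  v <- vapply(as.data.frame(table), var, numeric(1))
  list(keep = names(v)[v >= threshold], removed = names(v)[v < threshold])
}

#' Spearman redundancy pruning (stage 2 of the selection cascade)
#'
#' The full Spearman correlation matrix is computed once. Pairs with
#' `|rho| >= rho_threshold` are visited in descending `|rho|`; a pair with
#' an already-removed member is skipped; otherwise the member with the
#' higher mean `|rho|` against all other original features is removed
#' (lexicographically later name on ties).
#'
#' @param table data.frame of feature values (training rows).
#' @param rho_threshold absolute Spearman correlation threshold.
#' @return list with `keep`, and `removed` (data.frame: feature, partner,
#'   rho, mean_abs_rho_removed, mean_abs_rho_kept).
#' @export
spearman_prune <- function(table, rho_threshold = 0.95) {
  tab <- as.data.frame(table)
  p <- ncol(tab)
  empty_rm <- data.frame(feature = character(0), partner = character(0),
                         rho = numeric(0), mean_abs_rho_removed = numeric(0),
                         mean_abs_rho_kept = numeric(0),
                         stringsAsFactors = FALSE)
  if (p < 3L) return(list(keep = names(tab), removed = empty_rm))
  rho <- suppressWarnings(cor(tab, method = "spearman"))
  rho[is.na(rho)] <- 0
  a <- abs(rho); diag(a) <- NA
  mean_abs <- rowMeans(a, na.rm = TRUE)
  pairs <- which(upper.tri(a) & a >= rho_threshold, arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(list(keep = names(tab), removed = empty_rm))
  nm <- names(tab)
  ord <- order(-a[pairs], nm[pairs[, 1]], nm[pairs[, 2]])
  pairs <- pairs[ord, , drop = FALSE]
  removed <- character(0)
  log <- empty_rm
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    fi <- nm[i]; fj <- nm[j]
    if (fi %in% removed || fj %in% removed) next
    mi <- mean_abs[i]; mj <- mean_abs[j]
    drop_i <- if (mi > mj) TRUE else if (mj > mi) FALSE else fi > fj
    victim <- if (drop_i) fi else fj
    keeper <- if (drop_i) fj else fi
    removed <- c(removed, victim)
    log <- rbind(log, data.frame(
      feature = victim, partner = keeper, rho = rho[i, j],
      mean_abs_rho_removed = if (drop_i) mi else mj,
      mean_abs_rho_kept = if (drop_i) mj else mi,
      stringsAsFactors = FALSE))
  }
  list(keep = setdiff(nm, removed), removed = log)
}

# event-stratified fold assignment, deterministic per seed
stratified_folds <- function(event, k, seed) {
  n <- length(event)
  foldid <- integer(n)
  with_seed(seed, {
    for (lev in unique(event)) {
      idx <- which(event == lev)
      foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  foldid
}

#' LASSO-Cox feature selection (stage 3 of the selection cascade)
#'
#' L1-penalized Cox partial likelihood over a log-spaced lambda grid;
#' lambda is chosen by k-fold cross-validated partial-likelihood deviance
#' with event-stratified, seeded folds. Features with nonzero coefficients
#' at the chosen lambda are returned with their coefficients. Input features
#' are expected already normalized (no internal standardization).
#'
#' @param table data.frame/matrix of (normalized) features, training rows.
#' @param time,event survival outcome vectors.
#' @param lambda_grid optional lambda sequence (glmnet chooses one if NULL).
#' @param cv_folds number of CV folds.
#' @param seed integer seed for the fold assignment.
#' @return list: `selected` (named coefficient vector), `lambda`, `empty`
#'   (TRUE with a warning flag if nothing survives), `cv_folds`, `seed`.
#' @export
lasso_cox_select <- function(table, time, event, lambda_grid = NULL,
                             cv_folds = 5, seed = 1) {
  x <- as.matrix(table)
  if (sum(event) == 0) stop("no events: cannot fit LASSO-Cox", call. = FALSE)
  y <- survival::Surv(time, event)
  foldid <- stratified_folds(event, cv_folds, seed)
  for (f in seq_len(cv_folds))
    if (sum(event[foldid != f]) == 0)
      stop("a CV training fold has no events", call. = FALSE)
  cvfit <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1,
                             lambda = lambda_grid, foldid = foldid,
                             standardize = FALSE, type.measure = "deviance")
  co <- as.matrix(glmnet::coef.glmnet(cvfit, s = "lambda.min"))[, 1]
  sel <- co[co != 0]
  list(selected = sel, lambda = cvfit$lambda.min, empty = length(sel) == 0L,
       cv_folds = cv_folds, seed = seed)
}

#' The full three-stage selection cascade
#'
#' Fixed order: variance screen on raw training values, Spearman redundancy
#' pruning among the survivors, then LASSO-Cox on the normalized survivors.
#' Only training rows ever enter any stage.
#'
#' @param raw data.frame of raw (pre-normalization) training features.
#' @param norm data.frame of normalized training features (same columns).
#' @param time,event training outcomes.
#' @param variance_threshold,rho_threshold stage thresholds.
#' @inheritParams lasso_cox_select
#' @return a selection report: `removed_by_variance`,
#'   `removed_by_correlation` (data.frame), `lasso_selected` (named
#'   coefficients), `lambda`, `empty`, plus the thresholds used.
#' @export
select_features <- function(raw, norm, time, event,
                            variance_threshold = 0.01, rho_threshold = 0.95,
                            cv_folds = 5, seed = 1, lambda_grid = NULL) {
  vf <- variance_filter(raw, variance_threshold)
  sp <- spearman_prune(raw[, vf$keep, drop = FALSE], rho_threshold)
  survivors <- sp$keep
  las <- if (length(survivors) == 0L) {
    list(selected = numeric(0), lambda = NA_real_, empty = TRUE)
  } else {
    lasso_cox_select(norm[, survivors, drop = FALSE], time, event,
                     lambda_grid = lambda_grid, cv_folds = cv_folds,
                     seed = seed)
  }
  list(removed_by_variance = vf$removed,
       removed_by_correlation = sp$removed,
       lasso_selected = las$selected,
       lambda = las$lambda,
       empty = isTRUE(las$empty),
       variance_threshold = variance_threshold,
       rho_threshold = rho_threshold)
}
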