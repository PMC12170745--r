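#' Stratified train/test split
#'
#' Assigns `floor(train_frac * n)` patients to training, stratified jointly
#' by event indicator and tumor subtype: per-stratum training quotas are
#' `train_frac * n_s` rounded by largest remainder so stratum proportions
#' are preserved and the total is exact. Deterministic per seed.
#'
#' @param ids patient identifiers.
#' @param event event indicators (0/1).
#' @param subtype subtype labels.
#' @param train_frac training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors.
#' @export
split_cohort <- function(ids, event, subtype, train_frac = 0.7, seed = 1) {
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be in (0, 1)", call. = FALSE)
  n <- length(ids)
  strata <- interaction(event, subtype, drop = TRUE)
  total <- floor(train_frac * n)
  tab <- table(strata)
  if (any(tab == 0)) warning("empty stratum skipped")
  quota <- train_frac * as.vector(tab)
  base <- floor(quota)
  extra <- total - sum(base)
  rem <- quota - base
  ord <- order(-rem, names(tab))
  take <- base
  if (extra > 0) take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1L
  train_idx <- integer(0)
  with_seed(seed, {
    for (k in seq_along(tab)) {
      idx <- which(strata == names(tab)[k])
      train_idx <- c(train_idx, sort(sample(idx, take[k])))
    }
  })
  train_idx <- sort(train_idx)
  list(train = ids[train_idx], test = ids[-train_idx])
}

# clinical design matrices used by the model specifications
clinical_design <- function(clinical) {
  data.frame(
    preop_volume_ml = clinical$preop_volume_ml,
    postop_volume_ml = clinical$postop_volume_ml,
    eor_partial = as.integer(clinical$extent_of_resection == "partial"),
    eor_complete = as.integer(clinical$extent_of_resection == "complete"),
    astrocytoma = as.integer(clinical$subtype == "astrocytoma"),
    row.names = clinical$id)
}

# z-score a zone's columns on train and test; per protocol the test set
# uses its own statistics ("own"), switchable to training statistics
normalize_split <- function(raw_train, raw_test, test_stats = "own") {
  ztr <- zscore_normalize(raw_train)
  zte <- if (identical(test_stats, "own")) zscore_normalize(raw_test)
         else zscore_normalize(raw_test, center = attr(ztr, "center"),
                               scale = attr(ztr, "scale"))
  list(train = ztr, test = zte)
}

#' Run the full radiomics-versus-clinical survival study
#'
#' Orchestrates the whole pipeline on a generated (or loaded) cohort:
#' stratified 70:30 split; per-zone feature normalization and the
#' variance / Spearman / LASSO-Cox selection cascade on the training set;
#' fitting of the two clinical models, the four zone-wise radiomics models,
#' the two combined models (clinical covariates plus the best radiomics
#' zone's selected features, refit jointly) and the postoperative-volume
#' sensitivity variant; IPCW concordance evaluation on the test set with a
#' paired bootstrap; pairwise signed-rank model comparisons; and risk-group
#' stratification by the combined full model on the entire cohort. Every
#' random stage is seeded from the one master seed.
#'
#' @param cohort a cohort from [generate_cohort()] (with rendered images)
#'   or [load_cohort()].
#' @param feature_table optional precomputed [extract_feature_table()]
#'   output (skips extraction).
#' @param B bootstrap replicates.
#' @param tau truncation horizon (years) for the truncated c-index.
#' @param train_frac training fraction.
#' @param seed master seed.
#' @param test_stats `"own"` (test set normalized with its own statistics,
#'   as per protocol) or `"train"`.
#' @param spec a [discretization_spec()].
#' @param out_dir optional directory for the results record (JSON) and
#'   per-model metric table (CSV).
#' @return a results record list (see details in the metrics CSV columns):
#'   per-model feature counts, test Uno's c (point, bootstrap median/IQR),
#'   truncated variant, Harrell's c, pairwise comparisons, selection
#'   reports, risk-group stratification, and the split.
#' @export
run_study <- function(cohort, feature_table = NULL, B = 1000, tau = 5,
                      train_frac = 0.7, seed = 1, test_stats = "own",
                      spec = discretization_spec(), out_dir = NULL) {
  if (is.null(feature_table)) {
    if (is.null(cohort$patients))
      stop("cohort has no rendered images and no feature table supplied",
           call. = FALSE)
    feature_table <- extract_feature_table(cohort$patients, spec)
  }
  stopifnot(identical(feature_table$id, cohort$outcomes$id))
  ids <- cohort$outcomes$id
  time <- cohort$outcomes$time_years
  event <- cohort$outcomes$event
  clin <- clinical_design(cohort$clinical)

  split <- split_cohort(ids, event, cohort$clinical$subtype, train_frac,
                        seed = derive_seed(seed, 1))
  tr <- ids %in% split$train
  te <- !tr

  feats <- feature_table[, setdiff(names(feature_table), "id"),
                         drop = FALSE]
  ok_cols <- !vapply(feats, anyNA, logical(1))
  feats <- feats[, ok_cols, drop = FALSE]

  zones <- names(zone_specs())
  selection <- list(); rad_models <- list()
  risk_tr <- list(); risk_te <- list()
  norm_all <- list()
  for (zi in seq_along(zones)) {
    z <- zones[zi]
    cols <- grep(paste0("^", z, "_"), names(feats), value = TRUE)
    raw_tr <- feats[tr, cols, drop = FALSE]
    raw_te <- feats[te, cols, drop = FALSE]
    nz <- normalize_split(raw_tr, raw_te, test_stats)
    sel <- select_features(raw_tr, nz$train, time[tr], event[tr],
                           seed = derive_seed(seed, 10 + zi))
    selection[[z]] <- sel
    coefs <- sel$lasso_selected
    model <- structure(list(coef = coefs,
                            means = if (length(coefs))
                              colMeans(nz$train[, names(coefs),
                                                drop = FALSE])
                            else setNames(numeric(0), character(0)),
                            converged = TRUE, monotone = FALSE,
                            ties = "efron", l1_penalty = sel$lambda),
                       class = "radsurv_cox")
    rad_models[[z]] <- model
    risk_tr[[z]] <- risk_score(model, nz$train)
    risk_te[[z]] <- risk_score(model, nz$test)
    norm_all[[z]] <- nz
  }

  # best radiomics zone by training-set concordance (test set untouched)
  train_c <- vapply(zones, function(z) {
    if (length(rad_models[[z]]$coef) == 0L) return(0.5)
    uno_c(time[tr], event[tr], risk_tr[[z]])$estimate
  }, numeric(1))
  best_zone <- zones[which.max(train_c)]
  best_feats <- names(rad_models[[best_zone]]$coef)

  fit_clinical <- function(cols, rows) {
    fit_cox(clin[rows, cols, drop = FALSE], time[rows], event[rows])
  }
  preop_cols <- "preop_volume_ml"
  full_cols <- c("preop_volume_ml", "eor_partial", "eor_complete",
                 "astrocytoma")
  postop_cols <- c("preop_volume_ml", "postop_volume_ml", "astrocytoma")

  m_preop <- fit_clinical(preop_cols, tr)
  m_full <- fit_clinical(full_cols, tr)
  m_postop <- fit_clinical(postop_cols, tr)

  comb_design <- function(rows, set) {
    rad <- if (length(best_feats))
      norm_all[[best_zone]][[set]][, best_feats, drop = FALSE]
    else NULL
    base <- clin[rows, , drop = FALSE]
    if (is.null(rad)) base else cbind(base, rad)
  }
  X_comb_tr <- comb_design(tr, "train")
  X_comb_te <- comb_design(te, "test")
  m_comb_preop <- fit_cox(X_comb_tr[, c(preop_cols, best_feats),
                                    drop = FALSE], time[tr], event[tr])
  m_comb_full <- fit_cox(X_comb_tr[, c(full_cols, best_feats),
                                   drop = FALSE], time[tr], event[tr])

  model_names <- c("preop_clinical", "full_clinical",
                   paste0("radiomics_", zones),
                   "combined_preop", "combined_full",
                   "full_clinical_postop")
  risks_test <- c(
    list(preop_clinical = risk_score(m_preop, clin[te, , drop = FALSE]),
         full_clinical = risk_score(m_full, clin[te, , drop = FALSE])),
    setNames(lapply(zones, function(z) risk_te[[z]]),
             paste0("radiomics_", zones)),
    list(combined_preop = risk_score(m_comb_preop, X_comb_te),
         combined_full = risk_score(m_comb_full, X_comb_te),
         full_clinical_postop = risk_score(m_postop,
                                           clin[te, , drop = FALSE])))
  n_features <- c(preop_clinical = 1L, full_clinical = 3L,
                  setNames(vapply(zones, function(z)
                    length(rad_models[[z]]$coef), integer(1)),
                    paste0("radiomics_", zones)),
                  combined_preop = 1L + length(best_feats),
                  combined_full = 3L + length(best_feats),
                  full_clinical_postop = 3L)

  km_te <- km_estimator(time[te], event[te])
  point <- lapply(risks_test, function(r) {
    list(uno = uno_c(time[te], event[te], r, km = km_te)$estimate,
         uno_tau = uno_c(time[te], event[te], r, tau = tau,
                         km = km_te)$estimate,
         harrell = harrell_c(time[te], event[te], r)$estimate)
  })
  boot <- bootstrap_distribution(time[te], event[te], risks_test, B = B,
                                 tau = tau, seed = derive_seed(seed, 3))

  cmp_models <- c("preop_clinical", "full_clinical",
                  paste0("radiomics_", best_zone),
                  "combined_preop", "combined_full")
  comparisons <- list()
  for (i in seq_along(cmp_models)) for (j in seq_along(cmp_models)) {
    if (i >= j) next
    a <- cmp_models[i]; b <- cmp_models[j]
    key <- paste(a, "vs", b)
    comparisons[[key]] <- list(
      uno = compare_distributions(boot[[a]], boot[[b]], "uno"),
      uno_tau = compare_distributions(boot[[a]], boot[[b]], "uno_tau"))
  }

  # risk groups from the combined full model on the entire cohort
  risk_all <- numeric(length(ids))
  risk_all[tr] <- risk_score(m_comb_full, comb_design(tr, "train"))
  risk_all[te] <- risk_score(m_comb_full, X_comb_te)
  strat <- find_cutpoint(risk_all, time, event, min_frac = 0.33)
  km_groups <- km_curves(time, event, strat$group)
  subtype_strat <- lapply(c("astrocytoma", "oligodendroglioma"),
                          function(st) {
    sel <- cohort$clinical$subtype == st
    g <- strat$group[sel]
    if (nlevels(droplevels(g)) < 2L)
      return(list(note = "single risk group in subtype"))
    lt <- logrank_test(time[sel], event[sel], g)
    list(chisq = lt$chisq, p_value = lt$p_value,
         n_per_group = lt$n_per_group)
  })
  names(subtype_strat) <- c("astrocytoma", "oligodendroglioma")

  # linear SHAP explanations of the full clinical and best radiomics models
  shap_full <- linear_shap(m_full, clin[tr, , drop = FALSE],
                           clin[te, , drop = FALSE])
  shap_rad <- linear_shap(rad_models[[best_zone]],
                          norm_all[[best_zone]]$train,
                          norm_all[[best_zone]]$test)
  shap_summary <- list(
    full_clinical = as.list(colMeans(abs(shap_full))),
    best_radiomics = if (ncol(shap_rad)) as.list(colMeans(abs(shap_rad)))
                     else list())

  metrics <- data.frame(
    model = model_names,
    n_features = as.integer(n_features[model_names]),
    uno_c = vapply(model_names, function(m) point[[m]]$uno, numeric(1)),
    uno_c_boot_median = vapply(model_names, function(m) boot[[m]]$median,
                               numeric(1)),
    uno_c_boot_iqr = vapply(model_names, function(m) boot[[m]]$iqr,
                            numeric(1)),
    uno_c_tau = vapply(model_names, function(m) point[[m]]$uno_tau,
                       numeric(1)),
    uno_c_tau_boot_median = vapply(model_names, function(m)
      boot[[m]]$median_tau, numeric(1)),
    uno_c_tau_boot_iqr = vapply(model_names, function(m)
      boot[[m]]$iqr_tau, numeric(1)),
    harrell_c = vapply(model_names, function(m) point[[m]]$harrell,
                       numeric(1)),
    row.names = NULL)

  results <- list(
    seed = seed, B = B, tau = tau, train_frac = train_frac,
    n_patients = length(ids),
    n_train = sum(tr), n_test = sum(te),
    split = split,
    best_radiomics_zone = best_zone,
    models = metrics,
    selection = lapply(selection, function(s) list(
      n_removed_by_variance = length(s$removed_by_variance),
      n_removed_by_correlation = nrow(s$removed_by_correlation),
      lasso_selected = as.list(s$lasso_selected),
      empty = s$empty)),
    comparisons = lapply(comparisons, function(cp) list(
      uno_p = cp$uno$p_value, uno_tau_p = cp$uno_tau$p_value)),
    stratification = list(threshold = strat$threshold,
                          chisq = strat$chisq, p_value = strat$p_value,
                          n_high = strat$n_high, n_low = strat$n_low,
                          by_subtype = subtype_strat),
    shap_mean_abs = shap_summary)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_results_json(results, file.path(out_dir, "results.json"))
    write.csv(metrics, file.path(out_dir, "model_metrics.csv"),
              row.names = FALSE)
  }
  results$boot <- boot
  results$risk_all <- risk_all
  results$group <- strat$group
  results$km_groups <- km_groups
  invisible(results)
}

#' Load a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a cohort list usable by [run_study()].
#' @export
load_cohort <- function(dir) {
  need <- file.path(dir, c("clinical.csv", "outcomes.csv", "brain.nii.gz"))
  absent <- need[!file.exists(need)]
  if (length(absent))
    stop("missing cohort input file(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  clinical <- read.csv(file.path(dir, "clinical.csv"),
                       stringsAsFactors = FALSE)
  outcomes <- read.csv(file.path(dir, "outcomes.csv"),
                       stringsAsFactors = FALSE)
  brain_img <- RNifti::readNifti(file.path(dir, "brain.nii.gz"))
  spacing <- RNifti::pixdim(brain_img)[1:3]
  brain <- array(as.vector(brain_img) > 0.5, dim(brain_img))
  patients <- lapply(clinical$id, function(id) {
    rd <- function(name) {
      v <- RNifti::readNifti(file.path(dir, sprintf("%s_%s.nii.gz", name,
                                                    id)))
      array(as.vector(v), dim(v))
    }
    list(id = id,
         images = list(T1c = rd("t1c"), FLAIR = rd("flair")),
         tumor = array(as.vector(rd("tumor")) > 0.5,
                       dim(brain)),
         brain = brain, spacing_mm = spacing)
  })
  list(cfg = NULL, clinical = clinical, outcomes = outcomes,
       patients = patients)
}
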