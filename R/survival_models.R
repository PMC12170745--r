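#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with the Efron tie correction
#' (optionally L1-penalized). Monotone-likelihood degeneracies (divergent
#' coefficients) are detected and flagged rather than silently returned as
#' converged.
#'
#' @param X matrix or data.frame of covariates (possibly zero columns for
#'   the null model).
#' @param time,event outcome vectors (time in years, event 0/1).
#' @param l1_penalty nonnegative L1 penalty; 0 gives the unpenalized fit.
#' @return an object of class `radsurv_cox`: `coef` (named), `means`
#'   (training feature means), `converged`, `monotone` (monotone-likelihood
#'   flag), `ties`, `l1_penalty`.
#' @export
fit_cox <- function(X, time, event, l1_penalty = 0) {
  X <- as.data.frame(X)
  if (sum(event) == 0) stop("no events: Cox model undefined", call. = FALSE)
  if (length(time) != nrow(X) && ncol(X) > 0)
    stop("X and outcomes disagree in length", call. = FALSE)
  if (anyNA(X)) stop("missing covariate values", call. = FALSE)
  if (ncol(X) > 0) {
    sds <- vapply(X, sd, numeric(1))
    if (any(sds == 0))
      stop("constant covariate(s): ",
           paste(names(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  if (ncol(X) == 0L) {
    return(structure(list(coef = setNames(numeric(0), character(0)),
                          means = setNames(numeric(0), character(0)),
                          converged = TRUE, monotone = FALSE,
                          ties = "efron", l1_penalty = 0),
                     class = "radsurv_cox"))
  }
  if (l1_penalty > 0) {
    fit <- glmnet::glmnet(as.matrix(X), survival::Surv(time, event),
                          family = "cox", alpha = 1, lambda = l1_penalty,
                          standardize = FALSE)
    co <- as.matrix(glmnet::coef.glmnet(fit, s = l1_penalty))[, 1]
    return(structure(list(coef = co, means = colMeans(X), converged = TRUE,
                          monotone = FALSE, ties = "efron",
                          l1_penalty = l1_penalty),
                     class = "radsurv_cox"))
  }
  dat <- cbind(data.frame(.time = time, .event = event), X)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(X)), collapse = " + ")))
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|converged before",
                conditionMessage(w)))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- setNames(stats::coef(fit), names(X))
  structure(list(coef = co, means = colMeans(X),
                 converged = !monotone && fit$iter < 50,
                 monotone = monotone, ties = "efron", l1_penalty = 0,
                 loglik = fit$loglik, iter = fit$iter),
            class = "radsurv_cox")
}

#' @export
print.radsurv_cox <- function(x, ...) {
  cat("Cox model (", length(x$coef), " covariates, ties = ", x$ties,
      if (x$monotone) ", MONOTONE LIKELIHOOD" else "", ")\n", sep = "")
  if (length(x$coef)) print(round(x$coef, 4))
  invisible(x)
}

#' Linear risk score of a Cox model
#'
#' The linear predictor `beta . x`. No baseline hazard is involved: ranking,
#' concordance and risk stratification depend only on this score.
#'
#' @param model a `radsurv_cox` object.
#' @param X data.frame/matrix containing all model features.
#' @return numeric vector of risk scores (0 for the null model).
#' @export
risk_score <- function(model, X) {
  X <- as.data.frame(X)
  if (length(model$coef) == 0L) return(rep(0, nrow(X)))
  missing <- setdiff(names(model$coef), names(X))
  if (length(missing))
    stop("missing model feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  as.vector(as.matrix(X[, names(model$coef), drop = FALSE]) %*% model$coef)
}

#' Exact Shapley values for a linear risk model
#'
#' For a linear model with an independent-feature value function the Shapley
#' attribution has the closed form `phi_j = beta_j (x_j - mean_bg(x_j))`,
#' so each patient's attributions sum to their risk minus the mean
#' background risk (local accuracy).
#'
#' @param model a `radsurv_cox` object.
#' @param background data.frame of background patients (e.g. training set).
#' @param X data.frame of patients to explain.
#' @return matrix (patients x features) of Shapley contributions.
#' @export
linear_shap <- function(model, background, X) {
  background <- as.data.frame(background)
  X <- as.data.frame(X)
  if (nrow(background) == 0L) stop("background set is empty", call. = FALSE)
  feats <- names(model$coef)
  missing <- setdiff(feats, intersect(names(background), names(X)))
  if (length(missing))
    stop("feature mismatch: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(feats) == 0L)
    return(matrix(numeric(0), nrow = nrow(X), ncol = 0))
  mu <- colMeans(background[, feats, drop = FALSE])
  phi <- sweep(as.matrix(X[, feats, drop = FALSE]), 2, mu, `-`)
  sweep(phi, 2, model$coef, `*`)
}
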