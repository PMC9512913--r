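#' Single-feature and feature/disease-duration CATE rankers
#'
#' The simplest comparator rankers: the (signed) value of one baseline
#' feature, optionally divided by disease duration, is taken as the CATE
#' estimate. For example, "negative disease duration" (sign -1) predicts a
#' larger effect for shorter disease duration, and "T2 lesion
#' volume/disease duration" predicts a larger effect for a faster historical
#' rate of lesion accumulation.
#'
#' @param patients Baseline data frame or `trial_dataset`.
#' @param feature Feature name.
#' @param sign `+1` or `-1`.
#' @param divide_by_disease_duration If `TRUE`, the feature is divided by
#'   disease duration first.
#' @return Numeric vector of CATE estimates, one per patient.
#' @export
feature_ranker <- function(patients, feature, sign = 1,
                           divide_by_disease_duration = FALSE) {
  if (inherits(patients, "trial_dataset")) patients <- patients$patients
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  if (!feature %in% names(patients)) stop("unknown feature: ", feature)
  v <- as.numeric(patients[[feature]])
  if (divide_by_disease_duration) {
    dd <- as.numeric(patients$disease_duration)
    zero <- which(dd == 0)
    if (length(zero) > 0L) {
      stop("zero disease duration for patient(s): ",
           paste(patients$patient_id[zero], collapse = ", "))
    }
    v <- v / dd
  }
  sign * v
}

# ridge regression by the normal equations: centered predictors, unpenalized
# intercept; lambda -> 0 recovers OLS exactly
.ridge_fit <- function(X, y, lambda) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  beta <- solve(crossprod(Xc) + lambda * diag(ncol(X)),
                crossprod(Xc, y - ym))
  list(beta = drop(beta), intercept = ym - sum(xm * beta))
}

#' Ridge-regression T-learner
#'
#' Fits one L2-regularized linear regression of the EDSS slope on the
#' features per arm; the CATE estimate for a patient is
#' `-(mu_hat_treatment - mu_hat_control)`, matching the MLP's
#' benefit-positive sign convention.
#'
#' @param X Feature matrix.
#' @param y Slope targets.
#' @param alloc Arm allocation per patient.
#' @param treatment_arm,control_arm Arm ids.
#' @param lambda Ridge penalty (default 1e-3).
#' @return Object of class `ridge_tlearner` with a [predict()] method that
#'   returns CATE estimates for new feature rows.
#' @export
ridge_tlearner <- function(X, y, alloc, treatment_arm, control_arm,
                           lambda = 1e-3) {
  sel1 <- alloc == treatment_arm
  sel0 <- alloc == control_arm
  if (!any(sel1) || !any(sel0)) stop("both arms need patients")
  structure(list(fit1 = .ridge_fit(X[sel1, , drop = FALSE], y[sel1], lambda),
                 fit0 = .ridge_fit(X[sel0, , drop = FALSE], y[sel0], lambda),
                 lambda = lambda),
            class = "ridge_tlearner")
}

#' @export
predict.ridge_tlearner <- function(object, newdata, ...) {
  mu1 <- drop(newdata %*% object$fit1$beta) + object$fit1$intercept
  mu0 <- drop(newdata %*% object$fit0$beta) + object$fit0$intercept
  -(mu1 - mu0)
}

#' Cox proportional-hazards T-learner
#'
#' Fits one Cox model of time-to-CDP24 on the features per arm (Breslow
#' ties). The CATE estimate is the difference of linear predictors, control
#' minus treatment: a patient whose covariates predict high progression
#' hazard under control but low hazard under treatment scores high. Only the
#' ranking of these scores is consumed by the AD(c) evaluation, so any
#' monotone rescaling is equivalent.
#'
#' @param X Feature matrix.
#' @param time,event CDP24 survival labels.
#' @param alloc Arm allocation per patient.
#' @param treatment_arm,control_arm Arm ids.
#' @return Object of class `cph_tlearner` with a [predict()] method
#'   returning CATE scores.
#' @export
cph_tlearner <- function(X, time, event, alloc, treatment_arm, control_arm) {
  fit_arm <- function(sel) {
    df <- as.data.frame(X[sel, , drop = FALSE])
    df$.time <- time[sel]
    df$.event <- as.numeric(event[sel])
    survival::coxph(survival::Surv(.time, .event) ~ ., data = df,
                    ties = "breslow")
  }
  sel1 <- alloc == treatment_arm
  sel0 <- alloc == control_arm
  if (!any(sel1) || !any(sel0)) stop("both arms need patients")
  structure(list(fit1 = fit_arm(sel1), fit0 = fit_arm(sel0)),
            class = "cph_tlearner")
}

#' @export
predict.cph_tlearner <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  lp1 <- drop(as.matrix(nd[, names(stats::coef(object$fit1)), drop = FALSE]) %*%
                stats::coef(object$fit1))
  lp0 <- drop(as.matrix(nd[, names(stats::coef(object$fit0)), drop = FALSE]) %*%
                stats::coef(object$fit0))
  lp0 - lp1
}

#' Prognostic ranker
#'
#' Trains the MLP machinery on placebo-arm patients only (a single-headed
#' model) and uses the predicted placebo slope as the CATE estimate: a
#' patient predicted to worsen faster without treatment (worse prognosis)
#' is ranked as more responsive. Fitted as a cross-validated ensemble like
#' the full model.
#'
#' @param X Feature matrix (all patients).
#' @param y Slope targets.
#' @param alloc Arm allocation per patient.
#' @param placebo_arm Id of the placebo arm.
#' @param hp An [mlp_hyperparams()].
#' @param k Folds (default 4).
#' @param seed Seed.
#' @return Object of class `prognostic_ranker` with a [predict()] method
#'   returning predicted placebo slopes as CATE scores.
#' @export
prognostic_ranker <- function(X, y, alloc, placebo_arm, hp, k = 4L,
                              seed = 1L) {
  sel <- alloc == placebo_arm
  if (!any(sel)) stop("no placebo patients in the dataset")
  ens <- cross_validated_ensemble(X[sel, , drop = FALSE], y[sel],
                                  rep(placebo_arm, sum(sel)), hp,
                                  k = k, seed = seed,
                                  arms = placebo_arm)
  structure(list(ensemble = ens, placebo_arm = placebo_arm),
            class = "prognostic_ranker")
}

#' @export
predict.prognostic_ranker <- function(object, newdata, ...) {
  drop(predict(object$ensemble, newdata)[, object$placebo_arm])
}

#' Age/Gad binary responder rule
#'
#' The subgroup rule from the OLYMPUS post-hoc analysis: a patient is a
#' predicted responder when age is strictly below 51 years and the baseline
#' Gad lesion count is strictly positive.
#'
#' @param patients Baseline data frame or `trial_dataset` with `age` and
#'   `gad_count` columns.
#' @return Logical responder flags.
#' @export
hawker_rule <- function(patients) {
  if (inherits(patients, "trial_dataset")) patients <- patients$patients
  patients$age < 51 & patients$gad_count > 0
}
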