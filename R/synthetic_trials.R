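# reference moments used by the default slope/effect functions so that they
# are deterministic functions of the raw features, independent of any sample
.ref_moments <- list(
  age = c(mean = 46, sd = 8),
  disease_duration = c(mean = 7, sd = 5),
  edss = c(mean = 4.6, sd = 1.2),
  gad_count = c(mean = 0.8, sd = 2.5),
  t2_volume = c(mean = 9, sd = 12)
)

.zref <- function(patients, feature) {
  m <- .ref_moments[[feature]]
  (as.numeric(patients[[feature]]) - m["mean"]) / m["sd"]
}

#' Default heterogeneous treatment-effect function
#'
#' A bounded, strongly heterogeneous effect on the EDSS slope scale
#' (benefit-positive, EDSS/yr): a logistic index favouring patients with
#' more focal inflammation (higher Gad count and T2 volume), shorter disease
#' duration, younger age and higher baseline EDSS, scaled to a 0-0.35
#' EDSS/yr range. Mirrors the qualitative responder profile reported for
#' B-cell-depleting therapy in progressive MS.
#'
#' @param patients Baseline data frame.
#' @return Effect per patient (EDSS/yr by which treatment slows worsening).
#' @export
default_tau <- function(patients) {
  idx <- 0.9 * .zref(patients, "gad_count") +
    0.7 * .zref(patients, "t2_volume") -
    0.8 * .zref(patients, "disease_duration") -
    0.6 * .zref(patients, "age") +
    0.4 * .zref(patients, "edss")
  0.35 * stats::plogis(idx)
}

#' Linear heterogeneous treatment-effect function
#'
#' Builds an effect function that is linear in reference-standardized
#' baseline features. The defaults give a strong, linearly heterogeneous
#' effect (mean 0.15 EDSS/yr, SD about 0.14 across a PPMS-like cohort) with
#' the same responder profile as [default_tau()]; individual effects may be
#' negative. Used to study effect-ranking recovery under a known linear
#' ground truth.
#'
#' @param intercept Mean effect (EDSS/yr).
#' @param coefs Named vector of per-feature coefficients on the
#'   reference-standardized scale; names must be features with reference
#'   moments (`age`, `disease_duration`, `edss`, `gad_count`, `t2_volume`).
#' @return A `function(patients) -> numeric` usable as `tau` in
#'   [synthetic_config()].
#' @export
linear_tau <- function(intercept = 0.15,
                       coefs = c(gad_count = 0.08, t2_volume = 0.06,
                                 disease_duration = -0.07, age = -0.05,
                                 edss = 0.04)) {
  bad <- setdiff(names(coefs), names(.ref_moments))
  if (length(bad) > 0L) {
    stop("no reference moments for feature(s): ", paste(bad, collapse = ", "))
  }
  force(intercept)
  force(coefs)
  function(patients) {
    out <- rep(intercept, nrow(patients))
    for (f in names(coefs)) out <- out + coefs[[f]] * .zref(patients, f)
    out
  }
}

#' Default placebo progression-rate function
#'
#' Expected EDSS worsening rate without treatment: around 0.22 EDSS/yr,
#' slightly faster with higher baseline disability and lesion load.
#'
#' @param patients Baseline data frame.
#' @return Placebo slope per patient (EDSS/yr).
#' @export
default_beta0 <- function(patients) {
  0.22 + 0.05 * .zref(patients, "edss") + 0.04 * .zref(patients, "t2_volume")
}

#' Configuration for a synthetic randomized trial dataset
#'
#' Describes a multi-trial, multi-arm randomized dataset with known
#' ground-truth treatment effects: per-trial sample sizes and randomization
#' probabilities, an arm registry with per-arm effect multipliers, the true
#' placebo slope and effect functions, the visit schedule, EDSS observation
#' noise, dropout hazard, and per-trial multiplicative scale shifts on the
#' recorded MRI metrics (emulating inter-trial segmentation differences; the
#' shifts distort the recorded values only, not the biology driving
#' outcomes, which is what the cross-trial reference scaling must undo).
#'
#' @param trials List of per-trial lists: `trial_id`, `n`, `arm_probs`
#'   (named randomization probabilities), optional `mri_scale` (named
#'   multipliers for `gad_count`, `t2_volume`, `nbv`).
#' @param arms Arm registry data frame (`arm_id`, `name`, `is_control`).
#' @param effect_multiplier Named per-arm multiplier on `tau` (0 for
#'   control arms).
#' @param beta0,tau Functions of the baseline data frame returning the
#'   placebo slope and the base treatment effect (EDSS/yr,
#'   benefit-positive).
#' @param patient_noise_sd SD of the patient-level random slope component
#'   (EDSS/yr).
#' @param edss_noise_sd SD of per-visit EDSS observation noise (before
#'   rounding to the valid grid); the baseline visit is recorded exactly.
#' @param schedule_weeks Visit schedule in weeks from baseline.
#' @param dropout_rate Exponential censoring hazard (1/years), arm-
#'   independent.
#' @param profile Feature-distribution profile, `"ppms"` or `"rrms"`.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(trials, arms, effect_multiplier,
                             beta0 = default_beta0, tau = default_tau,
                             patient_noise_sd = 0.35, edss_noise_sd = 0.3,
                             schedule_weeks = seq(0, 120, by = 12),
                             dropout_rate = 0.12,
                             profile = c("ppms", "rrms")) {
  profile <- match.arg(profile)
  stopifnot(length(trials) >= 1, schedule_weeks[1] == 0,
            patient_noise_sd >= 0, edss_noise_sd >= 0, dropout_rate >= 0)
  for (tr in trials) {
    if (tr$n <= 0) stop("trial n must be positive: ", tr$trial_id)
    if (!all(names(tr$arm_probs) %in% arms$arm_id)) {
      stop("arm_probs references unregistered arm in trial ", tr$trial_id)
    }
  }
  if (!all(arms$arm_id %in% names(effect_multiplier))) {
    stop("effect_multiplier must cover every registered arm")
  }
  if (any(effect_multiplier[arms$arm_id[arms$is_control]] != 0)) {
    stop("control arms must have effect multiplier 0")
  }
  structure(list(trials = trials, arms = arms,
                 effect_multiplier = effect_multiplier,
                 beta0 = beta0, tau = tau,
                 patient_noise_sd = patient_noise_sd,
                 edss_noise_sd = edss_noise_sd,
                 schedule_weeks = schedule_weeks,
                 dropout_rate = dropout_rate,
                 profile = profile),
            class = "synthetic_config")
}

#' Default two-arm PPMS-like configuration
#'
#' Two placebo-controlled primary-progressive trials (2:1 treatment :
#' control randomization) pooling to `n` patients, with a Table-1-like
#' feature profile and a 30% relative MRI scale shift in the second trial.
#'
#' @param n Total patients across the two trials.
#' @param ratio Treatment:control randomization ratio (default 2).
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
ppms_synthetic_config <- function(n = 2000L, ratio = 2, ...) {
  p_treat <- ratio / (ratio + 1)
  arm_probs <- c(anti_cd20 = p_treat, placebo = 1 - p_treat)
  n1 <- round(n * 0.6)
  synthetic_config(
    trials = list(
      list(trial_id = "PPMS_A", n = n1, arm_probs = arm_probs),
      list(trial_id = "PPMS_B", n = n - n1, arm_probs = arm_probs,
           mri_scale = c(gad_count = 1.5, t2_volume = 1.3, nbv = 0.85))),
    arms = data.frame(arm_id = c("anti_cd20", "placebo"),
                      name = c("anti-CD20 antibody", "placebo"),
                      is_control = c(FALSE, TRUE)),
    effect_multiplier = c(anti_cd20 = 1, placebo = 0),
    profile = "ppms", ...)
}

#' Default five-arm RRMS-like configuration for pretraining
#'
#' A pooled relapsing-remitting dataset with four active arms plus placebo,
#' sharing the same effect structure as the PPMS configuration (scaled per
#' arm), a younger/less-disabled feature profile, and a mild MRI scale
#' shift in the second trial.
#'
#' @param n Total patients.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
rrms_synthetic_config <- function(n = 2500L, ...) {
  arm_ids <- c("ocrelizumab", "ifnb_sc", "laquinimod", "ifnb_im", "placebo")
  arm_probs <- stats::setNames(rep(0.2, 5L), arm_ids)
  n1 <- round(n * 0.55)
  synthetic_config(
    trials = list(
      list(trial_id = "RRMS_A", n = n1, arm_probs = arm_probs),
      list(trial_id = "RRMS_B", n = n - n1, arm_probs = arm_probs,
           mri_scale = c(gad_count = 1.3, t2_volume = 1.2, nbv = 0.9))),
    arms = data.frame(
      arm_id = arm_ids,
      name = c("ocrelizumab", "SC interferon beta-1a", "laquinimod",
               "IM interferon beta-1a", "placebo"),
      is_control = c(FALSE, FALSE, FALSE, FALSE, TRUE)),
    effect_multiplier = c(ocrelizumab = 1.2, ifnb_sc = 0.7, laquinimod = 0.5,
                          ifnb_im = 0.4, placebo = 0),
    profile = "rrms", ...)
}

#' Ground-truth CATE under a synthetic configuration
#'
#' Deterministic evaluation of the configured effect function on baseline
#' rows, on the benefit-positive convention (positive = slower worsening on
#' treatment relative to control, for an arm with effect multiplier 1).
#'
#' @param config A `synthetic_config`.
#' @param patients Baseline data frame (or `trial_dataset`).
#' @return Numeric effect per patient (EDSS/yr).
#' @export
true_cate <- function(config, patients) {
  if (inherits(patients, "trial_dataset")) patients <- patients$patients
  config$tau(patients)
}

# round to the valid EDSS grid (0, 1, 1.5, ..., 10): ordinary half-point
# rounding, with the invalid 0.5 cell resolved to its nearest valid value
.round_edss <- function(y) {
  y <- pmin(pmax(y, 0), 10)
  r <- round(y * 2) / 2
  mid <- r == 0.5
  r[mid] <- ifelse(y[mid] < 0.5, 0, 1)
  r
}

.sample_features <- function(n, profile) {
  rfss <- function(n, mean, sd) pmin(pmax(round(stats::rnorm(n, mean, sd)), 0), 6)
  if (profile == "ppms") {
    grid <- seq(3, 6.5, by = 0.5)
    edss <- sample(grid, n, replace = TRUE, prob = stats::dnorm(grid, 4.6, 1.0))
    age <- stats::rnorm(n, 46, 8)
    dd <- stats::rlnorm(n, log(6.5), 0.55)
  } else {
    grid <- c(0, seq(1, 5.5, by = 0.5))
    edss <- sample(grid, n, replace = TRUE, prob = stats::dnorm(grid, 2.5, 1.2))
    age <- stats::rnorm(n, 36, 9)
    dd <- stats::rlnorm(n, log(4.5), 0.6)
  }
  data.frame(
    age = pmin(pmax(age, 18), 70),
    sex = stats::rbinom(n, 1, 0.5),
    height = stats::rnorm(n, 170.5, 9.4),
    weight = pmax(stats::rnorm(n, 74, 16), 35),
    disease_duration = pmax(dd, 0.1),
    edss = edss,
    fss_bowel_bladder = rfss(n, 1.2, 0.9),
    fss_brainstem = rfss(n, 0.85, 0.9),
    fss_cerebellar = rfss(n, 2.1, 1.0),
    fss_cerebral = rfss(n, 1.0, 0.85),
    fss_pyramidal = rfss(n, 2.8, 0.7),
    fss_sensory = rfss(n, 1.6, 1.0),
    fss_visual = rfss(n, 0.8, 1.0),
    t25fw = stats::rlnorm(n, log(10), 0.6),
    nhpt_dominant = stats::rlnorm(n, log(29), 0.4),
    nhpt_nondominant = stats::rlnorm(n, log(31), 0.45),
    gad_count = stats::rnbinom(n, size = 0.35, mu = 0.8),
    t2_volume = stats::rlnorm(n, log(6.5), 1.0),
    nbv = stats::rnorm(n, 1.45, 0.09)
  )
}

#' Generate a synthetic randomized trial dataset
#'
#' Samples baseline features per trial, assigns arms by the configured
#' randomization probabilities (independently of the features), draws each
#' patient's latent slope as `beta0(x) - multiplier(arm) * tau(x) + noise`,
#' builds EDSS visit series on the configured schedule (baseline value plus
#' slope times time plus observation noise, rounded to the valid EDSS grid
#' and clamped to [0, 10]; the baseline visit is recorded exactly), applies
#' exponential dropout censoring, and finally applies the per-trial MRI
#' scale shifts to the *recorded* feature values. The effect functions are
#' evaluated on the undistorted features, so the scale shift is purely a
#' measurement artifact.
#'
#' @param config A `synthetic_config`.
#' @param seed Integer seed; the same seed always reproduces the dataset
#'   byte for byte.
#' @return List with `dataset` (a [trial_dataset()]) and `truth` (data
#'   frame of `patient_id`, `arm_id`, `tau` — the base effect,
#'   benefit-positive — `effect` — the multiplier-scaled effect actually
#'   applied — and `latent_slope`).
#' @export
generate_dataset <- function(config, seed = 1L) {
  set.seed(seed)
  times <- config$schedule_weeks * 7 / 365.25
  nv <- length(times)
  pat_list <- list()
  truth_list <- list()
  vis_list <- list()
  for (tr in config$trials) {
    n <- tr$n
    feats <- .sample_features(n, config$profile)
    pid <- sprintf("%s-%05d", tr$trial_id, seq_len(n))
    arm <- sample(names(tr$arm_probs), n, replace = TRUE,
                  prob = as.numeric(tr$arm_probs))
    tau <- config$tau(feats)
    eff <- as.numeric(config$effect_multiplier[arm]) * tau
    slope <- config$beta0(feats) - eff +
      stats::rnorm(n, 0, config$patient_noise_sd)
    # EDSS trajectories: n x nv matrix, baseline column exact
    noise <- matrix(stats::rnorm(n * nv, 0, config$edss_noise_sd), n, nv)
    noise[, 1L] <- 0
    E <- matrix(feats$edss, n, nv) + outer(slope, times) + noise
    E <- matrix(.round_edss(E), n, nv)
    E[, 1L] <- feats$edss
    censor <- if (config$dropout_rate > 0) {
      stats::rexp(n, config$dropout_rate)
    } else {
      rep(Inf, n)
    }
    keep <- outer(censor, times, `>=`)
    keep[, 1L] <- TRUE
    vis <- data.frame(patient_id = rep(pid, each = nv),
                      time_years = rep(times, times = n),
                      edss = as.vector(t(E)),
                      stringsAsFactors = FALSE)
    vis <- vis[as.vector(t(keep)), , drop = FALSE]
    # recorded MRI values carry the trial's scale distortion
    if (!is.null(tr$mri_scale)) {
      for (f in names(tr$mri_scale)) {
        feats[[f]] <- feats[[f]] * tr$mri_scale[[f]]
        if (f == "gad_count") feats[[f]] <- round(feats[[f]])
      }
    }
    pat_list[[tr$trial_id]] <- cbind(
      data.frame(patient_id = pid, trial_id = tr$trial_id, arm_id = arm,
                 stringsAsFactors = FALSE),
      feats)
    truth_list[[tr$trial_id]] <- data.frame(
      patient_id = pid, arm_id = arm, tau = tau, effect = eff,
      latent_slope = slope, stringsAsFactors = FALSE)
    vis_list[[tr$trial_id]] <- vis
  }
  patients <- do.call(rbind, pat_list)
  rownames(patients) <- NULL
  visits <- do.call(rbind, vis_list)
  rownames(visits) <- NULL
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL
  list(dataset = trial_dataset(patients, visits, config$arms),
       truth = truth)
}
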