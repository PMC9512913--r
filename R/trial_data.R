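#' Valid EDSS grid
#'
#' The Expanded Disability Status Scale takes values 0 (no disability) to 10
#' (death) in 0.5 steps, except that the step between 0.0 and 1.0 is a full
#' point: 0.5 is not a valid score.
#'
#' @return Numeric vector of all valid EDSS values.
#' @export
edss_grid <- function() {
  c(0, seq(1, 10, by = 0.5))
}

#' Check EDSS values against the valid grid
#'
#' @param x Numeric vector.
#' @param tol Absolute tolerance for grid membership.
#' @return Logical vector, `TRUE` where `x` is a valid EDSS score.
#' @export
is_valid_edss <- function(x, tol = 1e-8) {
  grid <- edss_grid()
  vapply(x, function(v) is.finite(v) && any(abs(v - grid) < tol), logical(1))
}

#' Baseline feature schema
#'
#' The 19 baseline features used for effect modelling: demographics, the EDSS
#' and its seven Functional Systems Scores (FSS), timed tests, and scalar MRI
#' metrics. `log_transform` marks the right-skewed features that are
#' natural-log transformed during preprocessing (normalized brain volume, T2
#' lesion volume, timed 25-foot walk, both 9-hole peg tests); `mri_scaled`
#' marks the segmentation-derived MRI metrics that undergo cross-trial
#' reference scaling (Gad lesion count, T2 lesion volume, normalized brain
#' volume).
#'
#' @return A data frame with columns `name`, `kind` (one of `"binary"`,
#'   `"ordinal"`, `"discrete"`, `"continuous"`), `log_transform`, `mri_scaled`.
#' @export
feature_schema <- function() {
  fss <- c("fss_bowel_bladder", "fss_brainstem", "fss_cerebellar",
           "fss_cerebral", "fss_pyramidal", "fss_sensory", "fss_visual")
  nm <- c("age", "sex", "height", "weight", "disease_duration", "edss", fss,
          "t25fw", "nhpt_dominant", "nhpt_nondominant",
          "gad_count", "t2_volume", "nbv")
  kind <- c("continuous", "binary", "continuous", "continuous", "continuous",
            "ordinal", rep("ordinal", 7L),
            "continuous", "continuous", "continuous",
            "discrete", "continuous", "continuous")
  data.frame(
    name = nm,
    kind = kind,
    log_transform = nm %in% c("nbv", "t2_volume", "t25fw",
                              "nhpt_dominant", "nhpt_nondominant"),
    mri_scaled = nm %in% c("gad_count", "t2_volume", "nbv"),
    stringsAsFactors = FALSE
  )
}

#' Assemble a trial dataset
#'
#' Container for pooled multi-trial tabular data: one baseline row per
#' randomized participant plus a long-format visit table of EDSS scores over
#' time. Validates referential integrity (every patient's arm and trial must
#' resolve in the registries, visit rows must reference known patients),
#' uniqueness of patient ids, and that every visit EDSS lies on the valid
#' grid. Visits are sorted by time within patient.
#'
#' @param patients Data frame with columns `patient_id`, `trial_id`, `arm_id`
#'   and the 19 feature columns of [feature_schema()].
#' @param visits Data frame with columns `patient_id`, `time_years`, `edss`.
#' @param arms Data frame registry with columns `arm_id`, `name`, `is_control`.
#' @param trials Optional data frame with column `trial_id`; defaults to the
#'   trials present in `patients`.
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(patients, visits, arms, trials = NULL) {
  schema <- feature_schema()
  need <- c("patient_id", "trial_id", "arm_id", schema$name)
  miss <- setdiff(need, names(patients))
  if (length(miss) > 0L) {
    stop("baseline table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in c("patient_id", "time_years", "edss")) {
    if (!col %in% names(visits)) {
      stop("visit table is missing required column: ", col)
    }
  }
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in baseline table: ",
         paste(unique(patients$patient_id[duplicated(patients$patient_id)]),
               collapse = ", "))
  }
  for (col in c("arm_id", "name", "is_control")) {
    if (!col %in% names(arms)) stop("arm registry is missing column: ", col)
  }
  bad_arm <- setdiff(unique(patients$arm_id), arms$arm_id)
  if (length(bad_arm) > 0L) {
    stop("arm_id not present in arm registry: ", paste(bad_arm, collapse = ", "))
  }
  unknown <- setdiff(unique(visits$patient_id), patients$patient_id)
  if (length(unknown) > 0L) {
    stop("visit rows reference unknown patient_id: ",
         paste(unknown, collapse = ", "))
  }
  if (any(!is.finite(visits$time_years)) || any(visits$time_years < 0)) {
    stop("visit times must be finite and non-negative")
  }
  ok <- is_valid_edss(visits$edss)
  if (!all(ok)) {
    stop("EDSS value off the valid grid (no 0.5 between 0 and 1) at visit row(s): ",
         paste(utils::head(which(!ok), 5L), collapse = ", "))
  }
  visits <- visits[order(match(visits$patient_id, patients$patient_id),
                         visits$time_years), , drop = FALSE]
  rownames(visits) <- NULL
  dup <- stats::ave(visits$time_years, visits$patient_id,
                    FUN = function(t) duplicated(t))
  if (any(dup > 0)) {
    stop("duplicate visit times for patient(s): ",
         paste(unique(visits$patient_id[dup > 0]), collapse = ", "))
  }
  if (is.null(trials)) {
    trials <- data.frame(trial_id = unique(patients$trial_id),
                         stringsAsFactors = FALSE)
  }
  bad_trial <- setdiff(unique(patients$trial_id), trials$trial_id)
  if (length(bad_trial) > 0L) {
    stop("trial_id not present in trial registry: ",
         paste(bad_trial, collapse = ", "))
  }
  structure(list(patients = patients, visits = visits,
                 arms = arms, trials = trials),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> %d patients, %d visits, %d arms, %d trial(s)\n",
              nrow(x$patients), nrow(x$visits), nrow(x$arms), nrow(x$trials)))
  invisible(x)
}

#' Number of patients in a trial dataset
#' @param dataset A `trial_dataset`.
#' @return Integer count.
#' @export
n_patients <- function(dataset) nrow(dataset$patients)

#' Load a trial dataset from CSV files
#'
#' Reads a baseline table (one row per patient, the 19 feature columns plus
#' `patient_id`, `trial_id`, `arm_id`) and a long-format visit table
#' (`patient_id`, `time_years`, `edss`), validates them and attaches sorted
#' visits.
#'
#' @param baseline_path Path to the baseline CSV.
#' @param visits_path Path to the visits CSV.
#' @param arm_registry Data frame registry (`arm_id`, `name`, `is_control`) or
#'   path to a JSON file encoding one.
#' @return A [trial_dataset()].
#' @export
load_trial_table <- function(baseline_path, visits_path, arm_registry) {
  patients <- utils::read.csv(baseline_path, stringsAsFactors = FALSE)
  visits <- utils::read.csv(visits_path, stringsAsFactors = FALSE)
  if (is.character(arm_registry)) {
    arm_registry <- as.data.frame(jsonlite::fromJSON(arm_registry))
  }
  trial_dataset(patients, visits, arm_registry)
}

#' Write a trial dataset to CSV files
#'
#' Inverse of [load_trial_table()]: writes `patients.csv`, `visits.csv` and
#' `arms.json` into a directory.
#'
#' @param dataset A `trial_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_trial_table <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pb <- file.path(dir, "patients.csv")
  pv <- file.path(dir, "visits.csv")
  pa <- file.path(dir, "arms.json")
  utils::write.csv(dataset$patients, pb, row.names = FALSE)
  utils::write.csv(dataset$visits, pv, row.names = FALSE)
  jsonlite::write_json(dataset$arms, pa, dataframe = "columns")
  invisible(c(pb, pv, pa))
}

#' Apply cohort exclusion rules
#'
#' Removes participants who (in this order of reporting) had fewer than two
#' clinical visits, spent less than 24 weeks in the trial (last visit before
#' 24*7/365.25 years), or were missing one or more baseline features.
#'
#' @param dataset A `trial_dataset`.
#' @param min_weeks Minimum required follow-up in weeks (default 24).
#' @return A list with elements `dataset` (the filtered `trial_dataset`) and
#'   `log` (data frame of `patient_id`, `reason` for every exclusion).
#' @export
apply_exclusions <- function(dataset, min_weeks = 24) {
  schema <- feature_schema()
  min_years <- min_weeks * 7 / 365.25
  pid <- dataset$patients$patient_id
  nv <- table(factor(dataset$visits$patient_id, levels = pid))
  last <- tapply(dataset$visits$time_years,
                 factor(dataset$visits$patient_id, levels = pid),
                 function(t) if (length(t)) max(t) else -Inf)
  last[is.na(last)] <- -Inf
  feat <- dataset$patients[, schema$name, drop = FALSE]
  missing_feat <- rowSums(is.na(feat)) > 0
  reason <- rep(NA_character_, length(pid))
  reason[missing_feat] <- "missing baseline feature"
  reason[last < min_years] <- sprintf("spent less than %d weeks in the trial",
                                      min_weeks)
  reason[as.integer(nv) < 2L] <- "fewer than two clinical visits"
  keep <- is.na(reason)
  log <- data.frame(patient_id = pid[!keep], reason = reason[!keep],
                    stringsAsFactors = FALSE)
  patients <- dataset$patients[keep, , drop = FALSE]
  rownames(patients) <- NULL
  visits <- dataset$visits[dataset$visits$patient_id %in% patients$patient_id, ,
                           drop = FALSE]
  rownames(visits) <- NULL
  out <- dataset
  out$patients <- patients
  out$visits <- visits
  list(dataset = out, log = log)
}
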