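#' Scale a value into a reference trial's range
#'
#' Linear map taking the source trial's mean +/- 3 SD interval onto the
#' reference trial's mean +/- 3 SD interval. Values are first clamped to the
#' source +/- 3 SD interval so the map is robust to extreme outliers; the
#' output therefore always lies within the reference interval.
#'
#' @param value Numeric vector to rescale.
#' @param source_mean,source_sd Moments of the feature in the source trial.
#' @param ref_mean,ref_sd Moments in the reference trial.
#' @return Rescaled numeric vector.
#' @export
scale_to_reference <- function(value, source_mean, source_sd, ref_mean, ref_sd) {
  if (!is.finite(source_sd) || source_sd <= 0) {
    stop("source_sd must be positive")
  }
  if (!is.finite(ref_sd) || ref_sd <= 0) {
    stop("ref_sd must be positive")
  }
  clamped <- pmin(pmax(value, source_mean - 3 * source_sd),
                  source_mean + 3 * source_sd)
  ref_mean + (clamped - source_mean) / source_sd * ref_sd
}

#' Ordinal bin code for a Gad lesion count
#'
#' Gadolinium-enhancing lesion counts are binned into 0, 1, 2, 3, 4, 5-6,
#' 7-9, 10-14, 15-19 and 20+ lesions, encoded as consecutive ordinal codes
#' 0..9 (which are then standardized like any other non-binary feature).
#'
#' @param count Numeric vector of lesion counts.
#' @return Integer vector of bin codes in 0..9.
#' @export
gad_bin <- function(count) {
  # lower edges of bins 1..9; anything below 1 (incl. negatives) is bin 0
  edges <- c(1, 2, 3, 4, 5, 7, 10, 15, 20)
  findInterval(count, edges)
}

#' Fit the preprocessing pipeline
#'
#' Fits, from the training split only, all statistics needed to map raw
#' baseline features to model inputs. The pipeline applies, in order:
#' (1) cross-trial scaling of the segmentation-derived MRI metrics toward a
#' reference trial (per-trial anchors, [scale_to_reference()]),
#' (2) natural-log transform of the right-skewed features (with a small
#' positive offset so zeros are representable),
#' (3) binning of the Gad count into ordinal codes ([gad_bin()]), and
#' (4) standardization of all non-binary features to training mean 0 / SD 1.
#' Binary features (sex) are passed through coded 0/1.
#'
#' @param dataset A `trial_dataset`.
#' @param schema Feature schema, defaults to [feature_schema()].
#' @param reference_trial_id Trial whose MRI scale anchors the others.
#' @param training_ids Patient ids of the training split; all fitted
#'   statistics use only these rows.
#' @param inclusion Optional predicate `function(patients) -> logical` that
#'   restricts the rows used to fit the cross-trial scaling anchors (the
#'   subset fulfilling the intersection of all trials' inclusion criteria);
#'   default `NULL` applies no restriction.
#' @param log_offset Offset added before the log transform (default 0.01) so
#'   zero-valued measurements remain finite.
#' @return An object of class `fitted_preprocessor`.
#' @export
fit_preprocessor <- function(dataset, schema = feature_schema(),
                             reference_trial_id, training_ids,
                             inclusion = NULL, log_offset = 0.01) {
  patients <- dataset$patients
  if (!all(training_ids %in% patients$patient_id)) {
    stop("training_ids contains ids not present in the dataset")
  }
  if (!reference_trial_id %in% patients$trial_id) {
    stop("reference trial not present in dataset: ", reference_trial_id)
  }
  train <- patients[patients$patient_id %in% training_ids, , drop = FALSE]

  anchor_rows <- train
  if (!is.null(inclusion)) {
    keep <- inclusion(train)
    if (!is.logical(keep) || length(keep) != nrow(train)) {
      stop("inclusion predicate must return one logical per patient")
    }
    anchor_rows <- train[keep, , drop = FALSE]
  }

  mri_feats <- schema$name[schema$mri_scaled]
  trial_ids <- unique(patients$trial_id)
  anchors <- list()
  for (f in mri_feats) {
    anchors[[f]] <- list()
    for (tr in trial_ids) {
      v <- anchor_rows[[f]][anchor_rows$trial_id == tr]
      m <- mean(v)
      s <- stats::sd(v)
      if (!is.finite(s) || s <= 0) {
        stop(sprintf("cannot fit scaling anchors: feature '%s' constant or empty in trial '%s'",
                     f, tr))
      }
      anchors[[f]][[tr]] <- c(mean = m, sd = s)
    }
  }

  prep <- structure(list(schema = schema,
                         reference_trial_id = reference_trial_id,
                         anchors = anchors,
                         log_offset = log_offset,
                         standardize = NULL),
                    class = "fitted_preprocessor")

  train_mat <- .preprocess_raw(prep, train)
  std <- list()
  for (f in schema$name[schema$kind != "binary"]) {
    m <- mean(train_mat[, f])
    s <- stats::sd(train_mat[, f])
    if (!is.finite(s) || s <= 0) {
      stop("feature constant on the training split, cannot standardize: ", f)
    }
    std[[f]] <- c(mean = m, sd = s)
  }
  prep$standardize <- std
  prep
}

# steps 1-3 of the pipeline (no standardization); returns a numeric matrix
.preprocess_raw <- function(prep, patients) {
  schema <- prep$schema
  out <- matrix(NA_real_, nrow = nrow(patients), ncol = nrow(schema),
                dimnames = list(patients$patient_id, schema$name))
  ref <- prep$reference_trial_id
  for (i in seq_len(nrow(schema))) {
    f <- schema$name[i]
    v <- as.numeric(patients[[f]])
    if (schema$mri_scaled[i]) {
      rf <- prep$anchors[[f]][[ref]]
      for (tr in unique(patients$trial_id)) {
        a <- prep$anchors[[f]][[tr]]
        if (is.null(a)) stop("no scaling anchors fitted for trial: ", tr)
        sel <- patients$trial_id == tr
        v[sel] <- scale_to_reference(v[sel], a["mean"], a["sd"],
                                     rf["mean"], rf["sd"])
      }
    }
    if (schema$log_transform[i]) {
      # cross-trial scaling of a skewed feature can map its lower tail below
      # zero; floor at 0 so the offset-log stays finite
      v <- log(pmax(v, 0) + prep$log_offset)
    }
    if (f == "gad_count") {
      v <- as.numeric(gad_bin(v))
    }
    out[, f] <- v
  }
  out
}

#' Apply a fitted preprocessor to baseline rows
#'
#' Reusable, pure transform: the same `fitted_preprocessor` applied to the
#' same rows always yields an identical matrix.
#'
#' @param prep A `fitted_preprocessor`.
#' @param patients A `trial_dataset` or a baseline data frame.
#' @return Numeric matrix (patients x 19 features), rownames = patient ids.
#' @export
apply_preprocessor <- function(prep, patients) {
  if (inherits(patients, "trial_dataset")) patients <- patients$patients
  mat <- .preprocess_raw(prep, patients)
  for (f in names(prep$standardize)) {
    st <- prep$standardize[[f]]
    mat[, f] <- (mat[, f] - st["mean"]) / st["sd"]
  }
  mat
}

#' Fit the preprocessor and transform the dataset in one call
#'
#' @inheritParams fit_preprocessor
#' @return A list with `preprocessor` (the [fit_preprocessor()] result) and
#'   `matrix` (the transformed feature matrix for the whole dataset).
#' @export
fit_transform <- function(dataset, schema = feature_schema(),
                          reference_trial_id, training_ids,
                          inclusion = NULL, log_offset = 0.01) {
  prep <- fit_preprocessor(dataset, schema, reference_trial_id, training_ids,
                           inclusion, log_offset)
  list(preprocessor = prep, matrix = apply_preprocessor(prep, dataset))
}

#' Serialize a fitted preprocessor to JSON
#'
#' Writes every fitted statistic (scaling anchors, log offset, standardization
#' means/SDs) at full precision so the transform can be reused bit-exactly.
#'
#' @param prep A `fitted_preprocessor`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_preprocessor <- function(prep, path) {
  payload <- list(
    reference_trial_id = prep$reference_trial_id,
    log_offset = prep$log_offset,
    schema = prep$schema,
    anchors = prep$anchors,
    standardize = prep$standardize
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read a serialized preprocessor
#'
#' @param path JSON file written by [write_preprocessor()].
#' @return A `fitted_preprocessor`.
#' @export
read_preprocessor <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  relabel <- function(x) {
    stats::setNames(as.numeric(x), c("mean", "sd"))
  }
  anchors <- lapply(payload$anchors, function(tr) lapply(tr, relabel))
  std <- lapply(payload$standardize, relabel)
  structure(list(schema = as.data.frame(payload$schema),
                 reference_trial_id = payload$reference_trial_id,
                 anchors = anchors,
                 log_offset = payload$log_offset,
                 standardize = std),
            class = "fitted_preprocessor")
}
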