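#' EDSS slope of a single patient's visit series
#'
#' Fits an ordinary-least-squares regression of EDSS on time (years) over all
#' of a participant's visits, baseline included, and returns its slope in
#' EDSS units per year. This per-patient rate of disability worsening is the
#' regression target used for effect modelling.
#'
#' @param time Visit times in years from baseline.
#' @param edss EDSS score at each visit.
#' @return A list with `slope` (EDSS/yr) and `n_visits`.
#' @export
slope_label <- function(time, edss) {
  if (length(time) != length(edss)) stop("time and edss lengths differ")
  if (length(time) < 2L) stop("at least two visits are required")
  tc <- time - mean(time)
  denom <- sum(tc^2)
  if (denom <= 0) stop("degenerate design: all visit times identical")
  slope <- sum(tc * (edss - mean(edss))) / denom
  list(slope = slope, n_visits = length(time))
}

#' Required EDSS increase for confirmed progression
#'
#' The increment that must be reached and sustained for a progression event:
#' 1.5 points from a baseline EDSS of 0, 0.5 points above a baseline of 5.5,
#' and 1.0 point in between. This accounts for patients transitioning through
#' EDSS scores at different rates.
#'
#' @param baseline_edss Baseline EDSS value(s) on the valid grid.
#' @return Numeric vector of required increments.
#' @export
progression_increment <- function(baseline_edss) {
  ok <- is_valid_edss(baseline_edss)
  if (!all(ok)) {
    stop("baseline EDSS off the valid grid: ",
         paste(baseline_edss[!ok], collapse = ", "))
  }
  ifelse(baseline_edss == 0, 1.5, ifelse(baseline_edss > 5.5, 0.5, 1.0))
}

#' Time to 24-week confirmed disability progression (CDP24)
#'
#' A CDP24 event is a 24-week sustained increase in EDSS of at least
#' [progression_increment()] points above the baseline (time-0) score. A
#' candidate onset visit qualifies when a confirming visit at least 24 weeks
#' later exists and the increase is sustained: in `"strict"` mode every visit
#' between onset and the first such confirming visit (inclusive) must remain
#' at or above threshold; in `"confirmation_only"` mode only the confirming
#' visit itself is checked. Event time is the onset visit time; patients
#' without a qualifying onset are censored at their last visit.
#'
#' @param time Visit times in years; the first visit (time 0) is baseline.
#' @param edss EDSS at each visit.
#' @param confirmation_weeks Sustainment window in weeks (default 24).
#' @param mode `"strict"` (default) or `"confirmation_only"`.
#' @return A list with `time` (years) and `event` (logical).
#' @export
cdp24_label <- function(time, edss, confirmation_weeks = 24,
                        mode = c("strict", "confirmation_only")) {
  mode <- match.arg(mode)
  if (length(time) < 2L) stop("at least two visits are required")
  o <- order(time)
  time <- time[o]
  edss <- edss[o]
  window <- confirmation_weeks * 7 / 365.25
  thr <- edss[1L] + progression_increment(edss[1L])
  above <- edss >= thr
  n <- length(time)
  for (i in seq(2L, n)) {
    if (!above[i]) next
    j <- which(time >= time[i] + window)
    j <- if (length(j)) j[1L] else NA_integer_
    if (is.na(j)) next  # no confirming visit in follow-up
    sustained <- if (mode == "strict") all(above[i:j]) else above[j]
    if (sustained) {
      return(list(time = time[i], event = TRUE))
    }
  }
  list(time = time[n], event = FALSE)
}

#' Outcome labels for every patient in a dataset
#'
#' Computes the EDSS slope ([slope_label()]) and the CDP24 survival label
#' ([cdp24_label()]) for each participant.
#'
#' @param dataset A `trial_dataset`.
#' @param confirmation_weeks,mode Passed to [cdp24_label()].
#' @return Data frame with columns `patient_id`, `slope`, `n_visits`,
#'   `ttcdp24_years`, `event`.
#' @export
outcome_labels <- function(dataset, confirmation_weeks = 24, mode = "strict") {
  pid <- dataset$patients$patient_id
  v <- dataset$visits
  idx <- split(seq_len(nrow(v)), factor(v$patient_id, levels = pid))
  res <- lapply(pid, function(p) {
    rows <- idx[[p]]
    tt <- v$time_years[rows]
    ee <- v$edss[rows]
    sl <- slope_label(tt, ee)
    sv <- cdp24_label(tt, ee, confirmation_weeks, mode)
    c(slope = sl$slope, n_visits = sl$n_visits,
      ttcdp24_years = sv$time, event = as.numeric(sv$event))
  })
  res <- do.call(rbind, res)
  data.frame(patient_id = pid,
             slope = res[, "slope"],
             n_visits = as.integer(res[, "n_visits"]),
             ttcdp24_years = res[, "ttcdp24_years"],
             event = res[, "event"] > 0,
             stringsAsFactors = FALSE)
}
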