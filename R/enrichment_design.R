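#' Log-rank sample size for a proportional-hazards trial
#'
#' Two-sided log-rank sample-size calculation (Rosner's formula, as used by
#' the lifelines implementation): with allocation ratio k (treatment :
#' control), postulated hazard ratio HR, and normal quantiles z_a (at
#' 1 - alpha/2) and z_b (at the desired power),
#'
#'   m = (1/k) * ((k*HR + 1) / (HR - 1))^2 * (z_a + z_b)^2
#'
#' is the required number of events; dividing by the expected event fraction
#' d = k * p_treatment + p_control gives the per-arm sample sizes
#' n_treatment = ceil(m * k / d) and n_control = ceil(m / d), each rounded
#' up separately before summing.
#'
#' @param hr Postulated hazard ratio (> 0, not 1).
#' @param p_event_treatment,p_event_control Expected event proportions over
#'   the trial duration in each arm, in (0, 1].
#' @param ratio Treatment-to-control allocation ratio k (default 2).
#' @param power Desired power (default 0.8).
#' @param alpha Two-sided significance level (default 0.05).
#' @return List with integer `n_treatment`, `n_control`, `n_total`.
#' @export
sample_size_cph <- function(hr, p_event_treatment, p_event_control,
                            ratio = 2, power = 0.8, alpha = 0.05) {
  if (!is.finite(hr) || hr <= 0) stop("hr must be positive")
  if (hr == 1) stop("hr = 1 implies an infinite sample size")
  for (p in c(p_event_treatment, p_event_control)) {
    if (!is.finite(p) || p <= 0 || p > 1) {
      stop("event proportions must lie in (0, 1]")
    }
  }
  if (!is.finite(ratio) || ratio <= 0) stop("ratio must be positive")
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  m <- (1 / ratio) * ((ratio * hr + 1) / (hr - 1))^2 * (z_a + z_b)^2
  d <- ratio * p_event_treatment + p_event_control
  n_treatment <- as.integer(ceiling(m * ratio / d))
  n_control <- as.integer(ceiling(m / d))
  list(n_treatment = n_treatment, n_control = n_control,
       n_total = n_treatment + n_control)
}

#' Enriched-trial design table
#'
#' For each enrichment percentile q, restricts the cohort to patients whose
#' CATE estimate is at or above the empirical q-th percentile, then computes
#' the subset's per-arm CDP24 event rates at the horizon (1 - Kaplan-Meier
#' survival, censoring-aware, or the crude event proportion), the treatment
#' hazard ratio ([cox_hr()]), the required sample size at that HR and those
#' rates ([sample_size_cph()]), and the number of participants that must be
#' screened to randomize that many predicted responders,
#' ceil(n_total / (1 - q/100)). A subset where an arm has no events yields a
#' row flagged non-estimable rather than an error.
#'
#' @param scores CATE estimates, one per patient.
#' @param time,event CDP24 survival labels.
#' @param treated Logical or 0/1 treatment indicator.
#' @param percentiles Enrichment thresholds in [0, 100); default 0,10,...,70.
#' @param horizon Event-rate horizon in years (default 2).
#' @param ratio,power,alpha Passed to [sample_size_cph()].
#' @param rate_method `"km"` (default, 1 - KM survival at horizon) or
#'   `"crude"` (raw event proportion).
#' @return Data frame with one row per percentile: `percentile`,
#'   `p_event_control`, `p_event_treatment`, `hr`, `hr_ci_lower`,
#'   `hr_ci_upper`, `p_logrank`, `n_treatment`, `n_control`, `n_total`,
#'   `n_screened`, `n_subset`, `estimable`.
#' @export
enrichment_table <- function(scores, time, event, treated,
                             percentiles = seq(0, 70, by = 10), horizon = 2,
                             ratio = 2, power = 0.8, alpha = 0.05,
                             rate_method = c("km", "crude")) {
  rate_method <- match.arg(rate_method)
  if (any(percentiles < 0 | percentiles >= 100)) {
    stop("percentiles must lie in [0, 100)")
  }
  treated <- as.logical(as.numeric(treated) > 0)
  event <- as.numeric(event)
  event_rate <- function(tt, ee) {
    if (rate_method == "crude") return(mean(ee > 0))
    km <- km_estimate(tt, ee)
    s <- c(1, km$surv)[sum(km$time <= horizon) + 1L]
    1 - s
  }
  rows <- lapply(percentiles, function(q) {
    thr <- stats::quantile(scores, probs = q / 100, type = 1, names = FALSE)
    sel <- scores >= thr
    base <- data.frame(percentile = q, p_event_control = NA_real_,
                       p_event_treatment = NA_real_, hr = NA_real_,
                       hr_ci_lower = NA_real_, hr_ci_upper = NA_real_,
                       p_logrank = NA_real_, n_treatment = NA_integer_,
                       n_control = NA_integer_, n_total = NA_integer_,
                       n_screened = NA_integer_, n_subset = sum(sel),
                       estimable = FALSE)
    res <- tryCatch({
      pt <- event_rate(time[sel & treated], event[sel & treated])
      pc <- event_rate(time[sel & !treated], event[sel & !treated])
      hr <- cox_hr(time[sel], event[sel], treated[sel])
      ss <- sample_size_cph(hr$hr, pt, pc, ratio, power, alpha)
      base$p_event_control <- pc
      base$p_event_treatment <- pt
      base$hr <- hr$hr
      base$hr_ci_lower <- hr$ci_lower
      base$hr_ci_upper <- hr$ci_upper
      base$p_logrank <- hr$p
      base$n_treatment <- ss$n_treatment
      base$n_control <- ss$n_control
      base$n_total <- ss$n_total
      base$n_screened <- as.integer(ceiling(ss$n_total / (1 - q / 100)))
      base$estimable <- TRUE
      base
    }, error = function(e) base)
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
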