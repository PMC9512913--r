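#' Kaplan-Meier estimate with exponential Greenwood confidence bands
#'
#' Product-limit survival estimate; the 95% confidence interval is built on
#' the log(-log S) scale (the exponential Greenwood formula), which keeps the
#' band inside [0, 1].
#'
#' @param time Follow-up times (years).
#' @param event Logical or 0/1 event indicator.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `km_estimate`: a list with `time`, `surv`,
#'   `n_risk`, `n_event`, `lower`, `upper`.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  if (length(time) < 1L) stop("at least one observation is required")
  if (all(time <= 0)) stop("all follow-up times are non-positive")
  fit <- survival::survfit(survival::Surv(time, as.numeric(event)) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  structure(list(time = fit$time, surv = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 lower = fit$lower, upper = fit$upper),
            class = "km_estimate")
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier step function from 0 to `horizon`, with the
#' curve extended flat beyond the last observed time.
#'
#' @param km A `km_estimate` (or `time`/`event` vectors via [rmst_from()]).
#' @param horizon Restriction time in years (default 2).
#' @return RMST in years, in [0, horizon].
#' @export
rmst <- function(km, horizon = 2) {
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be positive")
  knots <- c(0, km$time)
  surv <- c(1, km$surv)
  keep <- knots < horizon
  knots <- c(knots[keep], horizon)
  surv <- surv[keep]
  sum(diff(knots) * surv)
}

#' RMST directly from time/event vectors
#'
#' @param time,event Survival data.
#' @param horizon Restriction time (years).
#' @return RMST in years.
#' @export
rmst_from <- function(time, event, horizon = 2) {
  rmst(km_estimate(time, event), horizon)
}

#' Two-group log-rank test
#'
#' Standard 1-degree-of-freedom log-rank chi-square with a two-sided p-value.
#'
#' @param time,event Survival data for the pooled sample.
#' @param group Two-level grouping vector.
#' @return List with `statistic` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("exactly two non-empty groups required")
  if (sum(as.numeric(event)) == 0) {
    stop("log-rank test undefined: no events in the pooled data")
  }
  sd <- survival::survdiff(survival::Surv(time, as.numeric(event)) ~ group)
  stat <- sd$chisq
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Treatment hazard ratio from a univariate Cox model
#'
#' Proportional-hazards fit on the treatment indicator alone (Breslow ties).
#' Returns the hazard ratio with a Wald 95% CI; the p-value reported alongside
#' is from the two-group log-rank test, matching the usual trial-report
#' pairing.
#'
#' @param time,event Survival data.
#' @param treated Logical or 0/1 treatment indicator.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `hr`, `ci_lower`, `ci_upper`, `p`.
#' @export
cox_hr <- function(time, event, treated, conf_level = 0.95) {
  treated <- as.numeric(treated)
  if (length(unique(treated)) != 2L) stop("both treatment levels must be present")
  ev <- as.numeric(event)
  if (sum(ev[treated == 1]) < 1 || sum(ev[treated == 0]) < 1) {
    stop("each treatment level needs at least one event")
  }
  fit <- survival::coxph(survival::Surv(time, ev) ~ treated, ties = "breslow")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se)) stop("Cox model failed to converge")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lr <- logrank_test(time, ev, treated)
  list(hr = exp(beta),
       ci_lower = exp(beta - z * se),
       ci_upper = exp(beta + z * se),
       p = lr$p)
}

#' Average-difference curve AD(c)
#'
#' Ranking-evaluation curve for a CATE estimator on randomized survival data:
#' for each percentile threshold c, AD(c) is the ground-truth difference in
#' RMST (treated minus control, at `horizon` years) among the patients whose
#' predicted effect is at or above the empirical c-quantile of the scores. A
#' good effect ranking yields an AD(c) curve that increases with c; AD(0) is
#' the whole-group RMST difference.
#'
#' @param scores CATE estimates, one per patient (larger = more responsive).
#' @param time,event CDP24 survival labels.
#' @param treated Logical or 0/1 treatment indicator.
#' @param grid Percentile thresholds in [0, 1); default `seq(0, 0.85, 0.05)`
#'   (higher thresholds leave unstably small arms).
#' @param horizon RMST horizon in years (default 2).
#' @return Object of class `ad_curve`: data frame with columns `c`, `ad`,
#'   `n`, `n_treated`, `n_control`, `defined`; `ad` is `NA` where a subset
#'   leaves an arm empty. The horizon is stored as an attribute.
#' @export
ad_curve <- function(scores, time, event, treated,
                     grid = seq(0, 0.85, by = 0.05), horizon = 2) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n, length(treated) == n)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (any(grid < 0 | grid >= 1)) stop("grid thresholds must lie in [0, 1)")
  treated <- as.logical(as.numeric(treated) > 0)
  rows <- lapply(grid, function(cc) {
    thr <- stats::quantile(scores, probs = cc, type = 1, names = FALSE)
    sel <- scores >= thr
    nt <- sum(sel & treated)
    nc <- sum(sel & !treated)
    if (nt == 0L || nc == 0L) {
      return(data.frame(c = cc, ad = NA_real_, n = sum(sel),
                        n_treated = nt, n_control = nc, defined = FALSE))
    }
    ad <- rmst_from(time[sel & treated], event[sel & treated], horizon) -
      rmst_from(time[sel & !treated], event[sel & !treated], horizon)
    data.frame(c = cc, ad = ad, n = sum(sel),
               n_treated = nt, n_control = nc, defined = TRUE)
  })
  out <- do.call(rbind, rows)
  attr(out, "horizon") <- horizon
  class(out) <- c("ad_curve", class(out))
  out
}

#' Weighted area between an AD(c) curve and its unenriched level
#'
#' Scalar summary of effect-ranking quality: the area between AD(c) and the
#' horizontal line AD(0), integrated over the threshold grid by the
#' trapezoidal rule with weights w(c) and normalized by the integrated
#' weight. The default weight w(c) = 1 - c is the fraction of the cohort
#' retained at threshold c, so thresholds that keep more patients count
#' more. Larger positive values indicate a better ranking; any flat curve
#' scores exactly 0.
#'
#' @param curve An `ad_curve`.
#' @param weight `"retained"` (w(c) = 1 - c, default) or `"uniform"`.
#' @return Scalar AD_wabc value.
#' @export
ad_wabc <- function(curve, weight = c("retained", "uniform")) {
  weight <- match.arg(weight)
  cc <- curve$c[curve$defined]
  ad <- curve$ad[curve$defined]
  if (length(cc) < 2L) stop("need at least two defined thresholds")
  if (abs(cc[1L]) > 1e-12) stop("AD undefined at c = 0")
  w <- if (weight == "retained") 1 - cc else rep(1, length(cc))
  f <- w * (ad - ad[1L])
  trap <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  trap(cc, f) / trap(cc, w)
}

#' Responder vs non-responder baseline comparison table
#'
#' For each continuous/ordinal/discrete feature: group means and SDs, the
#' mean difference with its 95% CI, and a two-sided Welch t-test p-value
#' (unequal variances). For the binary feature (sex): the sample
#' (cross-product) odds ratio with a Woolf log-scale 95% CI and a two-sided
#' Fisher exact p-value. Features with zero variance in both groups get
#' p = 1 and a `degenerate` flag.
#'
#' @param patients Baseline data frame or `trial_dataset`.
#' @param responder_mask Logical vector: `TRUE` for the responder group.
#' @param schema Feature schema, defaults to [feature_schema()].
#' @return Data frame, one row per feature, with columns `feature`, `test`,
#'   `mean_responder`, `sd_responder`, `mean_nonresponder`,
#'   `sd_nonresponder`, `effect`, `ci_lower`, `ci_upper`, `p`, `degenerate`.
#' @export
subgroup_stats <- function(patients, responder_mask, schema = feature_schema()) {
  if (inherits(patients, "trial_dataset")) patients <- patients$patients
  responder_mask <- as.logical(responder_mask)
  if (!any(responder_mask) || !any(!responder_mask)) {
    stop("both responder and non-responder groups must be non-empty")
  }
  rows <- lapply(seq_len(nrow(schema)), function(i) {
    f <- schema$name[i]
    x <- as.numeric(patients[[f]][responder_mask])
    y <- as.numeric(patients[[f]][!responder_mask])
    if (schema$kind[i] == "binary") {
      tab <- rbind(c(sum(x == 1), sum(x == 0)),
                   c(sum(y == 1), sum(y == 0)))
      or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
      se <- sqrt(sum(1 / tab))
      p <- stats::fisher.test(tab)$p.value
      data.frame(feature = f, test = "fisher",
                 mean_responder = mean(x), sd_responder = stats::sd(x),
                 mean_nonresponder = mean(y), sd_nonresponder = stats::sd(y),
                 effect = or,
                 ci_lower = exp(log(or) - 1.96 * se),
                 ci_upper = exp(log(or) + 1.96 * se),
                 p = p, degenerate = FALSE)
    } else {
      degen <- stats::sd(x) == 0 && stats::sd(y) == 0
      if (degen) {
        data.frame(feature = f, test = "welch",
                   mean_responder = mean(x), sd_responder = 0,
                   mean_nonresponder = mean(y), sd_nonresponder = 0,
                   effect = mean(x) - mean(y),
                   ci_lower = NA_real_, ci_upper = NA_real_,
                   p = 1, degenerate = TRUE)
      } else {
        tt <- stats::t.test(x, y, var.equal = FALSE)
        data.frame(feature = f, test = "welch",
                   mean_responder = mean(x), sd_responder = stats::sd(x),
                   mean_nonresponder = mean(y), sd_nonresponder = stats::sd(y),
                   effect = mean(x) - mean(y),
                   ci_lower = tt$conf.int[1], ci_upper = tt$conf.int[2],
                   p = tt$p.value, degenerate = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
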