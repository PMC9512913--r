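test_that("Kaplan-Meier point estimates match the hand product-limit", {
  # no events: survival stays at 1
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # three events at 1, 2, 3 with n = 3
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_error(km_estimate(numeric(0), numeric(0)), "at least one")
})

test_that("confidence bands equal the exponential Greenwood formula", {
  set.seed(12)
  time <- rexp(40)
  event <- rbinom(40, 1, 0.7)
  km <- km_estimate(time, event)
  # independent evaluation of the log(-log S) interval: S^exp(+/- z*sqrt(v))
  # with v = sum(d/(n(n-d))) / log(S)^2 accumulated over event times
  ord <- order(km$time)
  gw <- cumsum(ifelse(km$n_risk > km$n_event,
                      km$n_event / (km$n_risk * (km$n_risk - km$n_event)), 0))
  z <- qnorm(0.975)
  inner <- km$surv > 0 & km$surv < 1
  v <- gw[inner] / log(km$surv[inner])^2
  lo <- km$surv[inner]^exp(z * sqrt(v))
  hi <- km$surv[inner]^exp(-z * sqrt(v))
  expect_equal(km$lower[inner], lo, tolerance = 1e-8)
  expect_equal(km$upper[inner], hi, tolerance = 1e-8)
  # the band contains the point estimate
  expect_true(all(km$lower[inner] <= km$surv[inner] + 1e-12))
  expect_true(all(km$upper[inner] >= km$surv[inner] - 1e-12))
})

test_that("RMST is the area under the survival step function", {
  # unit survival over the horizon
  expect_equal(rmst_from(c(2.5, 3), c(0, 0), horizon = 2), 2)
  # one event at 1 year, one censored after 2: area = 1*1 + 0.5*1
  expect_equal(rmst_from(c(1, 2.5), c(1, 0), horizon = 2), 1.5)
  # quadrature oracle on a random sample
  set.seed(4)
  time <- rexp(30, 0.5)
  event <- rbinom(30, 1, 0.8)
  km <- km_estimate(time, event)
  stepfun_s <- stats::stepfun(km$time, c(1, km$surv), right = FALSE)
  fine <- seq(0, 2, length.out = 2e5 + 1)
  mid <- (fine[-1] + fine[-length(fine)]) / 2
  quad <- sum(stepfun_s(mid)) * diff(fine)[1]
  expect_equal(rmst(km, 2), quad, tolerance = 1e-4)
  expect_true(rmst(km, 2) >= 0 && rmst(km, 2) <= 2)
})

test_that("log-rank statistic matches the hand O-E/V computation", {
  # identical groups: statistic 0, p = 1
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p, 1)
  # tiny worked example: group A events at 1, 2; group B event at 3, censor 4
  time <- c(1, 2, 3, 4)
  event <- c(1, 1, 1, 0)
  grp <- c("A", "A", "B", "B")
  # hand computation (group A as the observed series):
  # t=1: nA=2, n=4, d=1 -> E=0.5, V=(1*2*2*3)/(16*3)=0.25
  # t=2: nA=1, n=3, d=1 -> E=1/3, V=(1*1*2*2)/(9*2)=2/9
  # t=3: nA=0, n=2, d=1 -> E=0,   V=0
  O <- 2; E <- 0.5 + 1 / 3; V <- 0.25 + 2 / 9
  stat_hand <- (O - E)^2 / V
  lr <- logrank_test(time, event, grp)
  expect_equal(lr$statistic, stat_hand, tolerance = 1e-10)
  # p equals the chi-square(1) upper tail of the statistic
  expect_equal(lr$p, pchisq(lr$statistic, 1, lower.tail = FALSE))
  # symmetric in group order
  lr_swap <- logrank_test(time, event, rev(grp)[c(3, 4, 1, 2)])
  expect_equal(lr_swap$statistic, lr$statistic)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "no events")
})

test_that("Cox hazard ratio recovers known generative ratios", {
  set.seed(21)
  # null: identical exponential groups
  n <- 500
  tr <- rep(0:1, each = n / 2)
  time <- rexp(n, 0.5)
  cens <- runif(n, 0.5, 3)
  hr0 <- cox_hr(pmin(time, cens), time <= cens, tr)
  expect_true(hr0$hr > 0.8 && hr0$hr < 1.25)
  # true hazard ratio 0.5
  n <- 2000
  tr <- rep(0:1, each = n / 2)
  time <- rexp(n, ifelse(tr == 1, 0.25, 0.5))
  cens <- runif(n, 1, 4)
  hr <- cox_hr(pmin(time, cens), time <= cens, tr)
  expect_true(hr$hr > 0.42 && hr$hr < 0.59)
  expect_true(hr$ci_lower < hr$hr && hr$ci_upper > hr$hr)
  # relabeling arms inverts the ratio
  hr_swap <- cox_hr(pmin(time, cens), time <= cens, 1 - tr)
  expect_equal(hr_swap$hr, 1 / hr$hr, tolerance = 1e-6)
})

test_that("AD(0) equals the whole-group RMST difference", {
  g <- generate_dataset(ppms_synthetic_config(400), seed = 6)
  ex <- apply_exclusions(g$dataset)
  lab <- outcome_labels(ex$dataset)
  trt <- ex$dataset$patients$arm_id == "anti_cd20"
  scores <- rnorm(nrow(ex$dataset$patients))
  cur <- ad_curve(scores, lab$ttcdp24_years, lab$event, trt)
  direct <- rmst_from(lab$ttcdp24_years[trt], lab$event[trt], 2) -
    rmst_from(lab$ttcdp24_years[!trt], lab$event[!trt], 2)
  expect_equal(cur$ad[1], direct, tolerance = 1e-12)
})

test_that("constant scores keep the whole cohort at every threshold", {
  g <- generate_dataset(ppms_synthetic_config(200), seed = 8)
  ex <- apply_exclusions(g$dataset)
  lab <- outcome_labels(ex$dataset)
  trt <- ex$dataset$patients$arm_id == "anti_cd20"
  cur <- ad_curve(rep(1, nrow(ex$dataset$patients)), lab$ttcdp24_years,
                  lab$event, trt)
  expect_true(all(cur$defined))
  expect_true(all(abs(cur$ad - cur$ad[1]) < 1e-12))
  expect_equal(ad_wabc(cur), 0)
})

test_that("ad_wabc matches an independent weighted trapezoid evaluation", {
  toy <- structure(
    data.frame(c = c(0, 0.4, 0.8), ad = c(0.1, 0.1, 0.3),
               defined = TRUE),
    class = c("ad_curve", "data.frame"))
  # by hand: f = (1-c)*(AD-0.1) = (0, 0, 0.04); trapezoid integral 0.008;
  # weight integral (1+0.6)/2*0.4 + (0.6+0.2)/2*0.4 = 0.48
  expect_equal(ad_wabc(toy), 0.008 / 0.48, tolerance = 1e-12)
  # uniform weights: trapezoid of (0, 0, 0.2) is 0.04, weight integral 0.8
  expect_equal(ad_wabc(toy, weight = "uniform"), 0.04 / 0.8,
               tolerance = 1e-12)
})

test_that("ad_wabc has mean zero under random rankings of a homogeneous cohort", {
  cfg <- ppms_synthetic_config(800, tau = function(p) rep(0.15, nrow(p)))
  g <- generate_dataset(cfg, seed = 14)
  ex <- apply_exclusions(g$dataset)
  lab <- outcome_labels(ex$dataset)
  trt <- ex$dataset$patients$arm_id == "anti_cd20"
  set.seed(15)
  vals <- replicate(200, {
    ad_wabc(ad_curve(sample(seq_len(nrow(ex$dataset$patients))),
                     lab$ttcdp24_years, lab$event, trt))
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_true(abs(mean(vals)) < 2 * se + 1e-12)
})

test_that("subgroup statistics match Welch and Fisher oracles", {
  # identical groups: zero mean differences, Fisher p = 1
  p <- rbind(baseline_row("A1"), baseline_row("A2"),
             baseline_row("B1"), baseline_row("B2"))
  st <- subgroup_stats(p, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(st$effect[st$test == "welch"] == 0))
  expect_equal(st$p[st$feature == "sex"], 1)
  expect_true(all(st$degenerate[st$test == "welch"]))

  # Welch p on (1,2,3) vs (2,3,4,5): hand Welch statistic, Satterthwaite df
  x <- c(1, 2, 3); y <- c(2, 3, 4, 5)
  sx <- var(x) / 3; sy <- var(y) / 4
  tstat <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / 2 + sy^2 / 3)
  p_hand <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  pats <- do.call(rbind, lapply(seq_along(c(x, y)), function(i) {
    baseline_row(paste0("P", i), age = c(x, y)[i])
  }))
  st2 <- subgroup_stats(pats, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(st2$p[st2$feature == "age"], p_hand, tolerance = 1e-12)

  # Fisher on ((3,1),(1,3)): cross-product OR 9, p by hypergeometric
  # enumeration over all tables with the same margins
  pats2 <- do.call(rbind, lapply(1:8, function(i) {
    baseline_row(paste0("Q", i), sex = c(1, 1, 1, 0, 1, 0, 0, 0)[i])
  }))
  st3 <- subgroup_stats(pats2, rep(c(TRUE, FALSE), each = 4))
  expect_equal(st3$effect[st3$feature == "sex"], 9)
  probs <- dhyper(0:4, 4, 4, 4)
  p_enum <- sum(probs[probs <= dhyper(3, 4, 4, 4) + 1e-12])
  expect_equal(st3$p[st3$feature == "sex"], p_enum, tolerance = 1e-12)
})
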