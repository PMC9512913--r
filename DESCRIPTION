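Package: catenrich
Title: Conditional Average Treatment Effect Estimation and Predictive
    Enrichment for Disability-Progression Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing predictively enriched randomized trials of
    disability progression in multiple sclerosis. Estimates conditional
    average treatment effects (CATE) from baseline clinical and MRI features
    with an ensemble of multi-headed multilayer perceptrons (a T-learner with
    a shared trunk), labels outcomes as per-patient EDSS slopes and
    24-week confirmed disability progression (CDP24) survival times,
    evaluates effect rankings with average-difference AD(c) curves and their
    weighted-area summary, and computes log-rank sample sizes for enriched
    trial designs. Includes comparator rankers (single-feature rules, ridge
    and Cox proportional-hazards T-learners, a prognostic model) and a
    synthetic multi-trial generator with known ground-truth effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
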