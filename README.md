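# catenrich

Conditional average treatment effect (CATE) estimation and predictive
enrichment for disability-progression trials in multiple sclerosis.

Disability progression in progressive MS lacks a responsive phase-2
biomarker, so proof-of-concept trials need prohibitively many patients.
`catenrich` implements a predictive-enrichment workflow: estimate each
patient's treatment effect from 19 baseline clinical and MRI features,
rank patients by predicted responsiveness, and preferentially randomize
predicted responders — shrinking the required sample size several-fold.

The core estimator is a T-learner with a shared trunk: a multi-headed
multilayer perceptron with one common ReLU hidden layer and one
treatment-specific hidden layer plus scalar output per arm. Head *t*
predicts the potential outcome μ̂ₜ(x) — the patient's EDSS worsening rate
(slope, EDSS/yr) under arm *t* — and the CATE estimate is

    τ̂(x) = −( μ̂₁(x) − μ̂₀(x) )

sign-flipped so positive values mean predicted benefit. Training uses an
allocation-weighted factual loss (weights n_s/(m·n_t)), arm-stratified
mini-batches, dropout + L2 + max-norm regularization, 4-fold
cross-validated early stopping with ensembling, crogged (pooled
out-of-fold) validation metrics, random hyperparameter search with a
one-SD selection rule, and a pretrain → freeze-trunk → fine-tune transfer
scheme (5-headed RRMS pretraining, 2-headed PPMS fine-tuning).

Rankings are evaluated against time to 24-week confirmed disability
progression (CDP24) with the average-difference curve AD(c) — the RMST
difference between arms among patients above the c-th CATE percentile —
and its weighted-area summary AD_wabc. Enriched designs are sized with
the two-sided log-rank (Rosner) formula at a 2:1 allocation. A synthetic
multi-trial generator with known ground-truth effects makes the whole
pipeline testable end to end.

## Worked example

```r
library(catenrich)

# synthetic two-arm PPMS-like cohort (2:1), known linear effect
g  <- generate_dataset(ppms_synthetic_config(2000, tau = linear_tau()), seed = 9)
ds <- apply_exclusions(g$dataset)$dataset
ft <- fit_transform(ds, reference_trial_id = "PPMS_A",
                    training_ids = ds$patients$patient_id)
lab <- outcome_labels(ds)

# pretrain on a 5-arm RRMS-like cohort, freeze the trunk, fine-tune
rr  <- generate_dataset(rrms_synthetic_config(2500, tau = linear_tau()), seed = 8)
dr  <- apply_exclusions(rr$dataset)$dataset
fr  <- fit_transform(dr, reference_trial_id = "RRMS_A",
                     training_ids = dr$patients$patient_id)
lr  <- outcome_labels(dr)
hp  <- mlp_hyperparams()   # width 32, lr 0.02, momentum 0.9, <=100 epochs
tm  <- pretrain_and_finetune(fr$matrix, lr$slope, dr$patients$arm_id,
                             ft$matrix, lab$slope, ds$patients$arm_id,
                             hp, hp, k = 4, seed = 1)

cate <- predict_cate(tm$finetuned, ft$matrix, "anti_cd20", "placebo")
tau  <- g$truth$tau[match(ds$patients$patient_id, g$truth$patient_id)]
cor(cate, tau, method = "spearman")
#> [1] 0.6246896

trt   <- ds$patients$arm_id == "anti_cd20"
curve <- ad_curve(cate, lab$ttcdp24_years, lab$event, trt)
ad_wabc(curve)
#> [1] 0.06001018
```

The Spearman correlation says the fitted model recovers the planted
effect ranking well above chance (a ridge model given the true linear
form reaches ≈ 0.8 on the same data); the positive AD_wabc says patients
the model ranks as responsive really do show a larger RMST advantage on
treatment. Sizing an enriched two-year trial from published design
inputs:

```r
sample_size_cph(hr = 0.49, p_event_treatment = 0.20, p_event_control = 0.33,
                ratio = 2, power = 0.8, alpha = 0.05)
#> $n_treatment 163   $n_control 82   $n_total 245
```

Enriching at the 50th percentile randomizes 245 patients (screening
2 × 245 = 490) instead of the 1374 an unenriched trial would need.

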