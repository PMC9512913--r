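# shared fixture builders; everything is generated in code at test time

two_arm_registry <- function() {
  data.frame(arm_id = c("anti_cd20", "placebo"),
             name = c("anti-CD20 antibody", "placebo"),
             is_control = c(FALSE, TRUE))
}

# a complete baseline row with overridable fields
baseline_row <- function(patient_id, trial_id = "TRIAL_A",
                         arm_id = "placebo", ...) {
  row <- list(patient_id = patient_id, trial_id = trial_id, arm_id = arm_id,
              age = 45, sex = 1, height = 170, weight = 75,
              disease_duration = 6, edss = 4.0,
              fss_bowel_bladder = 1, fss_brainstem = 1, fss_cerebellar = 2,
              fss_cerebral = 1, fss_pyramidal = 3, fss_sensory = 2,
              fss_visual = 1, t25fw = 10, nhpt_dominant = 30,
              nhpt_nondominant = 32, gad_count = 1, t2_volume = 8,
              nbv = 1.45)
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row)
}

tiny_dataset <- function() {
  patients <- rbind(
    baseline_row("P1", arm_id = "anti_cd20", age = 40, gad_count = 2),
    baseline_row("P2", arm_id = "placebo", age = 50, gad_count = 0,
                 t2_volume = 12, nbv = 1.40))
  visits <- data.frame(
    patient_id = c("P1", "P1", "P1", "P2", "P2"),
    time_years = c(0, 1, 0.5, 0, 1),
    edss = c(4.0, 5.0, 4.5, 4.0, 4.0))
  trial_dataset(patients, visits, two_arm_registry())
}

# the strong linearly heterogeneous effect used for recovery studies
strong_linear_tau <- function() linear_tau()

weeks <- function(w) w * 7 / 365.25
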