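# Example synthetic-trial configuration for `dmcreport synth`.
arms:
  - label: High Dose
    n_subjects: 40
  - label: Placebo
    n_subjects: 40
reference_arm: Placebo
age_mean: 72
age_sd: 8
exposure_mean_days: 140
study_length_days: 182
dropout_prob: 0.3
seed: 2024
ae_models:
  - preferred_term: Pruritus
    system_organ_class: Skin and subcutaneous tissue disorders
    hazard_per_year:
      High Dose: 0.8
      Placebo: 0.15
    serious_prob: 0.01
    grade_probs: [0.55, 0.3, 0.1, 0.04, 0.01]
    related_prob: 0.8
  - preferred_term: Headache
    system_organ_class: Nervous system disorders
    hazard_per_year:
      High Dose: 0.2
      Placebo: 0.2
    serious_prob: 0.0
    grade_probs: [0.55, 0.3, 0.1, 0.04, 0.01]
    related_prob: 0.3
lab_models:
  - param_code: CK
    param_name: Creatine Kinase
    unit: U/L
    baseline_meanlog: 4.55
    baseline_sdlog: 0.35
    arm_drift:
      High Dose: 0.02
      Placebo: 0.0
    visit_schedule: [1, 14, 28, 56, 84]
    sd_within: 0.2
    outlier_prob: 0.01
    outlier_multiplier: 3
    lln: 30
    uln: 170
    limit_jitter_sd: 0.08
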