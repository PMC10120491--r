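# Example report configuration for `dmcreport build`.
comparisons:
  - [High Dose, Placebo]
front_matter:
  protocol_synopsis: >
    Randomized, double-blind, placebo-controlled study of a transdermal
    treatment in an elderly population; 26 weeks of treatment.
  previous_recommendations:
    - Continue the study without modification.
lab_params:
  - param_code: CK
    log_scale: true
    side: high
    spaghetti_multiplier: 3
include_vitals: false
include_shift_scatter: true
include_appendix: true
label_rule:
  p_cutoff: 0.05
exposure_adjusted: false
grading_rules:
  - param_code: CK
    direction: high
    thresholds: [1.0, 2.5, 5.0, 10.0]
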