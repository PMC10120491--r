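# dmcreport

Structured safety reports for Data Monitoring Committees (DMCs).

Independent DMCs must judge, in a few hours, whether accumulating safety
data from an ongoing randomized trial show a concerning imbalance — and
typical review packages are hundreds of pages of unfocused listings.
`dmcreport` is for the statisticians and programmers who prepare those
packages. It reads CDISC ADaM-like subject-level tables (ADSL/ADAE/ADLB/
ADEX-shaped CSV, or SAS transport v5) and produces a single, continuously
page-numbered report (PDF + hyperlinked HTML) built around the displays a
reviewer needs, with the statistics behind them implemented from first
principles and a seeded synthetic-trial generator so everything is
testable offline.

## What it computes

For preferred term $t$ with $a_t$ of $n_A$ subjects affected on active
and $b_t$ of $n_B$ on control:

- **Subject-level incidence** per term and arm, crude
  ($100\,a_t/n_A$) and exposure-adjusted (subjects with an event per 100
  patient-years, person-time from first to last dose inclusive /
  365.25), with a treatment-emergent window of last dose + 30 days
  (configurable).
- **Volcano statistics**: a two-sided Fisher exact p-value by direct
  hypergeometric enumeration (minimum-likelihood rule,
  $p = \sum_{P(T) \le P(t_{obs})} P(T)$ conditioned on the margins),
  Benjamini–Hochberg adjusted values
  $\tilde p_{(i)} = \min(1, \min_{j \ge i} m\,p_{(j)}/j)$,
  and a risk difference $100(a_t/n_A - b_t/n_B)$ or an
  exposure-adjusted rate ratio
  $\frac{(a_t + c)/PY_A}{(b_t + c)/PY_B}$ (continuity $c = 0.5$ only at
  zero cells). P-values are descriptive screening measures.
- **Laboratory derivations**: strict normal-range flagging against each
  measurement's own limits, CTC-style grading from configurable strictly
  monotone thresholds, per-visit box statistics (type-7 quantiles,
  1.5 IQR whiskers, per-visit n including zero), abnormal prevalence over
  visits, >k x ULN outlier-trajectory selection, and baseline vs
  post-baseline shift pairs whose 3x3 cross-tab provably conserves the
  eligible subjects.
- **Patient profiles**: one page per subject with a serious AE, a grade
  >= 3 AE, or a grade >= 3 laboratory value — demographics, history,
  medication, exposure, events, flagged labs, key-event timeline.
- **The report**: front matter (synopsis, amendments, previous
  recommendations, automatic "what has changed since the previous DMC"
  from manifest diffs), graphical demographics (no baseline p-values),
  AE dot plot and volcano per comparison, per-parameter lab displays,
  vitals by the same operators, profiles, appendix — with a
  page-numbered TOC and a JSON manifest of every artifact.

## Worked example

```r
library(dmcreport)

# a synthetic two-arm study shaped like an elderly dermatology-heavy
# population: 100 subjects/arm, 26-week treatment
trial <- generateTrial(xanomelineLikeFixture(n_per_arm = 100))
trial
#> <trial_data> 200 subjects, arms: High Dose / Placebo (reference: Placebo), cutoff day 182
#>   adverse events: 175 | lab records: 2768 | exposure intervals: 200

vs <- volcanoStats(trial, "High Dose", "Placebo")
head(vs[c("preferred_term", "estimate", "p_value", "fdr_p",
          "n_event_a", "n_event_b", "labeled")], 5)
#>              preferred_term estimate  p_value    fdr_p n_event_a n_event_b labeled
#> 1                  Pruritus       27 8.41e-07 8.41e-06        32         5    TRUE
#> 2                 Dizziness       14 2.57e-03 1.28e-02        18         4    TRUE
#> 3 Application site pruritus       13 1.19e-02 3.97e-02        20         7    TRUE
#> 4                  Erythema        7 5.82e-02 1.46e-01         9         2   FALSE
#> 5                  Headache       -4 4.80e-01 9.47e-01         8        12   FALSE
```

Reading row 1: 32/100 High Dose subjects vs 5/100 Placebo subjects
reported pruritus — a risk difference of 27 percentage points, Fisher
p = 8.4e-07, still 8.4e-06 after FDR adjustment across the 10 observed
terms, so the dot is labeled in the volcano plot. Erythema (row 4) sits
just above the default p < 0.05 labeling cutoff and stays unlabeled.

```r
# flagged trajectories and profile subjects
length(unique(selectOutlierSubjects(trial, "CK", multiplier = 3)$subject_id))
#> [1] 12
nrow(selectProfileSubjects(trial))
#> [1] 31

# the full report
cfg <- reportConfig(comparisons = list(c("High Dose", "Placebo")),
                    lab_params = c("CHOL", "CK"))
res <- buildReport(trial, cfg, "dmc_report")
res$manifest$sections
#> [1] "front_matter" "baseline" "adverse_events" "laboratory"
#> [5] "vitals" "profiles" "appendix"
```

`dmc_report/` then holds `report.pdf` (page-numbered, TOC with true page
numbers), `report.html` (anchor-linked), `figures/` (SVG + PNG + backing
CSV per figure) and `manifest.json`. Passing `previous_manifest =` a
prior manifest adds the change summary to the front matter.

A thin command-line front end is installed at `inst/cli/dmcreport`
(subcommands `validate`, `synth`, `ae-stats`, `build`).

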