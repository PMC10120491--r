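---
title: "Methods behind dmcreport: statistics, displays and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind dmcreport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Purpose

Data Monitoring Committees (DMCs) review accumulating safety data from
ongoing randomized trials under severe time pressure. `dmcreport` turns
CDISC ADaM-like subject-level tables (demographics, adverse events,
laboratory values, exposure, concomitant medication, medical history)
into a single, continuously page-numbered report organised around the
questions a DMC actually asks: is there an imbalance; can it be explained
at baseline; does it relate across domains; and which individual patients
deserve a closer look. This vignette documents the statistical methods,
the tunable parameters, and the design decisions where the choice was
genuinely open.

# Data model and input handling

All inputs are subject-level tables keyed by an opaque `subject_id`.
Readers accept CSV (the canonical round-trip dialect) and SAS transport
v5 (read-only), with case-insensitive header matching against documented
ADaM-style aliases (`USUBJID`, `AEDECOD`, `AEBODSYS`, `PARAMCD`,
`ANRLO`/`ANRHI`, ...). Dates may arrive as ISO-8601 `*_date` columns and
are converted with the conventional no-day-zero rule (the first dose day
is day 1; days before first dose are negative); precomputed `*_day`
columns win when both are present.

`assembleTrial()` enforces referential integrity, drops records beyond
the data-cut day (logging per-table counts), and truncates ongoing
intervals at the cut. `validateTrial()` re-audits every invariant and
never raises — it returns a findings table, so a pipeline can choose its
own failure policy. Limits of normal are carried per measurement, not
globally: real laboratories assign subject-specific reference ranges, and
several displays change behaviour when limits are not common to all
subjects.

# Adverse-event statistics

**Incidence.** A subject contributes at most once per preferred term to
subject-level incidence, however many episodes they report. The
denominator is the safety population (all dosed subjects in the arm).
Person-time runs from first to last dose day inclusive, divided by
365.25; the exposure-adjusted view reports subjects with an event per 100
patient-years. Treatment-emergent means onset on/after first dose and no
later than last dose plus a 30-day lag (configurable, `te_window`).

**The volcano display.** For each arm pair, every preferred term with at
least one affected subject enters a 2x2 table of affected vs unaffected
subjects. The p-value is a two-sided Fisher exact test computed by direct
hypergeometric enumeration under the minimum-likelihood rule: conditioning
on the margins, sum the point probabilities of all tables no more likely
than the observed one (a relative tolerance of 1e-7 absorbs floating-point
ties). Fisher was chosen over asymptotic tests because safety terms are
often rare and the display must behave sensibly at counts of 0–5; the
p-values are explicitly descriptive screening quantities, not confirmatory
tests, and the figure captions say so.

The effect axis is either a risk difference in percentage points or an
exposure-adjusted incidence rate ratio `((a+c)/PY_a)/((b+c)/PY_b)` with a
continuity constant `c = 0.5` applied only when a zero cell occurs. A
proportional-hazards fit would be disproportionate machinery for a
descriptive screen; the rate ratio is labelled as what it is. The ratio
is exactly symmetric under arm swap, and the whole record set is
antisymmetric: swapping arms negates risk differences, inverts rate
ratios and leaves p-values untouched (property-tested).

**Multiplicity.** Benjamini–Hochberg adjustment is available as the
alternative y-axis; the family is all preferred terms within one arm-pair
comparison, and separate comparisons are separate families. The step-up
definition is implemented directly: with order statistics
$p_{(1)} \le \dots \le p_{(m)}$, the adjusted value at rank $i$ is
$\min(1, \min_{j \ge i} m\,p_{(j)}/j)$. One mathematical point worth
recording: the adjusted values are *not* a fixed point of the adjustment
— re-adjusting $(0.08, 0.5)$ (the image of $(0.04, 0.5)$) yields
$(0.16, 0.5)$ — so the adjustment must be applied once to raw p-values,
never iterated. Labeling uses a raw-p cutoff (default 0.05) or a top-k
rule with ties broken by effect magnitude and then alphabetically.

# Laboratory derivations

**Flagging** is strict: a value is low/high only strictly beyond its own
limit; a value exactly at the limit is normal. The convention is
documented because the boundary case occurs in practice; it is applied
uniformly across flags, grades and outlier selection. When a limit is
missing, the value is excluded from the affected abnormality logic but
retained in distribution plots.

**CTC-style grading** uses four strictly monotone thresholds per
parameter, expressed as multiples of the subject's own ULN (high
direction) or LLN (low), or absolute values. The grade is the highest
threshold strictly exceeded; grading is monotone in the value. The rules
ship as editable configuration; the bundled defaults are illustrative
shapes only — a real review must load the protocol's CTCAE thresholds.

**Box-whisker summaries** use linear-interpolation quantiles (the common
type-7 default; the rule is stated in every caption because box plots
differ visibly across quantile rules) and whiskers at the last data point
within 1.5 IQR beyond the quartiles. Visits with no data are kept with
n = 0 so the per-visit n annotation row is always complete — shrinking n
over visits is itself safety information (drop-out). On a logarithmic
display the statistics are still computed on raw values: quartiles are
order statistics and commute with any monotone transform exactly at
order-statistic indices, and to plotting accuracy between them.

**Outlier trajectories** select subjects with any post-baseline value
strictly above `multiplier` (default 3) times their own ULN, or
attaining a configurable minimum grade. The spaghetti display colours
and annotates exactly the selected subjects over a grey context of all
others, and draws limit reference lines only when the limits are common
to every subject — otherwise it suppresses them and says so in the
caption, because a single line would misrepresent subject-specific
ranges.

**Shift pairs.** Eligible subjects have a baseline value (the
baseline-flagged record, else the last value on or before first dose) and
at least one post-baseline value; each contributes exactly one pair. The
post-baseline value is the worst case by default (maximum for
high-direction parameters) because a safety audience wants the
signal-maximizing view; the latest value is available as an alternative
(`post_rule = "last_value"`) since the field has no settled convention.
The classic 3x3 shift table is reconstructed from the same pairs, so the
scatter display and the table are provably consistent — the cross-tab
always sums to the number of eligible subjects.

# Figures and the report

All seven display builders return a `figure_spec` carrying the backing
data, the ggplot object, and a self-describing caption that states the
statistical conventions actually used (whisker rule, test, adjustment).
Figures are rendered as SVG + PNG with the backing data as CSV alongside,
for traceability. Arms keep fixed colours (an Okabe–Ito palette) across
every figure of a report, and the reference arm is listed last in
displays. The demographics panel deliberately contains no p-values:
significance testing of baseline differences in a randomized trial is
not performed. Volcano labels are placed by a deterministic greedy
displacement rule — label placement is presentation, not contract.

`buildReport()` assembles front matter (protocol synopsis, amendments,
previous recommendations, previous imbalances, and — when a previous
manifest is supplied — an automatic "what has changed" summary), baseline,
adverse events, laboratory, vital signs (the same operators applied to
the configured vitals parameters), patient profiles, an optional
verbatim efficacy placeholder (no efficacy statistics are computed; the
note points to the DMC charter), and an appendix of detailed listings.
One intermediate representation drives both outputs: a paginated PDF
drawn directly with grid (one block per page, true page numbers in the
table of contents) and an anchor-linked HTML document. Empty inputs
produce explicit "no events" statements rather than silently missing
sections. The manifest records the section set, pagination, artifact
hashes and a comparable state snapshot; `diffSincePrevious()` compares
two manifests to list new subjects, new adverse events, newly flagged
outliers and newly selected profile subjects. Reports are unblinded by
design (arm labels verbatim); a relabeling flag supports semi-blinded
output when a charter requires it.

**Patient profiles** select the union of subjects with a serious adverse
event, an adverse event of grade 3 or higher, or a laboratory value
grading 3 or higher — each id carrying its reasons. A profile is one
page: demographics, truncated history and medication lists (most recent
15 with an explicit "+k more" marker), exposure, adverse events, the
laboratory parameters with at least one abnormal value (baseline, worst
with grade, last), and a key-event timeline in which unresolved adverse
events extend to the data cut with an ongoing marker.

# The synthetic-trial generator

The generator exists so that every pipeline stage and every acceptance
property runs offline with known ground truth. Per arm it draws
demographics (truncated-normal age on [18, 90]), an exposure duration
(completers receive the full planned duration; dropouts a truncated
exponential), at most one event per adverse-event model from a
constant-hazard exponential clock emitted only within exposure, and
laboratory values at scheduled visits while on treatment: a log-normal
baseline, an additive per-visit log drift per arm, within-subject noise,
and occasional injected outliers drawn uniformly in (1.05, 1.5) times
`outlier_multiplier` times the subject's own ULN — strictly above the
selection threshold, so selection logic has exact ground truth. Limits of
normal are jittered per subject by a common multiplicative log-normal
factor, which preserves `lln < uln` by construction. Each table draws
from its own seeded stream, so adding a laboratory model never perturbs
the adverse-event draws. Study days are per-subject (first dose = day 1),
which makes the enrollment-window setting inert in study-day space; it is
retained for configuration-shape compatibility.

The bundled fixture (`xanomelineLikeFixture()`) echoes the shape of a
placebo-controlled study in an elderly population — two arms, a
skin-and-nervous-system-weighted adverse-event mix running hotter on
active treatment, a cholesterol-like parameter with common limits and a
creatine-kinase-like parameter with subject-jittered limits and injected
outliers. All of its numbers are synthetic.

What the generator does **not** emulate: correlated multi-parameter
physiology, recurrent adverse-event episodes (first event only),
realistic MedDRA vocabularies, visit-window jitter, and
missing-not-at-random lab data. Passing tests therefore demonstrate the
pipeline's correctness on data of the right *shape*, not the behaviour of
any real compound.

# Problem sizes and numerical checks

The test suite verifies the exact test against an independent
full-enumeration oracle on every 2x2 table with total N up to 25, the
FDR adjustment against the naive step-up definition on 1,000 random
vectors, box statistics against a sort-based oracle on every small
integer multiset up to size 8, arm-swap antisymmetry on 50 seeded trials,
and injected-imbalance recovery on 100 seeded trials of 200 subjects per
arm with one elevated term among ten null terms. Reports in the checks
are built from 30–60 subjects per arm; the statistics do not change
character with size, only runtime. Determinism is checked end to end:
the same seed and configuration produce byte-identical CSVs, manifests
and figures (PDF files embed a device creation timestamp and are
compared structurally — page counts and TOC — rather than byte-wise).
Two rendering choices exist purely for reproducibility: SVG output pins
a concrete font family (option `dmcreport.font_family`) because generic
family resolution can vary with font-cache state, and PNG output uses
the ragg device so raster text metrics never share a cache with the SVG
device's unhinted metrics — mixing the two makes text layout depend on
rendering order.

# Known limitations

- The rate-ratio axis is an exposure-adjusted incidence ratio, not a
  hazard ratio from a survival model; for strongly time-varying hazards
  the two differ.
- Exact p-values at very small denominators are highly discrete; the
  volcano's vertical spread collapses accordingly (this is a property of
  the data, not the display).
- The grading defaults are placeholders; unit conversion between
  laboratory unit systems is out of scope.
- The efficacy section renders supplied text verbatim and computes
  nothing; interim efficacy monitoring belongs to the DMC charter.
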