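# Shared fixtures and independent oracles used across the suite.

suppressMessages({
  library(dplyr)
  library(tibble)
})

# Small hand-built trial with known content for unit tests.
tiny_trial <- function() {
  subjects <- tibble(
    subject_id = c("A1", "A2", "A3", "A4", "B1", "B2", "B3", "B4"),
    arm = rep(c("Active", "Placebo"), each = 4),
    age = c(70, 72, 68, 75, 71, 69, 74, 73),
    sex = c("F", "M", "F", "F", "M", "F", "M", "F"),
    race = "WHITE", country = "USA",
    first_dose_day = 1L, last_dose_day = 180L,
    randomized_flag = TRUE, discontinued_flag = FALSE)
  ae <- tibble(
    subject_id = c("A1", "A1", "A1", "A2", "B1"),
    preferred_term = c("Nausea", "Nausea", "Nausea", "Nausea", "Headache"),
    system_organ_class = c(rep("Gastrointestinal disorders", 4),
                           "Nervous system disorders"),
    onset_day = c(10L, 30L, 50L, 20L, 15L),
    resolution_day = c(12L, 33L, NA, 25L, 16L),
    ctc_grade = c(1L, 2L, 1L, 3L, 1L),
    serious_flag = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    related_flag = TRUE, discontinuation_flag = FALSE, aesi_flag = FALSE)
  labs <- tibble(
    subject_id = rep(c("A1", "A2", "B1"), each = 3),
    param_code = "ALT", param_name = "Alanine aminotransferase",
    visit_index = rep(0:2, 3), visit_name = rep(c("Baseline", "W2", "W4"), 3),
    day = rep(c(1L, 14L, 28L), 3),
    value = c(30, 60, 45, 20, 22, 21, 25, 80, 30),
    unit = "U/L", lln = 7, uln = 40,
    baseline_flag = rep(c(TRUE, FALSE, FALSE), 3))
  exposure <- tibble(subject_id = subjects$subject_id, start_day = 1L,
                     end_day = 180L, dose_label = subjects$arm)
  conmeds <- tibble(subject_id = "A1", term = "Paracetamol", start_day = 5L,
                    end_day = 10L, ongoing_flag = FALSE)
  medhistory <- tibble(subject_id = "A1", term = "Hypertension",
                       start_day = -400L, end_day = NA_integer_,
                       ongoing_flag = TRUE)
  newTrialData(subjects, ae, labs, exposure, conmeds, medhistory,
               arms = c("Active", "Placebo"), reference_arm = "Placebo",
               cutoff_day = 182L)
}

fixture_trial <- function(seed = 1L, n = 50L) {
  generateTrial(xanomelineLikeFixture(n_per_arm = n, seed = seed))
}

# Independent two-sided Fisher oracle: enumerates every table with the
# observed margins and computes each probability from the factorial
# identity P = r1! r2! c1! c2! / (N! a! b! c! d!).
oracle_fisher <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12; r2 <- n21 + n22
  c1 <- n11 + n21; c2 <- n12 + n22
  N <- r1 + r2
  if (N == 0) return(NA_real_)
  lp <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(N) - lfactorial(a) - lfactorial(b) - lfactorial(cc) -
      lfactorial(d)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(vapply(support, lp, numeric(1)))
  obs <- probs[support == n11]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Independent sort-based quantile oracle (linear interpolation between
# order statistics) and box-statistics oracle.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

oracle_box <- function(x) {
  q1 <- oracle_quantile(x, 0.25)
  q3 <- oracle_quantile(x, 0.75)
  iqr <- q3 - q1
  inside <- x[x >= q1 - 1.5 * iqr & x <= q3 + 1.5 * iqr]
  list(q1 = q1, median = oracle_quantile(x, 0.5), q3 = q3,
       whisker_lo = min(inside), whisker_hi = max(inside),
       outliers = sort(x[x < q1 - 1.5 * iqr | x > q3 + 1.5 * iqr]))
}

# Config for parameter-recovery runs: one elevated term among null terms,
# full one-year exposure, no laboratory models (speed).
recovery_config <- function(seed, n_per_arm = 200L, n_null = 10L,
                            h_active = 0.15, h_ref = 0.05, h_null = 0.08) {
  mild <- c(.6, .3, .08, .015, .005)
  models <- c(
    list(list(preferred_term = "TermInjected", system_organ_class = "SOC A",
              hazard_per_year = c(Active = h_active, Placebo = h_ref),
              serious_prob = 0.02, grade_probs = mild, related_prob = 0.5)),
    lapply(seq_len(n_null), function(i)
      list(preferred_term = sprintf("TermNull%02d", i),
           system_organ_class = "SOC B",
           hazard_per_year = c(Active = h_null, Placebo = h_null),
           serious_prob = 0.02, grade_probs = mild, related_prob = 0.5)))
  synthConfig(
    arms = list(list(label = "Active", n_subjects = n_per_arm),
                list(label = "Placebo", n_subjects = n_per_arm)),
    reference_arm = "Placebo", exposure_mean_days = 365,
    study_length_days = 365L, dropout_prob = 0,
    ae_models = models, lab_models = list(), seed = seed)
}
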