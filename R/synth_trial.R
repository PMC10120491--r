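#' Build a synthetic-trial configuration
#'
#' Describes a CDISC-shaped randomized trial with injectable safety
#' imbalances: per-arm sample sizes and demographics, an exponential
#' exposure-duration model, per-preferred-term constant-hazard
#' adverse-event models, and log-normal laboratory models with per-visit
#' drift, within-subject noise, occasional injected outliers above the
#' subject's own upper limit of normal, and subject-jittered limits.
#'
#' Study days are per-subject (first dose = day 1), so
#' `enrollment_window_days` does not shift any study-day value; it is kept
#' for configuration-shape compatibility with calendar-time generators.
#'
#' @param arms List of `list(label =, n_subjects =)`.
#' @param reference_arm Label of the control arm.
#' @param age_mean,age_sd Normal age model, truncated at 18–90 years.
#' @param sex_female_prob Named per-arm probability (or single number).
#' @param enrollment_window_days Enrollment window (inert in study-day space).
#' @param exposure_mean_days Mean of the exponential exposure-duration model,
#'   truncated at `study_length_days`.
#' @param study_length_days Planned treatment duration; completers are
#'   exposed this long.
#' @param dropout_prob Probability a subject discontinues early (exposure
#'   then follows the truncated exponential).
#' @param ae_models List of per-term models:
#'   `list(preferred_term =, system_organ_class =, hazard_per_year = named
#'   per-arm positive rate, serious_prob =, grade_probs = 5-vector summing
#'   to 1, related_prob =, aesi = FALSE)`.
#' @param lab_models List of per-parameter models: `list(param_code =,
#'   param_name =, unit =, baseline_meanlog =, baseline_sdlog =,
#'   arm_drift = named per-arm additive log drift per visit step,
#'   visit_schedule = strictly increasing study days (first = baseline),
#'   sd_within =, outlier_prob =, outlier_multiplier =, lln =, uln =,
#'   limit_jitter_sd = sd of the multiplicative log-scale limit jitter)`.
#' @param conmed_terms,medhistory_terms Term pools for the profile tables.
#' @param seed Master seed; one derived stream per table.
#' @return A `synth_config` object.
#' @export
synthConfig <- function(arms, reference_arm, age_mean = 65, age_sd = 10,
                        sex_female_prob = 0.5, enrollment_window_days = 90,
                        exposure_mean_days = 120, study_length_days = 182,
                        dropout_prob = 0.25, ae_models = list(),
                        lab_models = list(),
                        conmed_terms = c("Paracetamol", "Ibuprofen", "Lisinopril",
                                         "Atorvastatin", "Metformin"),
                        medhistory_terms = c("Hypertension", "Osteoarthritis",
                                             "Type 2 diabetes mellitus",
                                             "Hyperlipidaemia", "Depression"),
                        seed = 1L) {
  labels <- vapply(arms, `[[`, character(1), "label")
  ns <- vapply(arms, `[[`, numeric(1), "n_subjects")
  if (any(ns <= 0)) stop("config error: n_subjects must be positive", call. = FALSE)
  stopifnot(reference_arm %in% labels, !anyDuplicated(labels))
  if (length(sex_female_prob) == 1 && is.null(names(sex_female_prob))) {
    sex_female_prob <- stats::setNames(rep(sex_female_prob, length(labels)), labels)
  }
  stopifnot(all(sex_female_prob >= 0 & sex_female_prob <= 1),
            dropout_prob >= 0, dropout_prob <= 1)
  for (m in ae_models) {
    stopifnot(all(m$hazard_per_year >= 0),
              abs(sum(m$grade_probs) - 1) < 1e-8, length(m$grade_probs) == 5,
              m$serious_prob >= 0, m$serious_prob <= 1)
  }
  for (m in lab_models) {
    stopifnot(all(diff(m$visit_schedule) > 0), m$outlier_prob >= 0,
              m$outlier_prob <= 1, is.na(m$lln) || is.na(m$uln) || m$lln < m$uln)
  }
  structure(list(
    arms = labels, n_subjects = stats::setNames(as.integer(ns), labels),
    reference_arm = reference_arm, age_mean = age_mean, age_sd = age_sd,
    sex_female_prob = sex_female_prob,
    enrollment_window_days = enrollment_window_days,
    exposure_mean_days = exposure_mean_days,
    study_length_days = as.integer(study_length_days),
    dropout_prob = dropout_prob, ae_models = ae_models,
    lab_models = lab_models, conmed_terms = conmed_terms,
    medhistory_terms = medhistory_terms, seed = as.integer(seed)
  ), class = "synth_config")
}

# Derived per-table sub-seed: keeps each table's stream stable when other
# models are added (regression-test stability).
.sub_seed <- function(seed, k) (as.integer(seed) %% 1000003L) * 1009L + 97L * k

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic trial
#'
#' Deterministic given `config$seed`. The returned object carries a
#' `ground_truth` attribute recording what was injected — subjects given a
#' serious adverse event, a grade >= 3 adverse event, and laboratory values
#' injected above `outlier_multiplier` times the subject's own upper limit
#' of normal — so selection logic can be audited against a known answer.
#'
#' @param config A [synthConfig()] object.
#' @return A validated `trial_data` object.
#' @export
generateTrial <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  arms <- config$arms
  L <- config$study_length_days

  ## -- subjects & exposure ------------------------------------------------
  set.seed(.sub_seed(config$seed, 1L))
  races <- c("WHITE", "BLACK OR AFRICAN AMERICAN", "ASIAN", "OTHER")
  countries <- c("USA", "DEU", "JPN", "GBR")
  subj <- bind_rows(lapply(arms, function(a) {
    n <- config$n_subjects[[a]]
    code <- toupper(substr(gsub("[^A-Za-z]", "", a), 1, 2))
    tibble(
      subject_id = sprintf("S-%s-%04d", code, seq_len(n)),
      arm = a,
      age = round(.rtruncnorm(n, config$age_mean, config$age_sd, 18, 90), 1),
      sex = ifelse(stats::runif(n) < config$sex_female_prob[[a]], "F", "M"),
      race = sample(races, n, replace = TRUE, prob = c(.7, .12, .12, .06)),
      country = sample(countries, n, replace = TRUE),
      first_dose_day = 1L,
      discontinued_flag = stats::runif(n) < config$dropout_prob,
      randomized_flag = TRUE
    )
  }))
  dur <- pmin(stats::rexp(nrow(subj), rate = 1 / config$exposure_mean_days), L)
  subj$last_dose_day <- ifelse(subj$discontinued_flag,
                               pmax(1L, as.integer(ceiling(dur))), L)
  subj <- subj[c("subject_id", "arm", "age", "sex", "race", "country",
                 "first_dose_day", "last_dose_day", "randomized_flag",
                 "discontinued_flag")]
  exposure <- tibble(
    subject_id = subj$subject_id, start_day = 1L,
    end_day = subj$last_dose_day,
    dose_label = subj$arm
  )

  ## -- adverse events: first event per term, constant hazard --------------
  set.seed(.sub_seed(config$seed, 2L))
  ae_rows <- list()
  for (m in config$ae_models) {
    rate_day <- unname(m$hazard_per_year[subj$arm]) / 365.25
    t_event <- ifelse(rate_day > 0, stats::rexp(nrow(subj), pmax(rate_day, 1e-12)), Inf)
    hit <- which(t_event <= subj$last_dose_day & rate_day > 0)
    if (!length(hit)) next
    n <- length(hit)
    onset <- pmax(1L, as.integer(ceiling(t_event[hit])))
    resolved <- stats::runif(n) < 0.85
    res_day <- onset + as.integer(stats::rpois(n, 10))
    ae_rows[[length(ae_rows) + 1L]] <- tibble(
      subject_id = subj$subject_id[hit],
      preferred_term = m$preferred_term,
      system_organ_class = m$system_organ_class,
      onset_day = onset,
      resolution_day = ifelse(resolved, res_day, NA_integer_),
      ctc_grade = as.integer(sample(1:5, n, replace = TRUE, prob = m$grade_probs)),
      serious_flag = stats::runif(n) < m$serious_prob,
      related_flag = stats::runif(n) < (m$related_prob %||% 0.5),
      discontinuation_flag = FALSE,
      aesi_flag = isTRUE(m$aesi)
    )
  }
  ae <- if (length(ae_rows)) bind_rows(ae_rows) else tibble(
    subject_id = character(), preferred_term = character(),
    system_organ_class = character(), onset_day = integer(),
    resolution_day = integer(), ctc_grade = integer(),
    serious_flag = logical(), related_flag = logical(),
    discontinuation_flag = logical(), aesi_flag = logical())
  if (nrow(ae)) {
    ae$resolution_day <- pmin(ae$resolution_day, config$study_length_days)
    ae <- arrange(ae, .data$subject_id, .data$onset_day, .data$preferred_term)
  }

  ## -- laboratory values ---------------------------------------------------
  set.seed(.sub_seed(config$seed, 3L))
  lab_rows <- list()
  gt_outliers <- list()
  for (m in config$lab_models) {
    sched <- as.integer(m$visit_schedule)
    jitter <- exp(stats::rnorm(nrow(subj), 0, m$limit_jitter_sd %||% 0))
    lln_s <- if (is.na(m$lln %||% NA)) rep(NA_real_, nrow(subj)) else m$lln * jitter
    uln_s <- if (is.na(m$uln %||% NA)) rep(NA_real_, nrow(subj)) else m$uln * jitter
    base <- stats::rlnorm(nrow(subj), m$baseline_meanlog, m$baseline_sdlog)
    drift <- unname((m$arm_drift %||% stats::setNames(rep(0, length(arms)), arms))[subj$arm])
    for (v in seq_along(sched)) {
      day <- sched[v]
      # a subject attends a visit while on treatment (baseline always)
      on <- if (v == 1L) rep(TRUE, nrow(subj)) else day <= subj$last_dose_day
      idx <- which(on)
      if (!length(idx)) next
      n <- length(idx)
      if (v == 1L) {
        val <- base[idx]
        is_out <- rep(FALSE, n)
      } else {
        val <- exp(log(base[idx]) + drift[idx] * (v - 1L) +
                     stats::rnorm(n, 0, m$sd_within))
        is_out <- stats::runif(n) < (m$outlier_prob %||% 0) & !is.na(uln_s[idx])
        if (any(is_out)) {
          val[is_out] <- uln_s[idx][is_out] * (m$outlier_multiplier %||% 3) *
            stats::runif(sum(is_out), 1.05, 1.5)
        }
      }
      lab_rows[[length(lab_rows) + 1L]] <- tibble(
        subject_id = subj$subject_id[idx], param_code = m$param_code,
        param_name = m$param_name, visit_index = v - 1L,
        visit_name = if (v == 1L) "Baseline" else paste("Week", day %/% 7),
        day = day, value = round(val, 4), unit = m$unit,
        lln = round(lln_s[idx], 4), uln = round(uln_s[idx], 4),
        baseline_flag = v == 1L)
      if (any(is_out)) {
        gt_outliers[[length(gt_outliers) + 1L]] <- tibble(
          subject_id = subj$subject_id[idx][is_out], param_code = m$param_code,
          day = day)
      }
    }
  }
  labs <- if (length(lab_rows)) {
    arrange(bind_rows(lab_rows), .data$param_code, .data$subject_id, .data$day)
  } else tibble(
    subject_id = character(), param_code = character(), param_name = character(),
    visit_index = integer(), visit_name = character(), day = integer(),
    value = numeric(), unit = character(), lln = numeric(), uln = numeric(),
    baseline_flag = logical())

  ## -- concomitant medication & medical history ---------------------------
  set.seed(.sub_seed(config$seed, 4L))
  mk_hist <- function(terms, interval) {
    rows <- lapply(seq_len(nrow(subj)), function(i) {
      k <- stats::rpois(1, 1.2)
      if (k == 0) return(NULL)
      picked <- sample(terms, min(k, length(terms)))
      st <- if (interval) as.integer(sample(-30:60, length(picked), replace = TRUE))
            else as.integer(sample(-2000:-100, length(picked), replace = TRUE))
      ongoing <- stats::runif(length(picked)) < 0.4
      tibble(subject_id = subj$subject_id[i], term = picked, start_day = st,
             end_day = ifelse(ongoing, NA_integer_,
                              st + as.integer(sample(5:120, length(picked), TRUE))),
             ongoing_flag = ongoing)
    })
    out <- bind_rows(rows)
    if (!nrow(out)) tibble(subject_id = character(), term = character(),
                           start_day = integer(), end_day = integer(),
                           ongoing_flag = logical()) else out
  }
  conmeds <- mk_hist(config$conmed_terms, interval = TRUE)
  medhistory <- mk_hist(config$medhistory_terms, interval = FALSE)

  trial <- newTrialData(
    subjects = subj, adverse_events = ae, labs = labs, exposure = exposure,
    conmeds = conmeds, medhistory = medhistory, arms = arms,
    reference_arm = config$reference_arm, cutoff_day = L)

  gt_out <- if (length(gt_outliers)) bind_rows(gt_outliers) else
    tibble(subject_id = character(), param_code = character(), day = integer())
  attr(trial, "ground_truth") <- list(
    sae_subjects = sort(unique(ae$subject_id[ae$serious_flag %in% TRUE])),
    grade3_ae_subjects = sort(unique(ae$subject_id[!is.na(ae$ctc_grade) &
                                                     ae$ctc_grade >= 3L])),
    lab_outliers = gt_out)
  trial
}

#' Canned configuration echoing the shape of an elderly two-arm study
#'
#' A fixed, documented configuration emulating the shape of a
#' placebo-controlled study in an elderly population: a Placebo and a
#' High Dose arm, a skin-and-nervous-system-weighted adverse-event mix in
#' which several terms run hotter on active treatment, a cholesterol-like
#' parameter with common limits of normal, and a creatine-kinase-like
#' parameter with subject-jittered limits and injected outliers above
#' three times the upper limit of normal. All values are synthetic.
#'
#' @param n_per_arm Subjects per arm (default 100).
#' @param seed Master seed (default 20230421).
#' @return A `synth_config` object.
#' @export
xanomelineLikeFixture <- function(n_per_arm = 100L, seed = 20230421L) {
  arms <- c("High Dose", "Placebo")
  haz <- function(hd, pbo) c("High Dose" = hd, "Placebo" = pbo)
  mild <- c(.55, .3, .1, .04, .01)
  ae_models <- list(
    list(preferred_term = "Pruritus", system_organ_class = "Skin and subcutaneous tissue disorders",
         hazard_per_year = haz(0.90, 0.15), serious_prob = 0.01, grade_probs = mild, related_prob = 0.8),
    list(preferred_term = "Application site pruritus", system_organ_class = "General disorders and administration site conditions",
         hazard_per_year = haz(0.60, 0.10), serious_prob = 0.00, grade_probs = mild, related_prob = 0.9),
    list(preferred_term = "Dizziness", system_organ_class = "Nervous system disorders",
         hazard_per_year = haz(0.45, 0.12), serious_prob = 0.02, grade_probs = mild, related_prob = 0.6),
    list(preferred_term = "Erythema", system_organ_class = "Skin and subcutaneous tissue disorders",
         hazard_per_year = haz(0.35, 0.08), serious_prob = 0.00, grade_probs = mild, related_prob = 0.7),
    list(preferred_term = "Nausea", system_organ_class = "Gastrointestinal disorders",
         hazard_per_year = haz(0.25, 0.15), serious_prob = 0.01, grade_probs = mild, related_prob = 0.4),
    list(preferred_term = "Syncope", system_organ_class = "Nervous system disorders",
         hazard_per_year = haz(0.10, 0.03), serious_prob = 0.6,
         grade_probs = c(.05, .25, .5, .18, .02), related_prob = 0.3, aesi = TRUE),
    list(preferred_term = "Fall", system_organ_class = "Injury, poisoning and procedural complications",
         hazard_per_year = haz(0.12, 0.10), serious_prob = 0.25,
         grade_probs = c(.3, .35, .25, .09, .01), related_prob = 0.1),
    list(preferred_term = "Headache", system_organ_class = "Nervous system disorders",
         hazard_per_year = haz(0.20, 0.20), serious_prob = 0.00, grade_probs = mild, related_prob = 0.3),
    list(preferred_term = "Diarrhoea", system_organ_class = "Gastrointestinal disorders",
         hazard_per_year = haz(0.15, 0.12), serious_prob = 0.01, grade_probs = mild, related_prob = 0.3),
    list(preferred_term = "Urinary tract infection", system_organ_class = "Infections and infestations",
         hazard_per_year = haz(0.10, 0.11), serious_prob = 0.05,
         grade_probs = c(.4, .35, .2, .04, .01), related_prob = 0.05)
  )
  visits <- c(1L, 14L, 28L, 56L, 84L, 112L, 140L, 168L)
  lab_models <- list(
    list(param_code = "CHOL", param_name = "Cholesterol", unit = "mmol/L",
         baseline_meanlog = log(5.2), baseline_sdlog = 0.18,
         arm_drift = c("High Dose" = 0.004, "Placebo" = 0.0),
         visit_schedule = visits, sd_within = 0.07, outlier_prob = 0,
         outlier_multiplier = 3, lln = 2.0, uln = 6.2, limit_jitter_sd = 0),
    list(param_code = "CK", param_name = "Creatine Kinase", unit = "U/L",
         baseline_meanlog = log(95), baseline_sdlog = 0.35,
         arm_drift = c("High Dose" = 0.02, "Placebo" = 0.0),
         visit_schedule = visits, sd_within = 0.2, outlier_prob = 0.01,
         outlier_multiplier = 3, lln = 30, uln = 170, limit_jitter_sd = 0.08)
  )
  synthConfig(
    arms = list(list(label = "High Dose", n_subjects = n_per_arm),
                list(label = "Placebo", n_subjects = n_per_arm)),
    reference_arm = "Placebo", age_mean = 75, age_sd = 8,
    sex_female_prob = c("High Dose" = 0.55, "Placebo" = 0.55),
    exposure_mean_days = 140, study_length_days = 182L, dropout_prob = 0.35,
    ae_models = ae_models, lab_models = lab_models, seed = seed)
}
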