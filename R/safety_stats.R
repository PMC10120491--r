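#' Two-sided Fisher exact p-value by direct hypergeometric enumeration
#'
#' Computes the minimum-likelihood two-sided exact p-value for a 2x2 table
#' with cells `(n11, n12; n21, n22)`: conditioning on the margins, the
#' p-value is the sum of the point hypergeometric probabilities of all
#' tables whose probability does not exceed that of the observed table
#' (with a relative tolerance of 1e-7 to absorb floating-point ties).
#'
#' @param n11,n12,n21,n22 Non-negative cell counts.
#' @return p-value in (0, 1]; `NA` when all four cells are zero.
#' @export
fisherTwoSided <- function(n11, n12, n21, n22) {
  cells <- c(n11, n12, n21, n22)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if (all(cells == 0)) return(NA_real_)
  r1 <- n11 + n12; r2 <- n21 + n22
  c1 <- n11 + n21; N <- r1 + r2
  # degenerate margin: only one table is possible
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) return(1)
  a <- max(0, c1 - r2):min(r1, c1)
  logmass <- lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(N, c1)
  mass <- exp(logmass)
  obs <- mass[a == n11]
  p <- sum(mass[mass <= obs * (1 + 1e-7)])
  min(p, 1)
}

#' Benjamini–Hochberg step-up adjustment
#'
#' With order statistics p(1) <= ... <= p(m), the adjusted value at rank i
#' is `min(1, min_{j >= i} m * p(j) / j)`, mapped back to input positions;
#' tied p-values share identical adjusted values.
#'
#' @param p_values Numeric vector with values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bhAdjust <- function(p_values) {
  stopifnot(length(p_values) >= 1)
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  o <- order(p_values)
  sorted <- p_values[o]
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * sorted[i] / i)
    adj[i] <- running
  }
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Exposure-adjusted incidence rate ratio
#'
#' `((n_a + c) / py_a) / ((n_b + c) / py_b)` with the continuity constant
#' `c` applied to both arms only when either event count is zero (default
#' 0.5). Exactly symmetric: swapping the arms inverts the ratio.
#'
#' @param n_a,n_b Event (or affected-subject) counts.
#' @param py_a,py_b Person-years at risk; must be positive.
#' @param continuity Continuity constant for zero cells.
#' @return Positive rate ratio.
#' @export
rateRatio <- function(n_a, py_a, n_b, py_b, continuity = 0.5) {
  if (py_a <= 0 || py_b <= 0) stop("person-years must be positive", call. = FALSE)
  stopifnot(n_a >= 0, n_b >= 0, continuity >= 0)
  cc <- if (n_a == 0 || n_b == 0) continuity else 0
  ((n_a + cc) / py_a) / ((n_b + cc) / py_b)
}

# Safety population and person-time. A subject is dosed (at risk) iff
# first_dose_day is present; person-time runs from first to last dose day
# inclusive, in years of 365.25 days.
.safety_pop <- function(trial) {
  trial$subjects |>
    filter(!is.na(.data$first_dose_day)) |>
    mutate(person_years = (.data$last_dose_day - .data$first_dose_day + 1) / 365.25)
}

# Treatment-emergent window: onset on/after first dose, no later than
# last dose + `te_window` days.
.te_events <- function(trial, te_window = 30) {
  pop <- .safety_pop(trial)
  trial$adverse_events |>
    inner_join(pop |> select("subject_id", "arm", "first_dose_day",
                             "last_dose_day"),
               by = "subject_id") |>
    filter(.data$onset_day >= .data$first_dose_day,
           .data$onset_day <= .data$last_dose_day + te_window)
}

#' Subject-level adverse-event incidence, crude and exposure-adjusted
#'
#' One record per term x arm. A subject contributes at most once to
#' `n_subjects_with_event` per term regardless of how many events they
#' report; `n_at_risk` is the number of dosed subjects in the arm (safety
#' population) and `person_years` the arm total of per-subject exposure
#' time. Terms with zero events in every arm are omitted; a term observed
#' in one arm still yields a zero-count record for the other arms.
#'
#' @param trial A validated `trial_data`.
#' @param filters Optional row filter over the adverse-event table: either
#'   a predicate function (data frame -> logical vector) or a named list
#'   of equality conditions, e.g. `list(serious_flag = TRUE)`.
#' @param group_by `"preferred_term"` or `"system_organ_class"`.
#' @param arms Optional subset of arms; an unknown label is an error.
#' @param te_window Treatment-emergent lag after last dose, in days.
#' @return Tibble of incidence records with `percent` and `rate_per_100py`.
#' @export
aeIncidence <- function(trial, filters = NULL,
                        group_by = c("preferred_term", "system_organ_class"),
                        arms = NULL, te_window = 30) {
  group_by <- match.arg(group_by)
  arms <- arms %||% trial$arms
  unknown <- setdiff(arms, trial$arms)
  if (length(unknown)) {
    stop("unknown arm(s) in filters: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ev <- .te_events(trial, te_window) |> filter(.data$arm %in% arms)
  if (is.function(filters)) {
    ev <- ev[filters(ev), , drop = FALSE]
  } else if (is.list(filters) && length(filters)) {
    for (nm in names(filters)) ev <- ev[ev[[nm]] %in% filters[[nm]], , drop = FALSE]
  }
  pop <- .safety_pop(trial) |> filter(.data$arm %in% arms)
  denom <- pop |>
    group_by(.data$arm) |>
    summarise(n_at_risk = dplyr::n(), person_years = sum(.data$person_years),
              .groups = "drop")
  if (!nrow(ev)) {
    return(tibble(term = character(), system_organ_class = character(),
                  arm = character(), n_subjects_with_event = integer(),
                  n_at_risk = integer(), percent = numeric(),
                  n_events = integer(), person_years = numeric(),
                  rate_per_100py = numeric()) |>
             rename(!!group_by := "term"))
  }
  soc <- ev |>
    group_by(term = .data[[group_by]]) |>
    summarise(system_organ_class = .data$system_organ_class[1], .groups = "drop")
  counts <- ev |>
    group_by(term = .data[[group_by]], .data$arm) |>
    summarise(n_subjects_with_event = dplyr::n_distinct(.data$subject_id),
              n_events = dplyr::n(), .groups = "drop")
  out <- tidyr::expand_grid(term = unique(counts$term), arm = arms) |>
    left_join(counts, by = c("term", "arm")) |>
    mutate(n_subjects_with_event = tidyr::replace_na(.data$n_subjects_with_event, 0L),
           n_events = tidyr::replace_na(.data$n_events, 0L)) |>
    left_join(denom, by = "arm") |>
    left_join(soc, by = "term") |>
    mutate(percent = 100 * .data$n_subjects_with_event / .data$n_at_risk,
           rate_per_100py = ifelse(.data$person_years > 0,
                                   100 * .data$n_subjects_with_event / .data$person_years,
                                   NA_real_)) |>
    select("term", "system_organ_class", "arm", "n_subjects_with_event",
           "n_at_risk", "percent", "n_events", "person_years",
           "rate_per_100py") |>
    arrange(.data$term, match(.data$arm, arms))
  if (group_by == "preferred_term") {
    out <- rename(out, preferred_term = "term")
  } else {
    out <- out |> select(-"system_organ_class") |>
      rename(system_organ_class = "term")
  }
  out
}

#' Deterministic term ordering for the adverse-event dot plot
#'
#' Sorts terms by the chosen arm's incidence metric (descending by
#' default); ties are broken by the highest other-arm metric descending,
#' then alphabetically — a deterministic total order.
#'
#' @param records Output of [aeIncidence()].
#' @param by_arm Arm whose rates drive the ordering.
#' @param descending Sort direction (default `TRUE`).
#' @param metric `"percent"` or `"rate_per_100py"` (exposure-adjusted view).
#' @return Character vector of unique terms in display order.
#' @export
orderTerms <- function(records, by_arm, descending = TRUE,
                       metric = c("percent", "rate_per_100py")) {
  metric <- match.arg(metric)
  term_col <- if ("preferred_term" %in% names(records)) "preferred_term"
              else "system_organ_class"
  stopifnot(by_arm %in% records$arm)
  wide <- records |>
    group_by(term = .data[[term_col]]) |>
    summarise(
      primary = sum(.data[[metric]][.data$arm == by_arm], na.rm = TRUE),
      other = if (all(.data$arm == by_arm)) 0 else
        max(.data[[metric]][.data$arm != by_arm], 0, na.rm = TRUE),
      .groups = "drop")
  s <- if (descending) -1 else 1
  wide <- arrange(wide, s * .data$primary, s * .data$other, .data$term)
  wide$term
}

#' Volcano statistics for one arm-pair comparison
#'
#' For every preferred term with at least one affected subject in either
#' arm: subject-level 2x2 incidence, a two-sided Fisher exact p-value
#' ([fisherTwoSided()]), Benjamini–Hochberg adjusted p-values over all
#' included terms jointly ([bhAdjust()]), and either a risk difference in
#' percentage points or an exposure-adjusted incidence rate ratio. The
#' p-values are descriptive screening measures, not confirmatory tests.
#'
#' @param trial A validated `trial_data`.
#' @param arm_a,arm_b Distinct arm labels (`arm_b` is the reference).
#' @param estimate_kind `"risk_difference"` (percentage points) or
#'   `"rate_ratio"`.
#' @param label_rule `list(p_cutoff = 0.05)` labels terms with raw
#'   p below the cutoff; `list(top_k = 10)` labels the k smallest
#'   p-values, ties broken by larger absolute effect then alphabetically.
#' @param te_window Treatment-emergent lag after last dose, in days.
#' @param continuity Zero-cell continuity constant for the rate ratio.
#' @return Tibble of volcano records sorted by p-value; zero rows when no
#'   term is eligible.
#' @export
volcanoStats <- function(trial, arm_a, arm_b,
                         estimate_kind = c("risk_difference", "rate_ratio"),
                         label_rule = list(p_cutoff = 0.05),
                         te_window = 30, continuity = 0.5) {
  estimate_kind <- match.arg(estimate_kind)
  stopifnot(arm_a != arm_b, all(c(arm_a, arm_b) %in% trial$arms))
  inc <- aeIncidence(trial, group_by = "preferred_term",
                     arms = c(arm_a, arm_b), te_window = te_window)
  if (!nrow(inc)) {
    return(tibble(preferred_term = character(), estimate_kind = character(),
                  estimate = numeric(), p_value = numeric(), fdr_p = numeric(),
                  n_event_a = integer(), n_event_b = integer(),
                  n_a = integer(), n_b = integer(), labeled = logical()))
  }
  a <- inc |> filter(.data$arm == arm_a)
  b <- inc |> filter(.data$arm == arm_b)
  rec <- inner_join(
    a |> select("preferred_term", n_event_a = "n_subjects_with_event",
                n_a = "n_at_risk", py_a = "person_years"),
    b |> select("preferred_term", n_event_b = "n_subjects_with_event",
                n_b = "n_at_risk", py_b = "person_years"),
    by = "preferred_term") |>
    filter(.data$n_event_a + .data$n_event_b > 0)
  if (!nrow(rec)) return(volcanoStats(trial, arm_a, arm_b)[0, ])
  rec$p_value <- mapply(function(ea, na, eb, nb)
    fisherTwoSided(ea, na - ea, eb, nb - eb),
    rec$n_event_a, rec$n_a, rec$n_event_b, rec$n_b)
  rec$fdr_p <- bhAdjust(rec$p_value)
  rec$estimate <- if (estimate_kind == "risk_difference") {
    100 * (rec$n_event_a / rec$n_a - rec$n_event_b / rec$n_b)
  } else {
    mapply(rateRatio, rec$n_event_a, rec$py_a, rec$n_event_b, rec$py_b,
           MoreArgs = list(continuity = continuity))
  }
  eff_mag <- if (estimate_kind == "rate_ratio") abs(log(rec$estimate)) else abs(rec$estimate)
  if (!is.null(label_rule$p_cutoff)) {
    rec$labeled <- rec$p_value < label_rule$p_cutoff
  } else if (!is.null(label_rule$top_k)) {
    ord <- order(rec$p_value, -eff_mag, rec$preferred_term)
    rec$labeled <- FALSE
    rec$labeled[ord[seq_len(min(label_rule$top_k, nrow(rec)))]] <- TRUE
  } else {
    stop("label_rule must contain `p_cutoff` or `top_k`", call. = FALSE)
  }
  rec |>
    mutate(estimate_kind = estimate_kind) |>
    select("preferred_term", "estimate_kind", "estimate", "p_value", "fdr_p",
           "n_event_a", "n_event_b", "n_a", "n_b", "labeled") |>
    arrange(.data$p_value, .data$preferred_term)
}
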