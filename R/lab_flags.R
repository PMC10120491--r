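#' Construct a CTC-style grading rule
#'
#' Four strictly monotone thresholds for grades 1–4, expressed as multiples
#' of the subject's own ULN (`direction = "high"`) or LLN
#' (`direction = "low"`), or as absolute values (`mode = "absolute"`).
#' Grade thresholds are configuration data: the defaults shipped with the
#' package ([defaultGradingRules()]) are illustrative, not authoritative.
#'
#' @param param_code Laboratory parameter code the rule applies to.
#' @param direction `"high"` or `"low"`.
#' @param thresholds Numeric length-4; strictly increasing for `"high"`,
#'   strictly decreasing for `"low"`.
#' @param mode `"multiple"` (of the limit) or `"absolute"`.
#' @return A `grading_rule` object.
#' @export
gradingRule <- function(param_code, direction = c("high", "low"),
                        thresholds, mode = c("multiple", "absolute")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  stopifnot(length(thresholds) == 4)
  d <- diff(thresholds)
  if (direction == "high" && !all(d > 0)) {
    stop("thresholds must be strictly increasing for direction 'high'", call. = FALSE)
  }
  if (direction == "low" && !all(d < 0)) {
    stop("thresholds must be strictly decreasing for direction 'low'", call. = FALSE)
  }
  structure(list(param_code = param_code, direction = direction,
                 thresholds = as.numeric(thresholds), mode = mode),
            class = "grading_rule")
}

#' Illustrative default grading rules for the fixture parameters
#'
#' Editable configuration with plausible shapes for a creatine-kinase-like
#' and a cholesterol-like parameter. These defaults are explicitly
#' non-authoritative placeholders: real reviews must load the
#' protocol-specified CTCAE thresholds.
#' @return Named list of [gradingRule()] objects.
#' @export
defaultGradingRules <- function() {
  list(
    CK   = gradingRule("CK", "high", c(1.0, 2.5, 5.0, 10.0)),
    CHOL = gradingRule("CHOL", "high", c(1.0, 1.25, 1.6, 2.0))
  )
}

#' Flag a laboratory value against its own limits of normal
#'
#' Vectorized. `"low"` iff value < LLN, `"high"` iff value > ULN (strict
#' inequalities: a value exactly at a limit is normal), `"normal"` when
#' both limits are present and neither bound is crossed, `"unknown"` when
#' the missing limit leaves the status undecidable (e.g. ULN missing and
#' the value is not below LLN).
#'
#' @param value,lln,uln Numeric vectors (limits may be `NA`).
#' @return Character vector in `{"low","normal","high","unknown"}`.
#' @export
flagAbnormal <- function(value, lln, uln) {
  n <- max(length(value), length(lln), length(uln))
  value <- rep_len(value, n); lln <- rep_len(lln, n); uln <- rep_len(uln, n)
  out <- rep("unknown", n)
  out[!is.na(lln) & !is.na(value) & value < lln] <- "low"
  out[!is.na(uln) & !is.na(value) & value > uln] <- "high"
  decidable_normal <- !is.na(value) & !is.na(lln) & !is.na(uln) &
    value >= lln & value <= uln
  out[decidable_normal] <- "normal"
  out[is.na(value)] <- "unknown"
  out
}

#' CTC-style grade of a laboratory value
#'
#' Highest grade whose threshold is exceeded (strict `>` for direction
#' high, strict `<` for low); 0 when none. Monotone in the value for fixed
#' limits. Returns `NA` when the required limit is missing in
#' multiple-of-limit mode.
#'
#' @param value Numeric vector of measured values.
#' @param lln,uln Limits of normal (recycled).
#' @param rule A [gradingRule()].
#' @return Integer vector of grades 0–4 (`NA` where undetermined).
#' @export
ctcGrade <- function(value, lln, uln, rule) {
  stopifnot(inherits(rule, "grading_rule"))
  n <- max(length(value), length(lln), length(uln))
  value <- rep_len(value, n); lln <- rep_len(lln, n); uln <- rep_len(uln, n)
  ref <- if (rule$mode == "absolute") rep(1, n)
         else if (rule$direction == "high") uln else lln
  out <- integer(n)
  for (g in 1:4) {
    cut <- rule$thresholds[g] * ref
    hit <- if (rule$direction == "high") value > cut else value < cut
    out[hit %in% TRUE] <- g
  }
  out[is.na(value) | is.na(ref)] <- NA_integer_
  out
}

# Linear-interpolation quantiles (the common type-7 default) via
# stats::quantile; kept in one place so the box-plot rule is stated once.
.box5 <- function(x) {
  q <- unname(stats::quantile(x, c(.25, .5, .75), type = 7, names = FALSE))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x[x >= lo_fence & x <= hi_fence]
  list(q1 = q[1], median = q[2], q3 = q[3],
       whisker_lo = min(inside), whisker_hi = max(inside),
       outliers = sort(x[x < lo_fence | x > hi_fence]))
}

#' Per-visit box-whisker statistics for one laboratory parameter
#'
#' Per arm x scheduled visit: n (subjects with a non-missing value),
#' quartiles by linear interpolation between order statistics, whiskers at
#' the last data point within 1.5 times the interquartile range beyond the
#' quartiles, and the values beyond the whiskers listed as outliers.
#' Visits with n = 0 are kept (with missing statistics) so the per-visit
#' n annotation row stays complete. With `log_scale = TRUE` the statistics
#' are still computed on the raw values — quartiles are order statistics,
#' invariant under the monotone log transform — and only the display axis
#' changes.
#'
#' @param trial A `trial_data`.
#' @param param_code Laboratory parameter.
#' @param log_scale Annotate for logarithmic display.
#' @return Tibble with one row per arm x visit; `outlier_values` is a
#'   list-column.
#' @export
visitBoxStats <- function(trial, param_code, log_scale = FALSE) {
  d <- trial$labs |> filter(.data$param_code == !!param_code)
  if (!nrow(d)) stop("parameter '", param_code, "' not present", call. = FALSE)
  visits <- d |> distinct(.data$visit_index, .data$day) |> arrange(.data$visit_index)
  grid <- tidyr::expand_grid(arm_label = trial$arms,
                             visit_index = visits$visit_index)
  subj_arm <- trial$subjects |> select("subject_id", "arm")
  d <- d |> inner_join(subj_arm, by = "subject_id") |> filter(!is.na(.data$value))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    x <- d$value[d$arm == grid$arm_label[i] & d$visit_index == grid$visit_index[i]]
    if (!length(x)) {
      tibble(param_code = param_code, visit_index = grid$visit_index[i],
             arm = grid$arm_label[i], n = 0L, q1 = NA_real_, median = NA_real_,
             q3 = NA_real_, whisker_lo = NA_real_, whisker_hi = NA_real_,
             outlier_values = list(numeric(0)))
    } else {
      b <- .box5(x)
      tibble(param_code = param_code, visit_index = grid$visit_index[i],
             arm = grid$arm_label[i], n = length(x), q1 = b$q1,
             median = b$median, q3 = b$q3, whisker_lo = b$whisker_lo,
             whisker_hi = b$whisker_hi, outlier_values = list(b$outliers))
    }
  })
  res <- bind_rows(out) |>
    left_join(visits, by = "visit_index") |>
    arrange(.data$visit_index, match(.data$arm, trial$arms))
  attr(res, "log_scale") <- log_scale
  res
}

#' Prevalence of abnormal values per arm and visit
#'
#' Denominators are subjects with at least one non-missing value at the
#' visit that is flaggable for the requested side (the relevant limit
#' present); a subject is abnormal if any of their values at the visit
#' crosses the limit. `side = "either"` counts a subject once however many
#' sides are crossed.
#'
#' @param trial A `trial_data`.
#' @param param_code Laboratory parameter.
#' @param side `"low"`, `"high"`, or `"either"`.
#' @return Tibble: arm, visit_index, day, n, n_abnormal, percent.
#' @export
abnormalPrevalence <- function(trial, param_code,
                               side = c("high", "low", "either")) {
  side <- match.arg(side)
  d <- trial$labs |> filter(.data$param_code == !!param_code, !is.na(.data$value))
  if (!nrow(d) && !nrow(trial$labs |> filter(.data$param_code == !!param_code))) {
    stop("parameter '", param_code, "' not present", call. = FALSE)
  }
  d <- d |>
    inner_join(trial$subjects |> select("subject_id", "arm"), by = "subject_id") |>
    mutate(
      flaggable = switch(side,
        high = !is.na(.data$uln),
        low = !is.na(.data$lln),
        either = !is.na(.data$uln) & !is.na(.data$lln)),
      flag = flagAbnormal(.data$value, .data$lln, .data$uln),
      abnormal = switch(side,
        high = .data$flag == "high",
        low = .data$flag == "low",
        either = .data$flag %in% c("low", "high")) & .data$flaggable)
  visits <- d |> distinct(.data$visit_index, .data$day) |> arrange(.data$visit_index)
  per_subj <- d |>
    filter(.data$flaggable) |>
    group_by(.data$arm, .data$visit_index, .data$subject_id) |>
    summarise(abn = any(.data$abnormal), .groups = "drop")
  tidyr::expand_grid(arm = unique(trial$arms), visit_index = visits$visit_index) |>
    left_join(per_subj |>
                group_by(.data$arm, .data$visit_index) |>
                summarise(n = dplyr::n(), n_abnormal = sum(.data$abn),
                          .groups = "drop"),
              by = c("arm", "visit_index")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L),
           n_abnormal = tidyr::replace_na(.data$n_abnormal, 0L),
           percent = ifelse(.data$n > 0, 100 * .data$n_abnormal / .data$n, NA_real_)) |>
    left_join(visits, by = "visit_index") |>
    select("arm", "visit_index", "day", "n", "n_abnormal", "percent") |>
    arrange(.data$visit_index, match(.data$arm, trial$arms))
}

#' Select subjects whose trajectories warrant individual inspection
#'
#' A subject is selected iff any post-baseline value strictly exceeds
#' `multiplier` times their own upper limit of normal, or — when a grading
#' rule is supplied — attains CTC grade `min_grade` or higher. Every
#' triggering measurement is recorded with its reason.
#'
#' @param trial A `trial_data`.
#' @param param_code Laboratory parameter.
#' @param multiplier Positive multiple of the subject's own ULN (default 3).
#' @param grade_rule Optional [gradingRule()].
#' @param min_grade Minimum grade to trigger (default 3).
#' @return Tibble of trigger measurements: subject_id, day, value, reason.
#' @export
selectOutlierSubjects <- function(trial, param_code, multiplier = 3,
                                  grade_rule = NULL, min_grade = 3L) {
  stopifnot(multiplier > 0)
  d <- trial$labs |>
    filter(.data$param_code == !!param_code, !(.data$baseline_flag %in% TRUE),
           !is.na(.data$value))
  d$over_mult <- !is.na(d$uln) & d$value > multiplier * d$uln
  d$grade <- if (!is.null(grade_rule)) ctcGrade(d$value, d$lln, d$uln, grade_rule)
             else NA_integer_
  d$over_grade <- !is.null(grade_rule) & !is.na(d$grade) & d$grade >= min_grade
  trig <- d |> filter(.data$over_mult | .data$over_grade)
  trig |>
    mutate(reason = dplyr::case_when(
      .data$over_mult & .data$over_grade ~
        sprintf("> %gxULN; grade %d", multiplier, .data$grade),
      .data$over_mult ~ sprintf("> %gxULN", multiplier),
      TRUE ~ sprintf("grade %d", .data$grade))) |>
    select("subject_id", "param_code", "day", "value", "uln", "reason") |>
    arrange(.data$subject_id, .data$day)
}

#' Baseline vs post-baseline value pairs for the shift display
#'
#' Eligible subjects have a baseline value (the baseline-flagged record,
#' else the last non-missing value on/before their first dose day) and at
#' least one post-baseline value. The post-baseline value is the worst
#' case (maximum for direction-high parameters, minimum for low) or the
#' latest value, per `post_rule`. Exactly one pair per eligible subject.
#'
#' @param trial A `trial_data`.
#' @param param_code Laboratory parameter.
#' @param post_rule `"worst_case"` (default) or `"last_value"`.
#' @param direction Worst-case direction, `"high"` or `"low"`.
#' @return Tibble of shift pairs with abnormality status at both ends.
#' @export
shiftPairs <- function(trial, param_code,
                       post_rule = c("worst_case", "last_value"),
                       direction = c("high", "low")) {
  post_rule <- match.arg(post_rule)
  direction <- match.arg(direction)
  d <- trial$labs |>
    filter(.data$param_code == !!param_code, !is.na(.data$value)) |>
    inner_join(trial$subjects |> select("subject_id", "first_dose_day"),
               by = "subject_id")
  base <- d |>
    group_by(.data$subject_id) |>
    group_modify(function(g, key) {
      flagged <- g |> filter(.data$baseline_flag %in% TRUE)
      if (nrow(flagged)) return(flagged[1, ])
      pre <- g |> filter(!is.na(.data$first_dose_day),
                         .data$day <= .data$first_dose_day)
      if (!nrow(pre)) return(g[0, ])
      pre[which.max(pre$day), ]
    }) |>
    ungroup() |>
    select("subject_id", baseline_value = "value",
           base_lln = "lln", base_uln = "uln", base_day = "day")
  post <- d |>
    anti_join(d |> filter(.data$baseline_flag %in% TRUE) |>
                select("subject_id", "day"),
              by = c("subject_id", "day")) |>
    inner_join(base |> select("subject_id", "base_day"), by = "subject_id") |>
    filter(.data$day > .data$base_day) |>
    group_by(.data$subject_id) |>
    group_modify(function(g, key) {
      i <- switch(post_rule,
        worst_case = if (direction == "high") which.max(g$value) else which.min(g$value),
        last_value = which.max(g$day))
      g[i, ]
    }) |>
    ungroup() |>
    select("subject_id", post_value = "value", post_lln = "lln",
           post_uln = "uln", post_day = "day")
  inner_join(base, post, by = "subject_id") |>
    mutate(param_code = !!param_code,
           baseline_abnormal = flagAbnormal(.data$baseline_value,
                                            .data$base_lln, .data$base_uln),
           post_abnormal = flagAbnormal(.data$post_value, .data$post_lln,
                                        .data$post_uln)) |>
    select("subject_id", "param_code", "baseline_value", "post_value",
           "baseline_abnormal", "post_abnormal") |>
    arrange(.data$subject_id)
}

#' Classic shift table reconstructed from shift pairs
#'
#' Cross-tabulates baseline vs post-baseline abnormality status; the cell
#' counts sum to the number of eligible subjects, so the scatter display
#' and the table are provably consistent.
#' @param pairs Output of [shiftPairs()].
#' @return Tibble: baseline_abnormal x post_abnormal with counts.
#' @export
shiftTable <- function(pairs) {
  lev <- c("low", "normal", "high", "unknown")
  tb <- table(factor(pairs$baseline_abnormal, lev),
              factor(pairs$post_abnormal, lev))
  as_tibble(as.data.frame(tb, stringsAsFactors = FALSE)) |>
    rename(baseline_abnormal = "Var1", post_abnormal = "Var2", n = "Freq")
}
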