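#' Read a synthetic-trial configuration from YAML
#'
#' The YAML mirrors [synthConfig()]'s arguments; `ae_models` and
#' `lab_models` are lists of mappings, with per-arm values given as
#' mappings from arm label to number.
#' @param path YAML file.
#' @return A `synth_config`.
#' @export
readSynthConfig <- function(path) {
  y <- yaml::read_yaml(path)
  num_by_arm <- function(x) if (is.list(x)) unlist(x) else x
  ae <- lapply(y$ae_models %||% list(), function(m) {
    m$hazard_per_year <- num_by_arm(m$hazard_per_year)
    m$grade_probs <- as.numeric(unlist(m$grade_probs))
    m
  })
  lb <- lapply(y$lab_models %||% list(), function(m) {
    m$arm_drift <- num_by_arm(m$arm_drift)
    m$visit_schedule <- as.integer(unlist(m$visit_schedule))
    m
  })
  args <- y[setdiff(names(y), c("ae_models", "lab_models", "sex_female_prob"))]
  args$ae_models <- ae
  args$lab_models <- lb
  if (!is.null(y$sex_female_prob)) args$sex_female_prob <- num_by_arm(y$sex_female_prob)
  do.call(synthConfig, args)
}

#' Read a report configuration from YAML
#'
#' The YAML mirrors [reportConfig()]'s arguments; `comparisons` is a list
#' of two-element lists `[arm_a, arm_b]`, `grading_rules` a list of
#' mappings with `param_code`, `direction`, `thresholds`.
#' @param path YAML file.
#' @return A `report_config`.
#' @export
readReportConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  args$comparisons <- lapply(y$comparisons, function(x) unlist(x))
  if (!is.null(y$grading_rules)) {
    args$grading_rules <- stats::setNames(
      lapply(y$grading_rules, function(r)
        gradingRule(r$param_code, r$direction %||% "high",
                    as.numeric(unlist(r$thresholds)), r$mode %||% "multiple")),
      vapply(y$grading_rules, `[[`, character(1), "param_code"))
  }
  if (!is.null(y$relabel_arms)) args$relabel_arms <- unlist(y$relabel_arms)
  do.call(reportConfig, args)
}
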