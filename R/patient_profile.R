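#' Select the subjects of special interest for individual profiles
#'
#' The union of subjects with at least one serious adverse event, at least
#' one adverse event of CTC grade 3 or higher, and at least one laboratory
#' value grading 3 or higher under the supplied rules. Each selected id
#' carries its reason list. Adding records can only add subjects, never
#' remove them (selection is monotone).
#'
#' @param trial A validated `trial_data`.
#' @param grading_rules Named list of [gradingRule()] objects (names are
#'   parameter codes), e.g. [defaultGradingRules()].
#' @param min_grade Minimum triggering grade (default 3).
#' @return Tibble: `subject_id`, `reasons` (list-column of character).
#' @export
selectProfileSubjects <- function(trial, grading_rules = defaultGradingRules(),
                                  min_grade = 3L) {
  ae <- trial$adverse_events
  sae <- unique(ae$subject_id[ae$serious_flag %in% TRUE])
  g3ae <- unique(ae$subject_id[!is.na(ae$ctc_grade) & ae$ctc_grade >= min_grade])
  g3lab <- character(0)
  for (pc in intersect(names(grading_rules), unique(trial$labs$param_code))) {
    d <- trial$labs |> filter(.data$param_code == pc, !is.na(.data$value))
    g <- ctcGrade(d$value, d$lln, d$uln, grading_rules[[pc]])
    g3lab <- c(g3lab, d$subject_id[!is.na(g) & g >= min_grade])
  }
  g3lab <- unique(g3lab)
  ids <- sort(unique(c(sae, g3ae, g3lab)))
  tibble(
    subject_id = ids,
    reasons = lapply(ids, function(id) {
      r <- character(0)
      if (id %in% sae) r <- c(r, "serious adverse event")
      if (id %in% g3ae) r <- c(r, sprintf("adverse event grade >= %d", min_grade))
      if (id %in% g3lab) r <- c(r, sprintf("laboratory value grade >= %d", min_grade))
      r
    }))
}

.truncate_list <- function(tb, n_max = 15L, order_col = "start_day") {
  if (nrow(tb) <= n_max) return(list(shown = tb, n_more = 0L))
  tb <- tb[order(-ifelse(is.na(tb[[order_col]]), -Inf, tb[[order_col]])), ]
  list(shown = tb[seq_len(n_max), ], n_more = nrow(tb) - n_max)
}

#' Build a one-page clinical profile for one subject
#'
#' Combines demographics, medical history, concomitant medication,
#' exposure, adverse events, and laboratory values for the subject into
#' one structure, plus an ordered key-event timeline. The lab block is
#' limited to parameters with at least one abnormal value for this subject
#' (baseline, worst value with its grade, and last value are shown).
#' History and medication lists truncate to the most recent `n_max`
#' entries with an explicit "+k more" count so the page stays one page.
#'
#' @param trial A validated `trial_data`.
#' @param subject_id Subject to profile.
#' @param grading_rules Named list of [gradingRule()] objects.
#' @param n_max List-truncation limit (default 15).
#' @return A `patient_profile` object.
#' @export
buildProfile <- function(trial, subject_id,
                         grading_rules = defaultGradingRules(), n_max = 15L) {
  if (!subject_id %in% trial$subjects$subject_id) {
    stop("unknown subject: ", subject_id, call. = FALSE)
  }
  demo <- trial$subjects |> filter(.data$subject_id == !!subject_id)
  mh <- .truncate_list(trial$medhistory |>
                         filter(.data$subject_id == !!subject_id), n_max)
  cm <- .truncate_list(trial$conmeds |>
                         filter(.data$subject_id == !!subject_id), n_max)
  expo <- trial$exposure |> filter(.data$subject_id == !!subject_id)
  aes_ <- trial$adverse_events |>
    filter(.data$subject_id == !!subject_id) |>
    arrange(.data$onset_day, .data$preferred_term)
  labs_s <- trial$labs |>
    filter(.data$subject_id == !!subject_id, !is.na(.data$value)) |>
    mutate(flag = flagAbnormal(.data$value, .data$lln, .data$uln))

  abnormal_params <- labs_s |>
    filter(.data$flag %in% c("low", "high")) |>
    distinct(.data$param_code) |>
    pull()
  lab_block <- bind_rows(lapply(sort(abnormal_params), function(pc) {
    g <- labs_s |> filter(.data$param_code == pc)
    rule <- grading_rules[[pc]]
    g$grade <- if (!is.null(rule)) ctcGrade(g$value, g$lln, g$uln, rule)
               else NA_integer_
    base <- g$value[g$baseline_flag %in% TRUE][1]
    worst_i <- if (all(is.na(g$grade))) which.max(g$value)
               else which.max(ifelse(is.na(g$grade), -1L, g$grade) * 1000 +
                                g$value / max(g$value))
    last_i <- which.max(g$day)
    tibble(param_code = pc, baseline = base, worst_value = g$value[worst_i],
           worst_day = g$day[worst_i], worst_grade = g$grade[worst_i],
           last_value = g$value[last_i], last_day = g$day[last_i],
           unit = g$unit[1])
  }))
  if (!nrow(lab_block)) {
    lab_block <- tibble(param_code = character(), baseline = numeric(),
                        worst_value = numeric(), worst_day = integer(),
                        worst_grade = integer(), last_value = numeric(),
                        last_day = integer(), unit = character())
  }

  flagged_labs <- labs_s |> filter(.data$flag %in% c("low", "high"))
  cutoff <- trial$cutoff_day
  timeline <- bind_rows(
    if (nrow(expo)) tibble(
      day = expo$start_day, end_day = expo$end_day, track = "exposure",
      label = expo$dose_label %||% "treatment", severity = NA_integer_,
      ongoing = FALSE),
    if (nrow(aes_)) tibble(
      day = aes_$onset_day,
      end_day = ifelse(is.na(aes_$resolution_day), cutoff, aes_$resolution_day),
      track = "ae", label = aes_$preferred_term, severity = aes_$ctc_grade,
      ongoing = is.na(aes_$resolution_day)),
    if (nrow(cm$shown)) tibble(
      day = cm$shown$start_day,
      end_day = ifelse(is.na(cm$shown$end_day), cutoff, cm$shown$end_day),
      track = "conmed", label = cm$shown$term, severity = NA_integer_,
      ongoing = cm$shown$ongoing_flag %in% TRUE),
    if (nrow(flagged_labs)) tibble(
      day = flagged_labs$day, end_day = flagged_labs$day, track = "lab",
      label = paste0(flagged_labs$param_code, " ", flagged_labs$flag),
      severity = NA_integer_, ongoing = FALSE)
  )
  if (!is.null(timeline) && nrow(timeline)) {
    timeline <- arrange(timeline, .data$day, .data$track, .data$label)
  } else {
    timeline <- tibble(day = integer(), end_day = numeric(), track = character(),
                       label = character(), severity = integer(),
                       ongoing = logical())
  }
  structure(list(
    subject_id = subject_id, demographics = demo,
    medhistory = mh$shown, medhistory_more = mh$n_more,
    conmeds = cm$shown, conmeds_more = cm$n_more,
    exposure = expo, adverse_events = aes_, lab_block = lab_block,
    timeline = timeline, cutoff_day = cutoff
  ), class = "patient_profile")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat("<patient_profile>", x$subject_id, "|", nrow(x$adverse_events),
      "AEs |", nrow(x$lab_block), "flagged lab parameter(s) |",
      nrow(x$timeline), "timeline events\n")
  invisible(x)
}

#' Timeline figure for a patient profile
#' @param profile A `patient_profile`.
#' @return A `figure_spec` with the key-event timeline.
#' @export
profileTimelineFigure <- function(profile) {
  tl <- profile$timeline
  if (!nrow(tl)) {
    tl <- tibble(day = 1, end_day = 1, track = "exposure",
                 label = "(no events)", severity = NA_integer_,
                 ongoing = FALSE)
  }
  tracks <- c("exposure", "ae", "conmed", "lab")
  d <- tl |>
    mutate(track = factor(.data$track, levels = rev(tracks)),
           row = paste(.data$track, .data$label)) |>
    group_by(.data$track) |>
    mutate(offset = as.integer(factor(.data$label,
                                      levels = unique(.data$label)))) |>
    ungroup() |>
    mutate(ypos = as.integer(.data$track) + (.data$offset - 1) * 0.18)
  plot <- ggplot(d, aes(y = .data$ypos)) +
    geom_segment(aes(x = .data$day, xend = .data$end_day,
                     yend = .data$ypos, colour = .data$track),
                 linewidth = 2, lineend = "butt") +
    geom_point(data = d |> filter(.data$day == .data$end_day),
               aes(x = .data$day, colour = .data$track), size = 2) +
    geom_text(aes(x = .data$end_day, label = .data$label), hjust = -0.05,
              size = 2.5) +
    scale_y_continuous(breaks = seq_along(tracks),
                       labels = rev(tracks), limits = c(0.5, length(tracks) + 1)) +
    scale_colour_manual(values = c(exposure = "#0072B2", ae = "#D55E00",
                                   conmed = "#009E73", lab = "#CC79A7"),
                        guide = "none") +
    xlim(min(c(0, d$day)), max(c(d$end_day, profile$cutoff_day)) * 1.3) +
    labs(x = "Study day", y = NULL,
         title = paste("Key events:", profile$subject_id)) +
    theme_minimal(base_size = 9)
  newFigureSpec("profile_timeline", d, plot,
                paste0("Key events over time for subject ", profile$subject_id,
                       "; bars are intervals (adverse events open until the",
                       " data cut when unresolved), points are single-day",
                       " events."),
                meta = list(subject_id = profile$subject_id))
}

# Plain-text rendering of a profile (used for the report page and the
# standalone file; every printed value comes verbatim from the tables).
profileText <- function(profile) {
  d <- profile$demographics
  fmt_int <- function(x) ifelse(is.na(x), "?", format(x))
  lines <- c(
    paste0("PATIENT PROFILE  ", profile$subject_id),
    paste0("Arm: ", d$arm, " | Age: ", d$age, " | Sex: ", d$sex,
           " | Race: ", d$race, " | Country: ", d$country),
    paste0("Dosed day ", fmt_int(d$first_dose_day), " to ",
           fmt_int(d$last_dose_day),
           if (isTRUE(d$discontinued_flag)) " (discontinued)" else ""),
    "", "Current treatment (exposure):")
  if (nrow(profile$exposure)) {
    lines <- c(lines, sprintf("  day %s-%s: %s", profile$exposure$start_day,
                              profile$exposure$end_day,
                              profile$exposure$dose_label))
  } else lines <- c(lines, "  (never dosed)")
  lines <- c(lines, "", "Medical history:")
  lines <- c(lines, if (nrow(profile$medhistory)) {
    sprintf("  %s (from day %s)", profile$medhistory$term,
            fmt_int(profile$medhistory$start_day))
  } else "  (none recorded)")
  if (profile$medhistory_more > 0) {
    lines <- c(lines, sprintf("  +%d more", profile$medhistory_more))
  }
  lines <- c(lines, "", "Concomitant medication:")
  lines <- c(lines, if (nrow(profile$conmeds)) {
    sprintf("  %s (day %s-%s%s)", profile$conmeds$term,
            fmt_int(profile$conmeds$start_day), fmt_int(profile$conmeds$end_day),
            ifelse(profile$conmeds$ongoing_flag %in% TRUE, ", ongoing", ""))
  } else "  (none recorded)")
  if (profile$conmeds_more > 0) {
    lines <- c(lines, sprintf("  +%d more", profile$conmeds_more))
  }
  lines <- c(lines, "", "Adverse events:")
  ae <- profile$adverse_events
  lines <- c(lines, if (nrow(ae)) {
    sprintf("  day %s%s: %s (grade %s%s%s)", ae$onset_day,
            ifelse(is.na(ae$resolution_day), ", ongoing",
                   paste0("-", ae$resolution_day)),
            ae$preferred_term, ae$ctc_grade,
            ifelse(ae$serious_flag %in% TRUE, ", serious", ""),
            ifelse(ae$related_flag %in% TRUE, ", related", ""))
  } else "  (none)")
  lines <- c(lines, "", "Laboratory values (parameters with an abnormal value):")
  lb <- profile$lab_block
  lines <- c(lines, if (nrow(lb)) {
    sprintf("  %s: baseline %s, worst %s on day %s (grade %s), last %s on day %s [%s]",
            lb$param_code, format(lb$baseline), format(lb$worst_value),
            lb$worst_day, ifelse(is.na(lb$worst_grade), "-", lb$worst_grade),
            format(lb$last_value), lb$last_day, lb$unit)
  } else "  (no abnormal values)")
  lines
}

#' Write a standalone one-page profile file
#'
#' Emits the profile as a single-page PDF (text blocks plus the key-event
#' timeline) and its timeline backing data as CSV.
#' @param profile A `patient_profile`.
#' @param path_base Output path without extension.
#' @return Paths written, invisibly.
#' @export
renderProfile <- function(profile, path_base) {
  pdf_path <- paste0(path_base, ".pdf")
  grDevices::pdf(pdf_path, width = 8.27, height = 11.69, onefile = TRUE)
  on.exit(grDevices::dev.off(), add = TRUE)
  .draw_profile_page(profile)
  csv_path <- paste0(path_base, ".csv")
  readr::write_csv(profile$timeline, csv_path, na = "", progress = FALSE)
  invisible(c(pdf = pdf_path, csv = csv_path))
}

# Draw one profile page on the current graphics device.
.draw_profile_page <- function(profile, page_label = NULL) {
  grid::grid.newpage()
  txt <- profileText(profile)
  grid::pushViewport(grid::viewport(layout = grid::grid.layout(
    2, 1, heights = grid::unit(c(0.62, 0.38), "npc"))))
  grid::pushViewport(grid::viewport(layout.pos.row = 1))
  grid::grid.text(paste(txt, collapse = "\n"),
                  x = 0.03, y = 0.97, just = c("left", "top"),
                  gp = grid::gpar(fontfamily = "mono", cex = 0.62))
  grid::popViewport()
  grid::pushViewport(grid::viewport(layout.pos.row = 2))
  fig <- profileTimelineFigure(profile)
  print(fig$plot, newpage = FALSE)
  grid::popViewport(2)
  if (!is.null(page_label)) {
    grid::grid.text(page_label, x = 0.5, y = 0.015,
                    gp = grid::gpar(cex = 0.7))
  }
  invisible(NULL)
}
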