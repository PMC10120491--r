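#' Declarative description of a DMC report
#'
#' Captures everything [buildReport()] needs: front-matter texts (protocol
#' synopsis, amendments, previous recommendations, previous imbalances),
#' the arm-pair comparisons, display variables and parameters, section
#' toggles, the volcano label rule, and whether the adverse-event overview
#' is exposure-adjusted.
#'
#' @param comparisons List of length-2 character vectors `c(arm_a, arm_b)`
#'   (`arm_b` the reference of each comparison).
#' @param front_matter List with elements `protocol_synopsis`,
#'   `amendments`, `previous_recommendations`, `previous_imbalances`
#'   (character vectors; all optional).
#' @param demographics_variables Subject columns for the baseline figure.
#' @param aesi_terms Preferred terms prespecified as adverse events of
#'   special interest.
#' @param lab_params List of per-parameter display options
#'   `list(param_code =, log_scale = FALSE, side = "high",
#'   spaghetti_multiplier = 3)`, or a character vector of codes.
#' @param vitals_params Same schema as `lab_params`, applied identically.
#' @param grading_rules Named list of [gradingRule()] objects.
#' @param label_rule Volcano label rule (see [volcanoStats()]).
#' @param exposure_adjusted Exposure-adjust the AE overview dot plot.
#' @param include_vitals,include_shift_scatter,include_appendix Section
#'   toggles.
#' @param efficacy_text Optional character vector rendered verbatim in a
#'   placeholder efficacy section (no efficacy statistics are computed).
#' @param relabel_arms Optional named character vector (`old = new`) for
#'   semi-blinded output; default off — arm labels appear verbatim.
#' @param formats Output formats, subset of `c("pdf", "html")`.
#' @return A `report_config` object.
#' @export
reportConfig <- function(comparisons,
                         front_matter = list(),
                         demographics_variables = c("age", "sex"),
                         aesi_terms = character(),
                         lab_params = list(),
                         vitals_params = list(),
                         grading_rules = defaultGradingRules(),
                         label_rule = list(p_cutoff = 0.05),
                         exposure_adjusted = FALSE,
                         include_vitals = TRUE,
                         include_shift_scatter = TRUE,
                         include_appendix = TRUE,
                         efficacy_text = NULL,
                         relabel_arms = NULL,
                         formats = c("pdf", "html")) {
  norm_params <- function(p) {
    if (is.character(p)) p <- lapply(p, function(x) list(param_code = x))
    lapply(p, function(x) {
      utils::modifyList(list(log_scale = FALSE, side = "high",
                             spaghetti_multiplier = 3), x)
    })
  }
  structure(list(
    comparisons = comparisons,
    front_matter = utils::modifyList(
      list(protocol_synopsis = "(no protocol synopsis supplied)",
           amendments = character(), previous_recommendations = character(),
           previous_imbalances = character()),
      front_matter),
    demographics_variables = demographics_variables,
    aesi_terms = aesi_terms,
    lab_params = norm_params(lab_params),
    vitals_params = norm_params(vitals_params),
    grading_rules = grading_rules, label_rule = label_rule,
    exposure_adjusted = exposure_adjusted,
    include_vitals = include_vitals,
    include_shift_scatter = include_shift_scatter,
    include_appendix = include_appendix,
    efficacy_text = efficacy_text, relabel_arms = relabel_arms,
    formats = match.arg(formats, several.ok = TRUE)
  ), class = "report_config")
}

# ---- intermediate representation ------------------------------------------

.block <- function(type, title, content = NULL, spec = NULL, note = NULL) {
  list(type = type, title = title, content = content, spec = spec, note = note)
}

.section <- function(id, title, blocks) {
  list(id = id, title = title, blocks = blocks)
}

.tbl_block <- function(title, tb, empty_text = "No records.") {
  if (is.null(tb) || !nrow(tb)) .block("text", title, empty_text)
  else .block("table", title, tb)
}

# Lab/vitals display blocks for one parameter set; shared by the labs and
# vitals sections ("the same operators applied to the vitals table").
.param_blocks <- function(trial, params, config, fig_store) {
  blocks <- list()
  for (p in params) {
    pc <- p$param_code
    if (!pc %in% trial$labs$param_code) {
      blocks[[length(blocks) + 1L]] <-
        .block("text", paste0(pc, ": not in data"),
               paste0("Parameter '", pc, "' has no records; nothing to display."))
      next
    }
    bs <- visitBoxStats(trial, pc, log_scale = isTRUE(p$log_scale))
    blocks[[length(blocks) + 1L]] <- .block(
      "figure", paste0(pc, ": distribution over time"),
      spec = figLabBoxes(bs, reference_arm = trial$reference_arm))
    prev <- abnormalPrevalence(trial, pc, side = p$side)
    blocks[[length(blocks) + 1L]] <- .block(
      "figure", paste0(pc, ": abnormal values over time"),
      spec = figAbnormalPrevalence(prev, side = p$side,
                                   reference_arm = trial$reference_arm))
    sel <- selectOutlierSubjects(trial, pc,
                                 multiplier = p$spaghetti_multiplier,
                                 grade_rule = config$grading_rules[[pc]])
    ids <- unique(sel$subject_id)
    blocks[[length(blocks) + 1L]] <- .block(
      "figure", paste0(pc, ": individual trajectories"),
      spec = figSpaghetti(trial, pc, selected = ids, show_limits = TRUE),
      note = if (!length(ids)) "No subject crossed the flagging thresholds."
             else paste0(length(ids), " subject(s) flagged: ",
                         paste(ids, collapse = ", ")))
    if (isTRUE(config$include_shift_scatter)) {
      pairs <- shiftPairs(trial, pc)
      if (nrow(pairs)) {
        lims <- trial$labs |> filter(.data$param_code == pc)
        common <- function(v) {
          u <- unique(stats::na.omit(v))
          if (length(u) == 1) u else NA_real_
        }
        blocks[[length(blocks) + 1L]] <- .block(
          "figure", paste0(pc, ": baseline vs post-baseline shift"),
          spec = figShiftScatter(pairs, lln = common(lims$lln),
                                 uln = common(lims$uln)))
      } else {
        blocks[[length(blocks) + 1L]] <- .block(
          "text", paste0(pc, ": baseline vs post-baseline shift"),
          "No subject has both a baseline and a post-baseline value.")
      }
    }
  }
  blocks
}

# Assemble the full intermediate representation (sections + blocks).
.build_ir <- function(trial, config, change_summary = NULL) {
  for (cmp in config$comparisons) {
    missing <- setdiff(cmp, trial$arms)
    if (length(missing)) {
      stop("config error: comparison references unknown arm(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(config$relabel_arms)) {
    map <- config$relabel_arms
    rl <- function(x) ifelse(x %in% names(map), unname(map[x]), x)
    trial$subjects$arm <- rl(trial$subjects$arm)
    trial$exposure$dose_label <- rl(trial$exposure$dose_label)
    trial$arms <- rl(trial$arms)
    trial$reference_arm <- rl(trial$reference_arm)
    config$comparisons <- lapply(config$comparisons, rl)
  }
  sections <- list()

  ## (i) front matter
  fm <- config$front_matter
  fm_blocks <- list(
    .block("text", "Protocol synopsis", fm$protocol_synopsis),
    .block("text", "New amendments",
           if (length(fm$amendments)) fm$amendments else "No new amendments."),
    .block("text", "Previous DMC recommendations",
           if (length(fm$previous_recommendations)) fm$previous_recommendations
           else "No previous recommendations on file."),
    .block("text", "Major safety imbalances found in the previous DMC review",
           if (length(fm$previous_imbalances)) fm$previous_imbalances
           else "None recorded."))
  if (!is.null(change_summary)) {
    fm_blocks[[length(fm_blocks) + 1L]] <-
      .block("text", "What has changed since the previous DMC",
             .format_changes(change_summary))
  }
  sections[[length(sections) + 1L]] <-
    .section("front_matter", "Front matter", fm_blocks)

  ## (ii) baseline
  top_terms <- function(tb, n = 10) {
    if (!nrow(tb)) return(tb[0, ])
    tb |> count(.data$term, sort = TRUE, name = "n_subjects") |>
      slice_head(n = n)
  }
  sections[[length(sections) + 1L]] <- .section(
    "baseline", "Baseline comparison", list(
      .block("figure", "Demographics",
             spec = figDemographics(trial, config$demographics_variables)),
      .tbl_block("Most frequent medical history terms (selected subset)",
                 top_terms(trial$medhistory),
                 "No medical history recorded."),
      .tbl_block("Most frequent concomitant medications (selected subset)",
                 top_terms(trial$conmeds),
                 "No concomitant medication recorded.")))

  ## (iii) adverse events
  ae_blocks <- list()
  inc <- aeIncidence(trial, group_by = "preferred_term")
  if (!nrow(inc)) {
    ae_blocks[[1]] <- .block("text", "Adverse event overview",
                             "No adverse events reported at this data cut.")
  } else {
    first_cmp <- config$comparisons[[1]]
    metric <- if (config$exposure_adjusted) "rate_per_100py" else "percent"
    ord <- orderTerms(inc, by_arm = first_cmp[1], metric = metric)
    ae_blocks[[length(ae_blocks) + 1L]] <- .block(
      "figure", "Adverse event overview",
      spec = figAeDotplot(inc, ord, exposure_adjusted = config$exposure_adjusted,
                          reference_arm = trial$reference_arm))
    for (cmp in config$comparisons) {
      vs <- volcanoStats(trial, cmp[1], cmp[2], label_rule = config$label_rule)
      ttl <- paste0("Volcano plot: ", cmp[1], " vs ", cmp[2])
      if (nrow(vs)) {
        ae_blocks[[length(ae_blocks) + 1L]] <-
          .block("figure", ttl, spec = figVolcano(vs))
      } else {
        ae_blocks[[length(ae_blocks) + 1L]] <-
          .block("text", ttl, "No term with events in either arm.")
      }
    }
  }
  aesi_inc <- if (length(config$aesi_terms)) {
    aeIncidence(trial, filters = function(d)
      d$preferred_term %in% config$aesi_terms | d$aesi_flag %in% TRUE)
  } else aeIncidence(trial, filters = list(aesi_flag = TRUE))
  ae_blocks[[length(ae_blocks) + 1L]] <- .tbl_block(
    "Adverse events of special interest", aesi_inc,
    "No adverse events of special interest reported.")
  g3 <- trial$adverse_events |>
    filter(!is.na(.data$ctc_grade), .data$ctc_grade >= 3) |>
    inner_join(trial$subjects |> select("subject_id", "arm"),
               by = "subject_id") |>
    select("subject_id", "arm", "preferred_term", "ctc_grade", "onset_day",
           "serious_flag") |>
    arrange(.data$subject_id, .data$onset_day)
  ae_blocks[[length(ae_blocks) + 1L]] <- .tbl_block(
    "Subjects with CTC grade >= 3 adverse events", g3,
    "No grade >= 3 adverse events reported.")
  sections[[length(sections) + 1L]] <-
    .section("adverse_events", "Adverse events", ae_blocks)

  ## (iv) laboratory
  lab_blocks <- .param_blocks(trial, config$lab_params, config, NULL)
  if (!length(lab_blocks)) {
    lab_blocks <- list(.block("text", "Laboratory parameters",
                              "No laboratory parameters configured."))
  }
  sections[[length(sections) + 1L]] <-
    .section("laboratory", "Laboratory", lab_blocks)

  ## (v) vitals
  if (isTRUE(config$include_vitals)) {
    vt_blocks <- .param_blocks(trial, config$vitals_params, config, NULL)
    if (!length(vt_blocks)) {
      vt_blocks <- list(.block("text", "Vital signs",
                               "No vital-sign parameters configured."))
    }
    sections[[length(sections) + 1L]] <-
      .section("vitals", "Vital signs", vt_blocks)
  }

  ## efficacy placeholder
  if (!is.null(config$efficacy_text)) {
    sections[[length(sections) + 1L]] <- .section(
      "efficacy", "Efficacy (placeholder)", list(
        .block("text", "Efficacy information (supplied verbatim)",
               c(config$efficacy_text, "",
                 paste("NOTE: no efficacy statistics are computed here;",
                       "the handling of interim efficacy looks and any",
                       "multiplicity adjustment should be clearly spelled",
                       "out in the DMC charter.")))))
  }

  ## patient profiles
  prof_sel <- selectProfileSubjects(trial, config$grading_rules)
  prof_blocks <- if (nrow(prof_sel)) {
    lapply(prof_sel$subject_id, function(id) {
      p <- buildProfile(trial, id, config$grading_rules)
      .block("profile", paste0("Profile: ", id), content = p,
             note = paste("Selected because:",
                          paste(prof_sel$reasons[[match(id, prof_sel$subject_id)]],
                                collapse = "; ")))
    })
  } else {
    list(.block("text", "Patient profiles",
                "No subject met the profile selection criteria."))
  }
  sections[[length(sections) + 1L]] <-
    .section("profiles", "Patient profiles", prof_blocks)

  ## (vi) appendix
  if (isTRUE(config$include_appendix)) {
    ae_detail <- trial$adverse_events |>
      inner_join(trial$subjects |> select("subject_id", "arm"),
                 by = "subject_id") |>
      arrange(.data$subject_id, .data$onset_day)
    sections[[length(sections) + 1L]] <- .section(
      "appendix", "Appendix: detailed listings", list(
        .tbl_block("All adverse events", ae_detail,
                   "No adverse events reported."),
        .tbl_block("All serious adverse events",
                   ae_detail |> filter(.data$serious_flag %in% TRUE),
                   "No serious adverse events reported."),
        .tbl_block("All concomitant medications", trial$conmeds,
                   "No concomitant medication recorded.")))
  }
  list(sections = sections, trial = trial, config = config)
}

.format_changes <- function(ch) {
  fmt <- function(x, what) {
    if (!length(x)) paste0("No new ", what, ".")
    else paste0("New ", what, ": ", paste(x, collapse = ", "))
  }
  c(fmt(ch$new_subjects, "subjects"),
    fmt(ch$new_aes, "adverse events (subject:term)"),
    fmt(ch$new_lab_outliers, "flagged laboratory outliers (subject:param)"),
    fmt(ch$new_profile_subjects, "profile subjects"))
}

# ---- pagination, rendering, manifest --------------------------------------

# One block per page after the title/TOC page; deterministic single-source
# pagination shared by the PDF renderer, the HTML TOC, and the manifest.
.paginate <- function(ir) {
  page <- 1L  # page 1 is title + table of contents
  toc <- list()
  for (si in seq_along(ir$sections)) {
    sec <- ir$sections[[si]]
    page <- page + 1L
    ir$sections[[si]]$page <- page
    for (bi in seq_along(sec$blocks)) {
      if (bi > 1L) page <- page + 1L
      ir$sections[[si]]$blocks[[bi]]$page <- page
    }
    toc[[si]] <- tibble(id = sec$id, title = sec$title,
                        page = ir$sections[[si]]$page)
  }
  ir$toc <- bind_rows(toc)
  ir$n_pages <- page
  ir
}

.fmt_table_lines <- function(tb, max_rows = 40L) {
  tb <- as.data.frame(tb)
  for (nm in names(tb)) {
    if (is.list(tb[[nm]])) tb[[nm]] <- vapply(tb[[nm]], function(v)
      paste(format(v), collapse = ";"), character(1))
    if (is.numeric(tb[[nm]])) tb[[nm]] <- signif(tb[[nm]], 5)
  }
  extra <- NULL
  if (nrow(tb) > max_rows) {
    extra <- paste0("... ", nrow(tb) - max_rows, " more row(s)")
    tb <- tb[seq_len(max_rows), , drop = FALSE]
  }
  c(utils::capture.output(print(tb, row.names = FALSE)), extra)
}

.draw_text_page <- function(title, lines, page, n_pages, header = NULL) {
  grid::grid.newpage()
  y <- 0.95
  if (!is.null(header)) {
    grid::grid.text(header, x = 0.05, y = 0.975, just = c("left", "top"),
                    gp = grid::gpar(cex = 0.7, col = "grey40"))
  }
  grid::grid.text(title, x = 0.05, y = y, just = c("left", "top"),
                  gp = grid::gpar(cex = 1.1, fontface = "bold"))
  grid::grid.text(paste(lines, collapse = "\n"), x = 0.05, y = y - 0.06,
                  just = c("left", "top"),
                  gp = grid::gpar(fontfamily = "mono", cex = 0.6))
  grid::grid.text(sprintf("Page %d of %d", page, n_pages), x = 0.5, y = 0.02,
                  gp = grid::gpar(cex = 0.7))
}

.render_pdf <- function(ir, path) {
  grDevices::pdf(path, width = 8.27, height = 11.69, onefile = TRUE,
                 title = "DMC report")
  on.exit(grDevices::dev.off(), add = TRUE)
  n <- ir$n_pages
  # title + TOC
  grid::grid.newpage()
  grid::grid.text("Data Monitoring Committee Report", x = 0.5, y = 0.9,
                  gp = grid::gpar(cex = 1.6, fontface = "bold"))
  grid::grid.text(paste0("Data cut: study day ", ir$trial$cutoff_day,
                         " | Arms: ", paste(ir$trial$arms, collapse = " / ")),
                  x = 0.5, y = 0.85, gp = grid::gpar(cex = 0.9))
  toc_lines <- sprintf("%-50s %4d", ir$toc$title, ir$toc$page)
  grid::grid.text("Table of contents", x = 0.15, y = 0.75,
                  just = c("left", "top"), gp = grid::gpar(fontface = "bold"))
  grid::grid.text(paste(toc_lines, collapse = "\n"), x = 0.15, y = 0.71,
                  just = c("left", "top"), gp = grid::gpar(fontfamily = "mono",
                                                           cex = 0.8))
  grid::grid.text(sprintf("Page 1 of %d", n), x = 0.5, y = 0.02,
                  gp = grid::gpar(cex = 0.7))
  for (sec in ir$sections) {
    for (bi in seq_along(sec$blocks)) {
      b <- sec$blocks[[bi]]
      header <- paste0(sec$title, if (bi == 1) "" else " (cont.)")
      if (b$type == "text") {
        .draw_text_page(b$title, b$content, b$page, n, header)
      } else if (b$type == "table") {
        .draw_text_page(b$title, .fmt_table_lines(b$content), b$page, n, header)
      } else if (b$type == "figure") {
        grid::grid.newpage()
        grid::grid.text(header, x = 0.05, y = 0.975, just = c("left", "top"),
                        gp = grid::gpar(cex = 0.7, col = "grey40"))
        grid::grid.text(b$title, x = 0.05, y = 0.95, just = c("left", "top"),
                        gp = grid::gpar(cex = 1.1, fontface = "bold"))
        grid::pushViewport(grid::viewport(y = 0.55, height = 0.7))
        print(b$spec$plot, newpage = FALSE)
        grid::popViewport()
        cap <- strwrap(paste0(b$spec$caption,
                              if (!is.null(b$note)) paste0(" ", b$note)), 110)
        grid::grid.text(paste(cap, collapse = "\n"), x = 0.05, y = 0.16,
                        just = c("left", "top"), gp = grid::gpar(cex = 0.65))
        grid::grid.text(sprintf("Page %d of %d", b$page, n), x = 0.5, y = 0.02,
                        gp = grid::gpar(cex = 0.7))
      } else if (b$type == "profile") {
        .draw_profile_page(b$content,
                           page_label = sprintf("Page %d of %d", b$page, n))
      }
    }
  }
  invisible(path)
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.tbl_html <- function(tb, max_rows = 200L) {
  tb <- as.data.frame(tb)
  for (nm in names(tb)) {
    if (is.list(tb[[nm]])) tb[[nm]] <- vapply(tb[[nm]], function(v)
      paste(format(v), collapse = ";"), character(1))
    if (is.numeric(tb[[nm]])) tb[[nm]] <- signif(tb[[nm]], 5)
  }
  note <- NULL
  if (nrow(tb) > max_rows) {
    note <- paste0("<p><em>... ", nrow(tb) - max_rows, " more row(s)</em></p>")
    tb <- tb[seq_len(max_rows), , drop = FALSE]
  }
  head <- paste0("<tr>", paste0("<th>", .html_escape(names(tb)), "</th>",
                                collapse = ""), "</tr>")
  rows <- apply(tb, 1, function(r)
    paste0("<tr>", paste0("<td>", .html_escape(as.character(r)), "</td>",
                          collapse = ""), "</tr>"))
  paste0("<table border='1' cellspacing='0' cellpadding='3'>", head,
         paste(rows, collapse = ""), "</table>", note %||% "")
}

.render_html <- function(ir, path, fig_files) {
  h <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
         "<title>DMC report</title>",
         "<style>body{font-family:sans-serif;max-width:60em;margin:auto}",
         "pre{font-size:80%}h2{border-top:2px solid #444;padding-top:0.4em}</style>",
         "</head><body>",
         "<h1>Data Monitoring Committee Report</h1>",
         paste0("<p>Data cut: study day ", ir$trial$cutoff_day, " | Arms: ",
                .html_escape(paste(ir$trial$arms, collapse = " / ")), "</p>"),
         "<h2 id='toc'>Table of contents</h2><ul class='toc'>")
  h <- c(h, sprintf("<li><a href='#%s'>%s</a> (page %d in the PDF)</li>",
                    ir$toc$id, .html_escape(ir$toc$title), ir$toc$page),
         "</ul>")
  for (sec in ir$sections) {
    h <- c(h, sprintf("<h2 id='%s'>%s</h2>", sec$id, .html_escape(sec$title)))
    for (b in sec$blocks) {
      h <- c(h, sprintf("<h3>%s</h3>", .html_escape(b$title)))
      if (b$type == "text") {
        h <- c(h, paste0("<p>", .html_escape(b$content), "</p>"))
      } else if (b$type == "table") {
        h <- c(h, .tbl_html(b$content))
      } else if (b$type == "figure") {
        key <- paste0("p", b$page)
        h <- c(h, sprintf("<img src='%s' style='max-width:100%%'>",
                          basename(fig_files[[key]]["svg"])),
               paste0("<p><em>", .html_escape(b$spec$caption),
                      if (!is.null(b$note)) paste0(" ", .html_escape(b$note)),
                      "</em></p>"))
      } else if (b$type == "profile") {
        h <- c(h, paste0("<pre>",
                         .html_escape(paste(profileText(b$content),
                                            collapse = "\n")), "</pre>"))
        if (!is.null(b$note)) h <- c(h, paste0("<p><em>",
                                               .html_escape(b$note),
                                               "</em></p>"))
      }
      h <- c(h, "<p><a href='#toc'>back to contents</a></p>")
    }
  }
  h <- c(h, "</body></html>")
  writeLines(h, path)
  invisible(path)
}

#' Build the DMC report
#'
#' Assembles front matter, baseline, adverse-event, laboratory, vital-sign,
#' patient-profile and appendix sections from a validated trial and a
#' [reportConfig()], renders a continuously page-numbered PDF (with a
#' page-numbered table of contents) and an anchor-linked HTML document
#' from one shared intermediate representation, writes every figure as SVG
#' + PNG + backing CSV, and emits a JSON manifest listing every artifact
#' with content hashes. Empty inputs produce explicit "no events"
#' statements, never silently absent sections.
#'
#' @param trial A validated `trial_data`.
#' @param config A [reportConfig()].
#' @param out_dir Output directory (created if needed).
#' @param previous_manifest Optional manifest (path or parsed list) from an
#'   earlier data cut; a "what has changed" summary is then rendered into
#'   the front matter.
#' @return Invisibly, a list with `manifest`, the paginated intermediate
#'   representation `ir`, and output `paths`.
#' @export
buildReport <- function(trial, config, out_dir,
                        previous_manifest = NULL) {
  stopifnot(inherits(trial, "trial_data"), inherits(config, "report_config"))
  probs <- validateTrial(trial)
  if (nrow(probs)) {
    stop("trial fails validation (", nrow(probs), " finding(s)); ",
         "first: ", probs$message[1], call. = FALSE)
  }
  change_summary <- NULL
  if (!is.null(previous_manifest)) {
    prev <- if (is.character(previous_manifest)) {
      jsonlite::read_json(previous_manifest, simplifyVector = TRUE)
    } else previous_manifest
    change_summary <- diffSincePrevious(.state_snapshot(trial, config), prev)
  }
  ir <- .paginate(.build_ir(trial, config, change_summary))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  fig_files <- list()
  for (sec in ir$sections) {
    for (b in sec$blocks) {
      if (b$type == "figure") {
        base <- file.path(fig_dir, sprintf("fig_p%03d", b$page))
        fig_files[[paste0("p", b$page)]] <-
          renderFigure(b$spec, base, formats = c("svg", "png", "csv"))
      }
    }
    message(sprintf("section '%s' prepared (%.1fs elapsed)", sec$id,
                    proc.time()[["elapsed"]] - t0))
  }
  # standalone one-page profile files next to the report
  prof_dir <- file.path(out_dir, "profiles")
  prof_csvs <- character(0)
  for (sec in ir$sections) {
    for (b in sec$blocks) {
      if (b$type == "profile") {
        dir.create(prof_dir, showWarnings = FALSE)
        written <- renderProfile(b$content,
                                 file.path(prof_dir, b$content$subject_id))
        prof_csvs <- c(prof_csvs, written["csv"])
      }
    }
  }
  paths <- character(0)
  if ("pdf" %in% config$formats) {
    paths["pdf"] <- file.path(out_dir, "report.pdf")
    .render_pdf(ir, paths["pdf"])
  }
  if ("html" %in% config$formats) {
    paths["html"] <- file.path(out_dir, "report.html")
    .render_html(ir, paths["html"], fig_files)
  }

  # manifest hashes cover every deterministic artifact (figure CSV, SVG
  # and PNG, profile timeline CSVs); PDFs embed a device creation date
  # and are listed by name only
  artifacts <- c(unlist(fig_files, use.names = FALSE), unname(prof_csvs))
  manifest <- c(.state_snapshot(trial, config), list(
    toc = ir$toc,
    n_pages = ir$n_pages,
    sections = vapply(ir$sections, `[[`, character(1), "id"),
    artifacts = tibble(
      file = basename(artifacts),
      md5 = unname(tools::md5sum(artifacts))),
    pdf_artifacts = basename(c(
      if ("pdf" %in% config$formats) file.path(out_dir, "report.pdf"),
      sub("[.]csv$", ".pdf", prof_csvs)))
  ))
  paths["manifest"] <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, ir = ir, paths = paths))
}

# Comparable state fingerprint stored in the manifest; drives
# diffSincePrevious.
.state_snapshot <- function(trial, config) {
  outl <- bind_rows(lapply(unique(
    vapply(config$lab_params, `[[`, character(1), "param_code")),
    function(pc) {
      if (!pc %in% trial$labs$param_code) return(NULL)
      selectOutlierSubjects(trial, pc,
                            multiplier = 3,
                            grade_rule = config$grading_rules[[pc]])
    }))
  list(
    manifest_version = 1L,
    cutoff_day = trial$cutoff_day,
    subjects = sort(trial$subjects$subject_id),
    ae_keys = sort(unique(paste0(trial$adverse_events$subject_id, ":",
                                 trial$adverse_events$preferred_term))),
    lab_outlier_keys = if (nrow(outl))
      sort(unique(paste0(outl$subject_id, ":", outl$param_code)))
      else character(0),
    profile_subjects = selectProfileSubjects(trial, config$grading_rules)$subject_id
  )
}

#' Change summary between two DMC data cuts
#'
#' Compares two manifests produced by [buildReport()] (or state snapshots)
#' and lists the new subjects, new adverse events (subject:term keys),
#' newly flagged laboratory outliers, and newly selected profile subjects
#' since the previous cut.
#'
#' @param current,previous Manifests (parsed lists or file paths).
#' @return A list of character vectors: `new_subjects`, `new_aes`,
#'   `new_lab_outliers`, `new_profile_subjects`.
#' @export
diffSincePrevious <- function(current, previous) {
  load_m <- function(m) {
    if (is.character(m)) jsonlite::read_json(m, simplifyVector = TRUE) else m
  }
  cur <- load_m(current); prev <- load_m(previous)
  if (!identical(as.integer(cur$manifest_version %||% NA),
                 as.integer(prev$manifest_version %||% NA))) {
    stop("manifest version mismatch", call. = FALSE)
  }
  d <- function(field) sort(setdiff(cur[[field]] %||% character(0),
                                    prev[[field]] %||% character(0)))
  list(new_subjects = d("subjects"),
       new_aes = d("ae_keys"),
       new_lab_outliers = d("lab_outlier_keys"),
       new_profile_subjects = d("profile_subjects"))
}
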