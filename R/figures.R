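#' @import ggplot2
NULL

# Colorblind-safe palette (Okabe-Ito); arms keep the same colors across
# every figure of a report.
.arm_palette <- function(arms) {
  pal <- c("#E69F00", "#56B4E9", "#009E73", "#CC79A7", "#0072B2", "#D55E00")
  stats::setNames(pal[seq_along(arms)], arms)
}

# Reference (control) arm listed last in displays.
.arm_levels <- function(trial_or_arms, reference = NULL) {
  if (inherits(trial_or_arms, "trial_data")) {
    arms <- trial_or_arms$arms; reference <- trial_or_arms$reference_arm
  } else arms <- trial_or_arms
  c(setdiff(arms, reference), reference)
}

newFigureSpec <- function(kind, data, plot, caption, meta = list()) {
  # provenance: content hash of the backing data plus the config snapshot,
  # so every rendered figure traces to its exact inputs
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f), add = TRUE)
  saveRDS(list(kind = kind, data = as.data.frame(data), meta = meta),
          f, version = 2, compress = FALSE)
  prov <- unname(tools::md5sum(f))
  structure(list(kind = kind, data = data, plot = plot, caption = caption,
                 meta = meta, provenance = prov), class = "figure_spec")
}

#' @export
print.figure_spec <- function(x, ...) {
  cat("<figure_spec> kind:", x$kind, "|", nrow(x$data), "data rows\n")
  cat("caption:", x$caption, "\n")
  invisible(x)
}

.whisker_text <- paste("Boxes cover the second and third quartile;",
                       "whiskers extend to the last data point within 1.5",
                       "times the interquartile range.")

#' Graphical demographics panel
#'
#' Continuous variables as horizontal box-whisker plots per arm with a
#' distinct mean marker; binary variables as a single-category bar per arm
#' (only one of the two categories is shown). By design the panel carries
#' no p-values: baseline hypothesis testing is not performed.
#'
#' @param trial A `trial_data`.
#' @param variables Ordered character vector of Subject columns.
#' @return A `figure_spec`.
#' @export
figDemographics <- function(trial, variables = c("age", "sex")) {
  s <- trial$subjects
  bad <- setdiff(variables, names(s))
  if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  lev <- .arm_levels(trial)
  pal <- .arm_palette(lev)
  s$arm <- factor(s$arm, levels = rev(lev))
  panels <- list()
  rows <- list()
  for (v in variables) {
    x <- s[[v]]
    if (is.numeric(x)) {
      d <- tibble(arm = s$arm, value = x, variable = v)
      rows[[v]] <- d |>
        group_by(.data$arm) |>
        summarise(variable = v, mean = mean(.data$value, na.rm = TRUE),
                  median = stats::median(.data$value, na.rm = TRUE),
                  n = sum(!is.na(.data$value)), .groups = "drop")
      panels[[v]] <- ggplot(d, aes(x = .data$value, y = .data$arm)) +
        geom_boxplot(aes(fill = .data$arm), coef = 1.5, outlier.shape = 1,
                     show.legend = FALSE, width = .6) +
        stat_summary(fun = mean, geom = "point", colour = "red", size = 2.5) +
        scale_fill_manual(values = pal) +
        labs(x = v, y = NULL) + theme_minimal(base_size = 10)
    } else {
      shown <- sort(unique(stats::na.omit(as.character(x))))[1]
      d <- s |>
        group_by(.data$arm) |>
        summarise(percent = 100 * mean(.data[[v]] == shown, na.rm = TRUE),
                  .groups = "drop") |>
        mutate(variable = v, category = shown)
      rows[[v]] <- d
      panels[[v]] <- ggplot(d, aes(x = .data$percent, y = .data$arm)) +
        geom_col(aes(fill = .data$arm), show.legend = FALSE, width = .6) +
        scale_fill_manual(values = pal) +
        xlim(0, 100) +
        labs(x = paste0("% ", v, " = ", shown), y = NULL) +
        theme_minimal(base_size = 10)
    }
  }
  plot <- patchwork::wrap_plots(panels, ncol = 1)
  caption <- paste(
    "Baseline demographics by treatment arm.",
    "Red dot: mean; box line: median.", .whisker_text,
    "For binary variables only one category is shown.",
    "No baseline p-values are displayed.")
  newFigureSpec("demographics", bind_rows(rows), plot, caption,
                meta = list(variables = variables))
}

#' Adverse-event overview dot plot
#'
#' One row per term in the supplied order, one dot per arm; x is the crude
#' percentage of subjects with the event or, in the exposure-adjusted
#' view, the rate per 100 patient-years. A term observed in only one arm
#' still draws the other arm's dot at zero.
#'
#' @param records Output of [aeIncidence()].
#' @param ordering Term order (top first), e.g. from [orderTerms()].
#' @param exposure_adjusted Use `rate_per_100py` instead of `percent`.
#' @param reference_arm Optional reference arm (listed last in the legend).
#' @return A `figure_spec`.
#' @export
figAeDotplot <- function(records, ordering, exposure_adjusted = FALSE,
                         reference_arm = NULL) {
  stopifnot(nrow(records) >= 1)
  term_col <- if ("preferred_term" %in% names(records)) "preferred_term"
              else "system_organ_class"
  metric <- if (exposure_adjusted) "rate_per_100py" else "percent"
  lev <- .arm_levels(unique(records$arm), reference_arm %||%
                       utils::tail(unique(records$arm), 1))
  d <- records |>
    mutate(term = factor(.data[[term_col]], levels = rev(ordering)),
           arm = factor(.data$arm, levels = lev),
           x = .data[[metric]])
  xlab <- if (exposure_adjusted) "Subjects with event per 100 patient-years"
          else "Subjects with event (%)"
  plot <- ggplot(d, aes(x = .data$x, y = .data$term,
                        colour = .data$arm, shape = .data$arm)) +
    geom_point(size = 2.5) +
    scale_colour_manual(values = .arm_palette(lev)) +
    labs(x = xlab, y = NULL, colour = "Arm", shape = "Arm") +
    theme_minimal(base_size = 10)
  caption <- paste0(
    "Adverse event overview: subject-level incidence",
    if (exposure_adjusted) " per 100 patient-years (exposure-adjusted)" else " (%)",
    " per preferred term and arm, ordered by the active arm's rates. ",
    "A subject counts at most once per term.")
  newFigureSpec("ae_dotplot", d, plot, caption,
                meta = list(exposure_adjusted = exposure_adjusted,
                            ordering = ordering))
}

# Deterministic greedy label displacement: labels sorted by y then x are
# pushed up by one step whenever they would collide with an already
# placed label. Presentation only; no randomness.
.place_labels <- function(d, eps_x, step_y) {
  d <- d[order(-d$y, d$x, d$label), , drop = FALSE]
  placed_x <- numeric(0); placed_y <- numeric(0)
  ly <- d$y
  for (i in seq_len(nrow(d))) {
    while (any(abs(d$x[i] - placed_x) < eps_x & abs(ly[i] - placed_y) < step_y)) {
      ly[i] <- ly[i] + step_y
    }
    placed_x <- c(placed_x, d$x[i]); placed_y <- c(placed_y, ly[i])
  }
  d$label_y <- ly
  d
}

#' Adverse-event volcano plot
#'
#' Scatter of per-term effect estimates against -log10 p-values (raw or
#' FDR-adjusted). Rate ratios are drawn on a log x-axis with a reference
#' line at 1; risk differences on a linear axis with a reference line at
#' 0. Records flagged `labeled` carry text annotations placed by a
#' deterministic collision-avoiding rule.
#'
#' @param records Output of [volcanoStats()].
#' @param y_mode `"p"` (raw) or `"fdr_p"`.
#' @return A `figure_spec`.
#' @export
figVolcano <- function(records, y_mode = c("p", "fdr_p")) {
  stopifnot(nrow(records) >= 1)
  y_mode <- match.arg(y_mode)
  kind <- records$estimate_kind[1]
  d <- records |>
    mutate(y = -log10(if (y_mode == "p") .data$p_value else .data$fdr_p),
           x = .data$estimate)
  lab <- d |> filter(.data$labeled) |> mutate(label = .data$preferred_term)
  if (nrow(lab)) {
    span_x <- diff(range(if (kind == "rate_ratio") log(d$x) else d$x)) + 1e-9
    lab <- .place_labels(lab, eps_x = span_x / 8, step_y = max(d$y, 1) / 15)
  }
  plot <- ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_point(aes(colour = .data$labeled), show.legend = FALSE) +
    scale_colour_manual(values = c("FALSE" = "grey55", "TRUE" = "#D55E00")) +
    labs(x = if (kind == "rate_ratio") "Incidence rate ratio"
             else "Risk difference (percentage points)",
         y = paste0("-log10(", if (y_mode == "p") "p-value" else
                      "FDR-adjusted p-value", ")")) +
    theme_minimal(base_size = 10)
  plot <- if (kind == "rate_ratio") {
    plot + scale_x_log10() + geom_vline(xintercept = 1, linetype = 2)
  } else {
    plot + geom_vline(xintercept = 0, linetype = 2)
  }
  if (nrow(lab)) {
    plot <- plot + geom_text(data = lab,
                             aes(y = .data$label_y, label = .data$label),
                             vjust = -0.6, size = 2.8)
  }
  caption <- paste0(
    "Adverse event volcano plot: ",
    if (kind == "rate_ratio") "exposure-adjusted incidence rate ratio (log scale)"
    else "risk difference in percentage points",
    " against -log10 of the ",
    if (y_mode == "p") "two-sided Fisher exact p-value"
    else "Benjamini-Hochberg FDR-adjusted two-sided Fisher exact p-value",
    ". P-values are descriptive, not inferential.")
  newFigureSpec("volcano", d, plot, caption,
                meta = list(y_mode = y_mode, estimate_kind = kind))
}

#' Laboratory box-whisker display over visits
#'
#' Per-visit per-arm boxes from precomputed [visitBoxStats()]; the
#' annotation row under the axis shows every arm's n at every visit,
#' including n = 0 (where no box is drawn).
#'
#' @param stats Output of [visitBoxStats()].
#' @param reference_arm Optional reference arm (listed last).
#' @return A `figure_spec`.
#' @export
figLabBoxes <- function(stats, reference_arm = NULL) {
  stopifnot(nrow(stats) >= 1)
  log_scale <- isTRUE(attr(stats, "log_scale"))
  lev <- .arm_levels(unique(stats$arm),
                     reference_arm %||% utils::tail(unique(stats$arm), 1))
  d <- stats |>
    mutate(arm = factor(.data$arm, levels = lev),
           visit = factor(.data$visit_index, levels = sort(unique(.data$visit_index))))
  pal <- .arm_palette(lev)
  boxes <- d |> filter(.data$n > 0)
  outl <- d |>
    select("visit", "arm", "outlier_values") |>
    tidyr::unnest("outlier_values") |>
    rename(value = "outlier_values")
  lo <- min(c(boxes$whisker_lo, outl$value), na.rm = TRUE)
  hi <- max(c(boxes$whisker_hi, outl$value), na.rm = TRUE)
  ann_y <- if (log_scale) lo * (lo / hi)^0.08 else lo - 0.1 * (hi - lo)
  pd <- position_dodge(width = .7)
  plot <- ggplot(boxes, aes(x = .data$visit, group = interaction(.data$visit, .data$arm))) +
    geom_errorbar(aes(ymin = .data$whisker_lo, ymax = .data$whisker_hi,
                      colour = .data$arm), position = pd, width = .3) +
    geom_crossbar(aes(y = .data$median, ymin = .data$q1, ymax = .data$q3,
                      fill = .data$arm), position = pd, width = .55,
                  alpha = .6, linewidth = .3) +
    geom_point(data = outl, aes(y = .data$value, colour = .data$arm),
               position = pd, shape = 1, size = 1.5) +
    geom_text(data = d, aes(y = ann_y, label = .data$n, colour = .data$arm),
              position = pd, size = 2.6, show.legend = FALSE) +
    scale_colour_manual(values = pal) + scale_fill_manual(values = pal) +
    labs(x = "Visit", y = stats$param_code[1], colour = "Arm", fill = "Arm") +
    theme_minimal(base_size = 10)
  if (log_scale) plot <- plot + scale_y_log10()
  caption <- paste(
    "Laboratory parameter distribution over time.", .whisker_text,
    "Points beyond the whiskers are drawn individually.",
    "The row under the axis gives the number of subjects with a value per arm and visit.",
    if (log_scale) "Values displayed on a logarithmic scale." else NULL)
  newFigureSpec("lab_boxes", d, plot, caption,
                meta = list(log_scale = log_scale,
                            param_code = stats$param_code[1]))
}

#' Abnormal-prevalence-over-time display
#'
#' Percent of evaluable subjects with an abnormal value per arm and visit,
#' with the per-visit n of both arms annotated (including n = 0).
#' @param prevalence Output of [abnormalPrevalence()].
#' @param side Which abnormality was counted (for the caption).
#' @param reference_arm Optional reference arm.
#' @return A `figure_spec`.
#' @export
figAbnormalPrevalence <- function(prevalence, side = "high",
                                  reference_arm = NULL) {
  stopifnot(nrow(prevalence) >= 1)
  lev <- .arm_levels(unique(prevalence$arm),
                     reference_arm %||% utils::tail(unique(prevalence$arm), 1))
  d <- prevalence |>
    mutate(arm = factor(.data$arm, levels = lev),
           visit = factor(.data$visit_index,
                          levels = sort(unique(.data$visit_index))))
  top <- max(c(d$percent, 5), na.rm = TRUE)
  plot <- ggplot(d |> filter(.data$n > 0),
                 aes(x = .data$visit, y = .data$percent, colour = .data$arm,
                     group = .data$arm)) +
    geom_line() + geom_point() +
    geom_text(data = d, aes(y = -0.08 * top, label = .data$n),
              position = position_dodge(width = .5), size = 2.6,
              show.legend = FALSE) +
    scale_colour_manual(values = .arm_palette(lev)) +
    labs(x = "Visit", y = paste0("% subjects abnormal (", side, ")"),
         colour = "Arm") +
    theme_minimal(base_size = 10)
  caption <- paste0(
    "Abnormal laboratory values over time (side: ", side, "). ",
    "Denominator: subjects with an evaluable value at the visit; ",
    "per-visit n for every arm annotated under the axis.")
  newFigureSpec("abnormal_prevalence", d, plot, caption,
                meta = list(side = side))
}

#' Spaghetti plot with flagged trajectories
#'
#' All subjects' trajectories for one parameter; unselected subjects are
#' muted grey context, selected subjects are coloured and annotated with
#' their subject id at the trajectory end. Reference lines for the limits
#' of normal are drawn only when `show_limits = TRUE` and the limits are
#' identical for every subject; otherwise they are suppressed and the
#' caption says so.
#'
#' @param trial A `trial_data`.
#' @param param_code Laboratory parameter.
#' @param selected Character vector of selected subject ids (must have data
#'   for the parameter).
#' @param show_limits Request limit reference lines.
#' @return A `figure_spec`.
#' @export
figSpaghetti <- function(trial, param_code, selected = character(),
                         show_limits = FALSE) {
  d <- trial$labs |>
    filter(.data$param_code == !!param_code, !is.na(.data$value))
  stopifnot(all(selected %in% d$subject_id))
  d$selected <- d$subject_id %in% selected
  common_limits <- length(unique(stats::na.omit(d$uln))) == 1 &&
    length(unique(stats::na.omit(d$lln))) == 1 &&
    !anyNA(d$uln) && !anyNA(d$lln)
  ends <- d |>
    filter(.data$selected) |>
    group_by(.data$subject_id) |>
    slice_max(.data$day, n = 1, with_ties = FALSE) |>
    ungroup()
  plot <- ggplot(d, aes(x = .data$day, y = .data$value,
                        group = .data$subject_id)) +
    geom_line(data = d |> filter(!.data$selected), colour = "grey80",
              linewidth = .3) +
    geom_line(data = d |> filter(.data$selected),
              aes(colour = .data$subject_id), linewidth = .6,
              show.legend = FALSE) +
    labs(x = "Study day", y = param_code) +
    theme_minimal(base_size = 10)
  if (nrow(ends)) {
    plot <- plot + geom_text(data = ends,
                             aes(label = .data$subject_id,
                                 colour = .data$subject_id),
                             hjust = -0.05, size = 2.6, show.legend = FALSE)
  }
  limit_note <- ""
  if (show_limits && common_limits) {
    plot <- plot +
      geom_hline(yintercept = unique(stats::na.omit(d$uln)), linetype = 2) +
      geom_hline(yintercept = unique(stats::na.omit(d$lln)), linetype = 2)
    limit_note <- " Dashed lines: common limits of normal."
  } else if (show_limits && !common_limits) {
    limit_note <- paste(" Reference lines for the limits of normal are",
                        "suppressed because the limits vary by subject.")
  }
  caption <- paste0(
    "Individual trajectories of ", param_code,
    "; flagged subjects coloured and annotated with their subject id, all",
    " other subjects in grey for context.", limit_note)
  newFigureSpec("spaghetti", d, plot, caption,
                meta = list(selected = sort(selected),
                            common_limits = common_limits,
                            show_limits = show_limits))
}

#' Graphical alternative to the laboratory shift table
#'
#' One point per subject: baseline value against post-baseline value, with
#' the identity diagonal and — when common limits are available — limit
#' lines on both axes partitioning the plane into the nine shift cells.
#'
#' @param pairs Output of [shiftPairs()].
#' @param lln,uln Common limits of normal, or `NA` to suppress the lines.
#' @return A `figure_spec`.
#' @export
figShiftScatter <- function(pairs, lln = NA_real_, uln = NA_real_) {
  stopifnot(nrow(pairs) >= 1)
  have_limits <- !is.na(lln) || !is.na(uln)
  plot <- ggplot(pairs, aes(x = .data$baseline_value, y = .data$post_value)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    geom_point(shape = 1, size = 1.8) +
    labs(x = "Baseline value", y = "Post-baseline value") +
    theme_minimal(base_size = 10)
  for (lim in c(lln, uln)) {
    if (!is.na(lim)) {
      plot <- plot + geom_vline(xintercept = lim) + geom_hline(yintercept = lim)
    }
  }
  caption <- paste0(
    "Shift display: baseline vs post-baseline value, one point per",
    " eligible subject; the diagonal marks no change.",
    if (have_limits) " Black lines are the limits of normal, partitioning the plane into the shift cells."
    else " Limit lines suppressed (no common limits of normal).")
  newFigureSpec("shift_scatter", pairs, plot, caption,
                meta = list(lln = lln, uln = uln))
}

.warmup_env <- new.env(parent = emptyenv())

# Render one throwaway text plot per session so the font machinery is
# fully initialized before any artifact is produced; keeps repeated
# renders byte-identical even when the first render of a session would
# otherwise warm caches mid-run.
.graphics_warmup <- function() {
  if (isTRUE(.warmup_env$done)) return(invisible())
  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".png")
  for (open_dev in list(function() grDevices::svg(f1, 3, 3),
                        function() ragg::agg_png(f2, 300, 300))) {
    try({
      open_dev()
      grid::grid.text("warmup 0123456789", gp = grid::gpar(fontfamily = "mono"))
      grid::grid.text("warmup", gp = grid::gpar(fontface = "bold"))
      grDevices::dev.off()
    }, silent = TRUE)
  }
  unlink(c(f1, f2))
  .warmup_env$done <- TRUE
  invisible()
}

#' Render a figure specification to disk
#'
#' Writes the vector (SVG), raster (PNG), and backing-data (CSV) artifacts
#' next to each other for traceability. Output is deterministic for
#' identical inputs: no timestamps are embedded in the SVG or CSV.
#'
#' @param spec A `figure_spec`.
#' @param path_base Output path without extension.
#' @param formats Subset of `c("svg", "png", "csv")`.
#' @param width,height Device size in inches.
#' @return Named character vector of the files written, invisibly.
#' @export
renderFigure <- function(spec, path_base, formats = c("svg", "png", "csv"),
                         width = 7, height = 5) {
  stopifnot(inherits(spec, "figure_spec"))
  .graphics_warmup()
  out <- character(0)
  if ("csv" %in% formats) {
    f <- paste0(path_base, ".csv")
    flat <- spec$data
    for (nm in names(flat)) {
      if (is.list(flat[[nm]])) {
        flat[[nm]] <- vapply(flat[[nm]], function(v)
          paste(format(v, trim = TRUE), collapse = ";"), character(1))
      }
    }
    readr::write_csv(flat, f, na = "", progress = FALSE)
    out["csv"] <- f
  }
  # a concrete font family makes fontconfig matching (and hence text
  # metrics and panel layout) reproducible across renders
  fam <- getOption("dmcreport.font_family", "DejaVu Sans")
  if ("svg" %in% formats) {
    f <- paste0(path_base, ".svg")
    grDevices::svg(f, width = width, height = height, family = fam)
    print(spec$plot)
    grDevices::dev.off()
    out["svg"] <- f
  }
  if ("png" %in% formats) {
    # ragg keeps raster text off the cairo/pango stack: mixing hinted
    # (raster) and unhinted (SVG) cairo font metrics in one process makes
    # text layout depend on cache order and breaks byte reproducibility
    f <- paste0(path_base, ".png")
    ragg::agg_png(f, width = width * 100, height = height * 100, res = 100)
    print(spec$plot)
    grDevices::dev.off()
    out["png"] <- f
  }
  invisible(out)
}
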