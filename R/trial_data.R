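#' @import dplyr
#' @importFrom rlang .data %||%
#' @importFrom tibble tibble as_tibble
NULL

# Canonical schemas for the five subject-level tables plus the two
# profile-only tables. `aliases` are the documented ADaM-style header
# aliases, matched case-insensitively. Types: chr, num, int, lgl.
.dmc_schemas <- list(
  subjects = list(
    key = "subject_id",
    cols = list(
      subject_id         = list(type = "chr", required = TRUE,  aliases = c("USUBJID", "SUBJID")),
      arm                = list(type = "chr", required = TRUE,  aliases = c("ARM", "TRT01A", "TRT01P", "ACTARM")),
      age                = list(type = "num", required = FALSE, aliases = c("AGE")),
      sex                = list(type = "chr", required = FALSE, aliases = c("SEX")),
      race               = list(type = "chr", required = FALSE, aliases = c("RACE")),
      country            = list(type = "chr", required = FALSE, aliases = c("COUNTRY")),
      first_dose_day     = list(type = "int", required = FALSE, aliases = c("TRTSDY", "FIRSTDOSEDY")),
      last_dose_day      = list(type = "int", required = FALSE, aliases = c("TRTEDY", "LASTDOSEDY")),
      randomized_flag    = list(type = "lgl", required = FALSE, aliases = c("RANDFL")),
      discontinued_flag  = list(type = "lgl", required = FALSE, aliases = c("DISCFL", "DCSREASFL"))
    )
  ),
  adverse_events = list(
    key = NULL,
    cols = list(
      subject_id           = list(type = "chr", required = TRUE,  aliases = c("USUBJID", "SUBJID")),
      preferred_term       = list(type = "chr", required = TRUE,  aliases = c("AEDECOD", "AETERM")),
      system_organ_class   = list(type = "chr", required = FALSE, aliases = c("AEBODSYS", "AESOC")),
      onset_day            = list(type = "int", required = TRUE,  aliases = c("ASTDY", "AESTDY")),
      resolution_day       = list(type = "int", required = FALSE, aliases = c("AENDY", "AEENDY")),
      ctc_grade            = list(type = "int", required = FALSE, aliases = c("AETOXGR", "ATOXGR")),
      serious_flag         = list(type = "lgl", required = FALSE, aliases = c("AESER")),
      related_flag         = list(type = "lgl", required = FALSE, aliases = c("AEREL")),
      discontinuation_flag = list(type = "lgl", required = FALSE, aliases = c("AEACNFL", "AEDISCFL")),
      aesi_flag            = list(type = "lgl", required = FALSE, aliases = c("AESIFL", "AOCCFL"))
    )
  ),
  labs = list(
    key = NULL,
    cols = list(
      subject_id    = list(type = "chr", required = TRUE,  aliases = c("USUBJID", "SUBJID")),
      param_code    = list(type = "chr", required = TRUE,  aliases = c("PARAMCD")),
      param_name    = list(type = "chr", required = FALSE, aliases = c("PARAM")),
      visit_index   = list(type = "int", required = FALSE, aliases = c("AVISITN", "VISITNUM")),
      visit_name    = list(type = "chr", required = FALSE, aliases = c("AVISIT", "VISIT")),
      day           = list(type = "int", required = TRUE,  aliases = c("ADY")),
      value         = list(type = "num", required = TRUE,  aliases = c("AVAL", "LBSTRESN")),
      unit          = list(type = "chr", required = FALSE, aliases = c("AVALU", "LBSTRESU")),
      lln           = list(type = "num", required = FALSE, aliases = c("ANRLO", "LBSTNRLO")),
      uln           = list(type = "num", required = FALSE, aliases = c("ANRHI", "LBSTNRHI")),
      baseline_flag = list(type = "lgl", required = FALSE, aliases = c("ABLFL"))
    )
  ),
  exposure = list(
    key = NULL,
    cols = list(
      subject_id = list(type = "chr", required = TRUE,  aliases = c("USUBJID", "SUBJID")),
      start_day  = list(type = "int", required = TRUE,  aliases = c("ASTDY", "EXSTDY")),
      end_day    = list(type = "int", required = TRUE,  aliases = c("AENDY", "EXENDY")),
      dose_label = list(type = "chr", required = FALSE, aliases = c("EXTRT", "EXDOSE"))
    )
  ),
  conmeds = list(
    key = NULL,
    cols = list(
      subject_id   = list(type = "chr", required = TRUE,  aliases = c("USUBJID", "SUBJID")),
      term         = list(type = "chr", required = TRUE,  aliases = c("CMDECOD", "CMTRT")),
      start_day    = list(type = "int", required = FALSE, aliases = c("ASTDY", "CMSTDY")),
      end_day      = list(type = "int", required = FALSE, aliases = c("AENDY", "CMENDY")),
      ongoing_flag = list(type = "lgl", required = FALSE, aliases = c("CMONGO", "ONGOFL"))
    )
  ),
  medhistory = list(
    key = NULL,
    cols = list(
      subject_id   = list(type = "chr", required = TRUE,  aliases = c("USUBJID", "SUBJID")),
      term         = list(type = "chr", required = TRUE,  aliases = c("MHDECOD", "MHTERM")),
      start_day    = list(type = "int", required = FALSE, aliases = c("ASTDY", "MHSTDY")),
      end_day      = list(type = "int", required = FALSE, aliases = c("AENDY", "MHENDY")),
      ongoing_flag = list(type = "lgl", required = FALSE, aliases = c("MHONGO", "ONGOFL"))
    )
  )
)

#' Table kinds understood by the readers
#' @return Character vector of table kind names.
#' @export
tableKinds <- function() names(.dmc_schemas)

.coerce_col <- function(x, type) {
  switch(type,
    chr = as.character(x),
    num = suppressWarnings(as.numeric(x)),
    int = {
      v <- suppressWarnings(as.numeric(x))
      ifelse(is.na(v), NA_integer_, as.integer(round(v)))
    },
    lgl = {
      if (is.logical(x)) return(x)
      s <- toupper(trimws(as.character(x)))
      out <- rep(NA, length(s))
      out[s %in% c("Y", "YES", "TRUE", "T", "1")] <- TRUE
      out[s %in% c("N", "NO", "FALSE", "F", "0", "")] <- FALSE
      out[is.na(s)] <- NA
      out
    }
  )
}

# Map raw headers to canonical names, case-insensitively; unknown columns
# are dropped. Also accepts `<field>_date` ISO-8601 columns, converted to
# study days downstream.
.normalize_headers <- function(df, schema) {
  lookup <- list()
  for (canon in names(schema$cols)) {
    for (a in c(canon, schema$cols[[canon]]$aliases)) lookup[[toupper(a)]] <- canon
  }
  raw <- names(df)
  canon_names <- vapply(raw, function(nm) {
    hit <- lookup[[toupper(nm)]]
    if (is.null(hit)) NA_character_ else hit
  }, character(1))
  # keep *_date columns for day derivation
  is_date <- grepl("_date$", tolower(raw)) | toupper(raw) %in% c("TRTSDT", "TRTEDT", "ASTDT", "AENDT", "ADT")
  keep <- !is.na(canon_names) | is_date
  df <- df[keep]
  nm <- ifelse(!is.na(canon_names[keep]), canon_names[keep], tolower(raw[keep]))
  names(df) <- nm
  df[!duplicated(names(df))]
}

# CDISC study-day convention: no day 0. Dates on/after first dose get
# day = date - first_dose + 1; earlier dates get date - first_dose.
studyDay <- function(date, first_dose_date) {
  d <- as.integer(as.Date(date) - as.Date(first_dose_date))
  ifelse(is.na(d), NA_integer_, as.integer(ifelse(d >= 0, d + 1L, d)))
}

.date_to_day_cols <- function(df, kind, first_dose_dates) {
  date_map <- list(
    subjects = c(first_dose_day = "trtsdt", last_dose_day = "trtedt"),
    adverse_events = c(onset_day = "astdt", resolution_day = "aendt"),
    labs = c(day = "adt"),
    exposure = c(start_day = "astdt", end_day = "aendt"),
    conmeds = c(start_day = "astdt", end_day = "aendt"),
    medhistory = c(start_day = "astdt", end_day = "aendt")
  )[[kind]]
  # generic <field>_date columns take the canonical field's name
  for (fld in names(.dmc_schemas[[kind]]$cols)) {
    dc <- paste0(sub("_day$", "", fld), "_date")
    if (grepl("_day$", fld) && dc %in% names(df) && !is.null(date_map)) {
      date_map[fld] <- dc
    }
  }
  for (fld in names(date_map)) {
    src <- date_map[[fld]]
    if (!src %in% names(df)) next
    if (fld %in% names(df) && !all(is.na(df[[fld]]))) next  # precomputed *_day wins
    if (kind == "subjects") {
      ref <- df[["trtsdt"]] %||% df[["first_dose_date"]]
      df[[fld]] <- studyDay(df[[src]], ref)
    } else {
      if (is.null(first_dose_dates)) {
        stop("date columns supplied for '", kind,
             "' but no `first_dose_dates` reference given", call. = FALSE)
      }
      ref <- unname(first_dose_dates[df[["subject_id"]]])
      df[[fld]] <- studyDay(df[[src]], ref)
    }
  }
  df[, !grepl("^(trtsdt|trtedt|astdt|aendt|adt)$|_date$", names(df)), drop = FALSE]
}

#' Read one clinical table from CSV or SAS transport (XPT v5)
#'
#' Reads a subject-level table, resolves documented ADaM-style header
#' aliases (e.g. `USUBJID` -> `subject_id`, `AEDECOD` -> `preferred_term`,
#' `ANRLO`/`ANRHI` -> `lln`/`uln`), coerces columns to the schema types,
#' and enforces per-table row invariants. ISO-8601 `*_date` columns (or
#' ADaM `TRTSDT`-style date columns) are converted to study days with the
#' no-day-zero convention; precomputed `*_day` columns win when both are
#' present.
#'
#' @param path Path to the file.
#' @param table_kind One of [tableKinds()].
#' @param dialect `"csv"` (canonical, round-trip) or `"xpt"` (read-only).
#' @param first_dose_dates Optional named vector (subject_id -> first dose
#'   date) used to convert event dates to study days for non-subject tables.
#' @return A validated tibble with canonical column names; attribute
#'   `table_kind` records the kind.
#' @export
readTable <- function(path, table_kind, dialect = c("csv", "xpt"),
                      first_dose_dates = NULL) {
  dialect <- match.arg(dialect)
  table_kind <- match.arg(table_kind, tableKinds())
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schema <- .dmc_schemas[[table_kind]]

  raw <- if (dialect == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE)
  } else {
    haven::read_xpt(path)
  }
  df <- .normalize_headers(as_tibble(raw), schema)
  df <- .date_to_day_cols(df, table_kind, first_dose_dates)

  missing_req <- setdiff(
    names(Filter(function(c) isTRUE(c$required), schema$cols)), names(df))
  if (length(missing_req)) {
    stop("schema error in ", table_kind, " table: missing required column(s) ",
         paste0("'", missing_req, "'", collapse = ", "), call. = FALSE)
  }
  for (canon in names(schema$cols)) {
    type <- schema$cols[[canon]]$type
    if (!canon %in% names(df)) {
      df[[canon]] <- .coerce_col(rep(NA, nrow(df)), type)
      next
    }
    before <- df[[canon]]
    after <- .coerce_col(before, type)
    bad <- which(is.na(after) & !is.na(before) &
                   !(trimws(as.character(before)) %in% c("", "NA", ".")))
    if (length(bad)) {
      stop("parse error in ", table_kind, " column '", canon, "' at row(s) ",
           paste(utils::head(bad, 10), collapse = ", "),
           ": unparseable value(s) e.g. '", before[bad[1]], "'", call. = FALSE)
    }
    df[[canon]] <- after
  }
  df <- df[names(schema$cols)]

  .check_table_rows(df, table_kind, stop_on_error = TRUE)
  attr(df, "table_kind") <- table_kind
  df
}

# Row-level invariant checks shared by readTable (hard errors) and
# validateTrial (collected records).
.check_table_rows <- function(df, kind, stop_on_error = FALSE) {
  probs <- tibble(severity = character(), table = character(),
                  row = integer(), message = character())
  add <- function(rows, msg) {
    if (!length(rows)) return()
    probs <<- bind_rows(probs, tibble(severity = "error", table = kind,
                                      row = as.integer(rows), message = msg))
  }
  if (kind == "subjects") {
    dup <- which(duplicated(df$subject_id))
    add(dup, paste0("duplicate subject_id '", df$subject_id[dup], "'"))
    bad <- which(!is.na(df$first_dose_day) & !is.na(df$last_dose_day) &
                   df$last_dose_day < df$first_dose_day)
    add(bad, paste0("subject '", df$subject_id[bad],
                    "': last_dose_day before first_dose_day"))
    neg <- which(!is.na(df$age) & df$age < 0)
    add(neg, paste0("subject '", df$subject_id[neg], "': negative age"))
  }
  if (kind == "adverse_events") {
    bad <- which(!is.na(df$ctc_grade) & !(df$ctc_grade %in% 1:5))
    add(bad, paste0("ctc_grade ", df$ctc_grade[bad], " outside 1..5"))
    res <- which(!is.na(df$resolution_day) & !is.na(df$onset_day) &
                   df$resolution_day < df$onset_day)
    add(res, "resolution_day before onset_day")
  }
  if (kind == "labs") {
    bad <- which(!is.na(df$lln) & !is.na(df$uln) & df$lln >= df$uln)
    add(bad, paste0("lln (", df$lln[bad], ") not below uln (", df$uln[bad], ")"))
    bl <- df |>
      mutate(.row = dplyr::row_number()) |>
      filter(.data$baseline_flag %in% TRUE) |>
      group_by(.data$subject_id, .data$param_code) |>
      filter(dplyr::n() > 1) |>
      ungroup()
    add(bl$.row, "more than one baseline-flagged record for subject x param")
  }
  if (kind == "exposure") {
    bad <- which(!is.na(df$start_day) & !is.na(df$end_day) &
                   df$end_day < df$start_day)
    add(bad, "exposure end_day before start_day")
    if (nrow(df)) {
      ov <- df |>
        mutate(.row = dplyr::row_number()) |>
        arrange(.data$subject_id, .data$start_day) |>
        group_by(.data$subject_id) |>
        mutate(.overlap = !is.na(dplyr::lag(.data$end_day)) &
                 .data$start_day <= dplyr::lag(.data$end_day)) |>
        ungroup() |>
        filter(.data$.overlap)
      add(ov$.row, "overlapping exposure intervals for one subject")
    }
  }
  if (stop_on_error && nrow(probs)) {
    stop("integrity error in ", kind, " table: row ", probs$row[1], ": ",
         probs$message[1],
         if (nrow(probs) > 1) paste0(" (and ", nrow(probs) - 1, " more)"),
         call. = FALSE)
  }
  probs
}

#' Write a clinical table to CSV
#'
#' CSV is the canonical round-trip dialect: [readTable()] on the written
#' file reproduces all field values exactly.
#' @param x Table as returned by [readTable()] or a generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTable <- function(x, path) {
  readr::write_csv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' Assemble the per-table inputs into one trial container
#'
#' Enforces cross-table referential integrity, applies the data cut
#' (records with onset/measurement day beyond `cutoff_day` are dropped,
#' with per-table drop counts reported via `message()`), and truncates
#' ongoing intervals at the cut.
#'
#' @param subjects,adverse_events,labs,exposure,conmeds,medhistory Tables
#'   as returned by [readTable()] (the last two may be `NULL`).
#' @param arms Ordered character vector of arm labels.
#' @param reference_arm The control arm; defaults to the last of `arms`.
#' @param cutoff_day Study-day of the data cut for this DMC look.
#' @return A `trial_data` object.
#' @export
assembleTrial <- function(subjects, adverse_events, labs, exposure,
                          conmeds = NULL, medhistory = NULL,
                          arms, reference_arm = arms[length(arms)],
                          cutoff_day) {
  stopifnot(length(arms) >= 1, reference_arm %in% arms)
  empty <- function(kind) {
    cols <- .dmc_schemas[[kind]]$cols
    out <- lapply(cols, function(c) .coerce_col(character(0), c$type))
    as_tibble(out)
  }
  adverse_events <- adverse_events %||% empty("adverse_events")
  conmeds <- conmeds %||% empty("conmeds")
  medhistory <- medhistory %||% empty("medhistory")

  known <- subjects$subject_id
  for (nm in c("adverse_events", "labs", "exposure", "conmeds", "medhistory")) {
    tb <- get(nm)
    orphan <- setdiff(tb$subject_id, known)
    if (length(orphan)) {
      stop("integrity error: ", nm, " references unknown subject id(s): ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
  }
  drop_after <- function(tb, day_col, label) {
    keep <- is.na(tb[[day_col]]) | tb[[day_col]] <= cutoff_day
    n_drop <- sum(!keep)
    if (n_drop > 0) message("data cut: dropped ", n_drop, " ", label,
                            " record(s) beyond day ", cutoff_day)
    tb[keep, , drop = FALSE]
  }
  adverse_events <- drop_after(adverse_events, "onset_day", "adverse-event")
  labs <- drop_after(labs, "day", "laboratory")
  exposure <- drop_after(exposure, "start_day", "exposure")
  conmeds <- conmeds |> filter(is.na(.data$start_day) | .data$start_day <= cutoff_day)
  medhistory <- medhistory |> filter(is.na(.data$start_day) | .data$start_day <= cutoff_day)

  trunc_at <- function(x) ifelse(!is.na(x) & x > cutoff_day, cutoff_day, x)
  adverse_events$resolution_day <- trunc_at(adverse_events$resolution_day)
  exposure$end_day <- as.integer(trunc_at(exposure$end_day))
  conmeds$end_day <- as.integer(trunc_at(conmeds$end_day))
  subjects$last_dose_day <- as.integer(trunc_at(subjects$last_dose_day))

  newTrialData(subjects = subjects, adverse_events = adverse_events,
               labs = labs, exposure = exposure, conmeds = conmeds,
               medhistory = medhistory, arms = arms,
               reference_arm = reference_arm, cutoff_day = cutoff_day)
}

#' Low-level trial container constructor (no filtering, no checks)
#'
#' Used by [assembleTrial()] and the synthetic generator; call
#' [validateTrial()] to audit an object built this way.
#' @inheritParams assembleTrial
#' @return A `trial_data` object: a list of the six tables plus `arms`,
#'   `reference_arm` and `cutoff_day`.
#' @export
newTrialData <- function(subjects, adverse_events, labs, exposure,
                         conmeds, medhistory, arms, reference_arm,
                         cutoff_day) {
  structure(list(
    subjects = as_tibble(subjects),
    adverse_events = as_tibble(adverse_events),
    labs = as_tibble(labs),
    exposure = as_tibble(exposure),
    conmeds = as_tibble(conmeds),
    medhistory = as_tibble(medhistory),
    arms = as.character(arms),
    reference_arm = reference_arm,
    cutoff_day = as.integer(cutoff_day)
  ), class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat("<trial_data> ", nrow(x$subjects), " subjects, arms: ",
      paste(x$arms, collapse = " / "),
      " (reference: ", x$reference_arm, "), cutoff day ", x$cutoff_day, "\n",
      sep = "")
  cat("  adverse events: ", nrow(x$adverse_events),
      " | lab records: ", nrow(x$labs),
      " | exposure intervals: ", nrow(x$exposure), "\n", sep = "")
  invisible(x)
}

#' Audit every structural invariant of a trial container
#'
#' Validation never raises: it returns a tibble of findings with columns
#' `severity`, `table`, `row`, `message`; a zero-row result means every
#' invariant holds.
#' @param trial A `trial_data` object.
#' @return A tibble of findings (possibly empty).
#' @export
validateTrial <- function(trial) {
  stopifnot(inherits(trial, "trial_data"))
  out <- bind_rows(
    .check_table_rows(trial$subjects, "subjects"),
    .check_table_rows(trial$adverse_events, "adverse_events"),
    .check_table_rows(trial$labs, "labs"),
    .check_table_rows(trial$exposure, "exposure")
  )
  known <- trial$subjects$subject_id
  for (nm in c("adverse_events", "labs", "exposure", "conmeds", "medhistory")) {
    tb <- trial[[nm]]
    if (!nrow(tb)) next
    orphan <- which(!tb$subject_id %in% known)
    if (length(orphan)) {
      out <- bind_rows(out, tibble(
        severity = "error", table = nm, row = as.integer(orphan),
        message = paste0("unknown subject_id '", tb$subject_id[orphan], "'")))
    }
  }
  bad_arm <- which(!is.na(trial$subjects$arm) &
                     !trial$subjects$arm %in% trial$arms)
  if (length(bad_arm)) {
    out <- bind_rows(out, tibble(
      severity = "error", table = "subjects", row = as.integer(bad_arm),
      message = paste0("arm '", trial$subjects$arm[bad_arm],
                       "' not in declared arm set")))
  }
  over <- function(tb, col, nm) {
    i <- which(!is.na(tb[[col]]) & tb[[col]] > trial$cutoff_day)
    if (length(i)) {
      out <<- bind_rows(out, tibble(
        severity = "error", table = nm, row = as.integer(i),
        message = paste0(col, " beyond cutoff_day ", trial$cutoff_day)))
    }
  }
  over(trial$adverse_events, "onset_day", "adverse_events")
  over(trial$labs, "day", "labs")
  over(trial$exposure, "end_day", "exposure")
  out
}
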