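test_that("ADaM-style header aliases resolve case-insensitively", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("USUBJID,ARM,AGE,SEX",
               "X1,Active,64,F", "X2,Active,71,M", "X3,Placebo,58,F"), f)
  tb <- readTable(f, "subjects")
  expect_equal(nrow(tb), 3)
  expect_equal(tb$subject_id, c("X1", "X2", "X3"))
  expect_equal(tb$arm, c("Active", "Active", "Placebo"))
  expect_equal(tb$age, c(64, 71, 58))
})

test_that("missing required column raises a schema error naming it", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("USUBJID,AGE", "X1,64"), f)
  expect_error(readTable(f, "subjects"), "schema error.*'arm'")
})

test_that("inverted limits of normal are an integrity error citing the row", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("USUBJID,PARAMCD,ADY,AVAL,ANRLO,ANRHI",
               "X1,ALT,1,30,7,40",
               "X1,ALT,14,35,10,5"), f)
  expect_error(readTable(f, "labs"), "integrity error.*row 2")
})

test_that("unparseable values are rejected with row numbers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("USUBJID,ARM,AGE", "X1,Active,sixty"), f)
  expect_error(readTable(f, "subjects"), "row.*1")
})

test_that("XPT v5 input is read with the same alias resolution", {
  f <- withr::local_tempfile(fileext = ".xpt")
  haven::write_xpt(
    data.frame(USUBJID = c("X1", "X2"), ARM = "Active", AGE = c(60, 65),
               SEX = c("F", "M")), f, version = 5, name = "ADSL")
  tb <- readTable(f, "subjects", dialect = "xpt")
  expect_equal(tb$subject_id, c("X1", "X2"))
  expect_equal(tb$age, c(60, 65))
})

test_that("ISO dates convert with the no-day-zero study-day convention", {
  expect_equal(studyDay("2023-01-10", "2023-01-10"), 1L)
  expect_equal(studyDay("2023-01-12", "2023-01-10"), 3L)
  expect_equal(studyDay("2023-01-09", "2023-01-10"), -1L)

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("USUBJID,ARM,first_dose_date,last_dose_date",
               "X1,Active,2023-01-10,2023-03-10"), f)
  tb <- readTable(f, "subjects")
  expect_equal(tb$first_dose_day, 1L)
  expect_equal(tb$last_dose_day, 60L)
})

test_that("CSV round-trip reproduces all field values exactly", {
  trial <- fixture_trial(seed = 3, n = 20)
  for (nm in c("subjects", "adverse_events", "labs", "exposure")) {
    f <- withr::local_tempfile(fileext = ".csv")
    writeTable(trial[[nm]], f)
    back <- readTable(f, nm)
    expect_equal(as.data.frame(back), as.data.frame(trial[[nm]]),
                 tolerance = 0, info = nm, ignore_attr = "table_kind")
  }
})

test_that("assembleTrial applies the data cut and truncates intervals", {
  subjects <- tibble(
    subject_id = c("X1", "X2"), arm = c("Active", "Placebo"),
    age = 60, sex = "F", race = "WHITE", country = "USA",
    first_dose_day = 1L, last_dose_day = c(500L, 100L),
    randomized_flag = TRUE, discontinued_flag = FALSE)
  ae <- tibble(subject_id = "X1", preferred_term = "Nausea",
               system_organ_class = "GI", onset_day = 400L,
               resolution_day = NA_integer_, ctc_grade = 1L,
               serious_flag = FALSE, related_flag = FALSE,
               discontinuation_flag = FALSE, aesi_flag = FALSE)
  exposure <- tibble(subject_id = c("X1", "X2"), start_day = 1L,
                     end_day = c(500L, 100L), dose_label = "x")
  labs <- tiny_trial()$labs[0, ]
  expect_message(
    trial <- assembleTrial(subjects, ae, labs, exposure,
                           arms = c("Active", "Placebo"), cutoff_day = 365),
    "dropped 1 adverse-event")
  expect_equal(nrow(trial$adverse_events), 0)     # beyond-cutoff AE dropped
  expect_equal(trial$exposure$end_day, c(365L, 100L))  # interval truncated
  expect_equal(trial$subjects$last_dose_day, c(365L, 100L))

  # idempotence: re-assembling the assembled tables changes nothing
  trial2 <- assembleTrial(trial$subjects, trial$adverse_events, trial$labs,
                          trial$exposure, trial$conmeds, trial$medhistory,
                          arms = trial$arms, cutoff_day = 365)
  for (nm in c("subjects", "adverse_events", "labs", "exposure")) {
    expect_identical(trial[[nm]], trial2[[nm]], info = nm)
  }
})

test_that("assembleTrial rejects events for unknown subjects, listing ids", {
  t0 <- tiny_trial()
  bad_ae <- bind_rows(t0$adverse_events,
                      t0$adverse_events[1, ] |> mutate(subject_id = "GHOST"))
  expect_error(
    assembleTrial(t0$subjects, bad_ae, t0$labs, t0$exposure,
                  arms = t0$arms, cutoff_day = 182),
    "GHOST")
})

test_that("an empty adverse-event table assembles and yields zero incidence", {
  t0 <- tiny_trial()
  trial <- assembleTrial(t0$subjects, NULL, t0$labs, t0$exposure,
                         arms = t0$arms, cutoff_day = 182)
  expect_s3_class(trial, "trial_data")
  expect_equal(nrow(aeIncidence(trial)), 0)
})

test_that("validateTrial reports violations without raising", {
  trial <- fixture_trial(seed = 5, n = 15)
  expect_equal(nrow(validateTrial(trial)), 0)

  broken <- trial
  broken$subjects$last_dose_day[1] <- broken$subjects$first_dose_day[1] - 5L
  rep1 <- validateTrial(broken)
  expect_true(any(grepl("last_dose_day before first_dose_day", rep1$message)))
  expect_true(any(grepl(broken$subjects$subject_id[1], rep1$message)))

  broken2 <- trial
  broken2$labs$subject_id[1] <- "NOBODY"
  rep2 <- validateTrial(broken2)
  expect_true(any(rep2$table == "labs" & grepl("NOBODY", rep2$message)))
})

test_that("trial tables survive a directory round trip", {
  trial <- fixture_trial(seed = 9, n = 12)
  dir <- withr::local_tempdir()
  writeTrialTables(trial, dir)
  back <- readTrialTables(dir)
  expect_equal(back$arms, trial$arms)
  expect_equal(back$cutoff_day, trial$cutoff_day)
  expect_equal(as.data.frame(back$subjects), as.data.frame(trial$subjects),
               ignore_attr = "table_kind")
  expect_equal(as.data.frame(back$labs), as.data.frame(trial$labs),
               ignore_attr = "table_kind")
})
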