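report_fixture <- function(seed = 71, n = 30) {
  trial <- fixture_trial(seed = seed, n = n)
  cfg <- reportConfig(
    comparisons = list(c("High Dose", "Placebo")),
    lab_params = c("CHOL", "CK"),
    front_matter = list(protocol_synopsis = "Synthetic phase 3 study.",
                        previous_recommendations = "Continue unchanged."))
  list(trial = trial, cfg = cfg)
}

quiet_build <- function(...) suppressMessages(suppressWarnings(buildReport(...)))

test_that("the report contains every section kind with a matching TOC", {
  fx <- report_fixture()
  out <- withr::local_tempdir()
  res <- quiet_build(fx$trial, fx$cfg, out)
  ids <- res$manifest$sections
  expect_equal(ids, c("front_matter", "baseline", "adverse_events",
                      "laboratory", "vitals", "profiles", "appendix"))
  # TOC entries match emitted sections one-to-one, with increasing pages
  expect_equal(res$manifest$toc$id, ids)
  expect_true(all(diff(res$manifest$toc$page) > 0))
  expect_true(file.size(res$paths["pdf"]) > 0)

  # HTML TOC anchors resolve to emitted section headings
  doc <- xml2::read_html(res$paths["html"])
  hrefs <- sub("^#", "", xml2::xml_attr(
    xml2::xml_find_all(doc, "//ul[@class='toc']/li/a"), "href"))
  anchors <- xml2::xml_attr(xml2::xml_find_all(doc, "//h2[@id]"), "id")
  expect_equal(hrefs, setdiff(anchors, "toc"))

  # pages in the PDF equal the pagination the manifest records
  pdf_pages <- length(grep("/Type /Page[^s]",
                           readLines(res$paths["pdf"], warn = FALSE),
                           useBytes = TRUE))
  expect_equal(pdf_pages, res$manifest$n_pages)
})

test_that("toggling a section removes both the section and its TOC entry", {
  fx <- report_fixture()
  fx$cfg$include_vitals <- FALSE
  fx$cfg$include_appendix <- FALSE
  out <- withr::local_tempdir()
  res <- quiet_build(fx$trial, fx$cfg, out)
  expect_false("vitals" %in% res$manifest$sections)
  expect_false("vitals" %in% res$manifest$toc$id)
  expect_false("appendix" %in% res$manifest$sections)
})

test_that("an empty AE table yields explicit no-event statements", {
  cfg0 <- recovery_config(seed = 5, n_per_arm = 20, n_null = 1,
                          h_active = 0, h_ref = 0, h_null = 0)
  trial <- generateTrial(cfg0)
  rcfg <- reportConfig(comparisons = list(c("Active", "Placebo")),
                       lab_params = list())
  out <- withr::local_tempdir()
  res <- quiet_build(trial, rcfg, out)
  expect_true("adverse_events" %in% res$manifest$sections)
  html <- paste(readLines(res$paths["html"], warn = FALSE), collapse = "\n")
  expect_match(html, "No adverse events reported")
})

test_that("an invalid comparison fails before any rendering", {
  fx <- report_fixture()
  fx$cfg$comparisons <- list(c("High Dose", "NoSuchArm"))
  out <- file.path(withr::local_tempdir(), "never")
  expect_error(quiet_build(fx$trial, fx$cfg, out), "config error")
  expect_false(dir.exists(out))
})

test_that("arm relabeling hides true labels; default leaves them verbatim", {
  fx <- report_fixture()
  out1 <- withr::local_tempdir()
  res1 <- quiet_build(fx$trial, fx$cfg, out1)
  html1 <- paste(readLines(res1$paths["html"], warn = FALSE), collapse = "\n")
  expect_match(html1, "High Dose")   # unblinded by design

  fx$cfg$relabel_arms <- c("High Dose" = "Arm X", "Placebo" = "Arm Y")
  out2 <- withr::local_tempdir()
  res2 <- quiet_build(fx$trial, fx$cfg, out2)
  html2 <- paste(readLines(res2$paths["html"], warn = FALSE), collapse = "\n")
  expect_false(grepl("High Dose", html2))
  expect_match(html2, "Arm X")
})

test_that("identical cuts diff to an empty change summary; new SAEs surface", {
  fx <- report_fixture(seed = 72, n = 25)
  out1 <- withr::local_tempdir()
  res1 <- quiet_build(fx$trial, fx$cfg, out1)
  ch0 <- diffSincePrevious(res1$paths["manifest"], res1$paths["manifest"])
  expect_equal(lengths(ch0), c(new_subjects = 0L, new_aes = 0L,
                               new_lab_outliers = 0L,
                               new_profile_subjects = 0L))

  # add one new serious AE for a previously unremarkable subject
  trial2 <- fx$trial
  plain <- setdiff(trial2$subjects$subject_id,
                   selectProfileSubjects(trial2)$subject_id)[1]
  newae <- trial2$adverse_events[1, ]
  newae$subject_id <- plain
  newae$preferred_term <- "Myocardial infarction"
  newae$serious_flag <- TRUE
  newae$ctc_grade <- 4L
  trial2$adverse_events <- dplyr::bind_rows(trial2$adverse_events, newae)
  out2 <- withr::local_tempdir()
  res2 <- quiet_build(trial2, fx$cfg, out2,
                      previous_manifest = res1$paths["manifest"])
  ch <- diffSincePrevious(res2$manifest, res1$manifest)
  expect_equal(ch$new_aes, paste0(plain, ":Myocardial infarction"))
  expect_equal(ch$new_profile_subjects, plain)
  html <- paste(readLines(res2$paths["html"], warn = FALSE), collapse = "\n")
  expect_match(html, "What has changed since the previous DMC")

  bad <- res1$manifest
  bad$manifest_version <- 99L
  expect_error(diffSincePrevious(res1$manifest, bad), "version mismatch")
})

test_that("rebuilding from the same inputs is byte-stable", {
  fx <- report_fixture(seed = 73, n = 20)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  res1 <- quiet_build(fx$trial, fx$cfg, out1)
  res2 <- quiet_build(fx$trial, fx$cfg, out2)
  expect_equal(res1$manifest$artifacts$md5, res2$manifest$artifacts$md5)
  expect_equal(res1$manifest$toc, res2$manifest$toc)
})

test_that("YAML round trips for synth and report configuration", {
  y <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    arms = list(list(label = "A", n_subjects = 10),
                list(label = "B", n_subjects = 10)),
    reference_arm = "B", seed = 4,
    ae_models = list(list(preferred_term = "Nausea",
                          system_organ_class = "GI",
                          hazard_per_year = list(A = 0.3, B = 0.1),
                          serious_prob = 0.1,
                          grade_probs = c(.6, .3, .08, .015, .005)))), y)
  cfg <- readSynthConfig(y)
  expect_s3_class(cfg, "synth_config")
  trial <- generateTrial(cfg)
  expect_equal(nrow(trial$subjects), 20)

  r <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    comparisons = list(c("A", "B")),
    lab_params = list(),
    include_vitals = FALSE,
    grading_rules = list(list(param_code = "ALT", direction = "high",
                              thresholds = c(1, 1.5, 2, 5)))), r)
  rcfg <- readReportConfig(r)
  expect_s3_class(rcfg, "report_config")
  expect_false(rcfg$include_vitals)
  expect_s3_class(rcfg$grading_rules$ALT, "grading_rule")
})
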