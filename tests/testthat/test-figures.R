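test_that("the demographics panel shows one category and no p-values", {
  trial <- fixture_trial(seed = 51, n = 30)
  spec <- figDemographics(trial, c("age", "sex"))
  expect_s3_class(spec, "figure_spec")
  sexrows <- spec$data[spec$data$variable == "sex", ]
  expect_equal(nrow(sexrows), length(trial$arms))        # one bar per arm only
  expect_equal(unique(sexrows$category), "F")
  # no p-value appears anywhere in the spec
  expect_false(any(grepl("p-value|p value|p<|p =", spec$caption[
    !grepl("No baseline p-values", spec$caption)])))
  expect_match(spec$caption, "No baseline p-values")
  expect_match(spec$caption, "1.5 times the interquartile range")
  expect_false(any(grepl("p_value", names(spec$data))))
  expect_error(figDemographics(trial, "shoe_size"), "unknown variable")
})

test_that("the dot plot keeps supplied order and draws zero-incidence dots", {
  trial <- tiny_trial()
  inc <- aeIncidence(trial)
  ord <- orderTerms(inc, "Active")
  spec <- figAeDotplot(inc, ord, reference_arm = "Placebo")
  expect_equal(nrow(spec$data), nrow(inc))     # completeness: no dropping
  expect_equal(levels(spec$data$term), rev(ord))
  # Nausea has no Placebo events but its dot is drawn at 0
  z <- spec$data[spec$data$term == "Nausea" & spec$data$arm == "Placebo", ]
  expect_equal(z$x, 0)
  adj <- figAeDotplot(inc, ord, exposure_adjusted = TRUE)
  expect_true(adj$meta$exposure_adjusted)
  expect_equal(adj$data$x, adj$data$rate_per_100py)
})

test_that("the volcano figure annotates exactly the labeled records", {
  trial <- fixture_trial(seed = 52, n = 50)
  vs <- volcanoStats(trial, "High Dose", "Placebo")
  spec <- figVolcano(vs)
  expect_equal(nrow(spec$data), nrow(vs))
  expect_match(spec$caption, "Fisher exact")
  built <- ggplot2::ggplot_build(spec$plot)
  txt_layer <- built$data[[length(built$data)]]
  expect_setequal(txt_layer$label, vs$preferred_term[vs$labeled])
  # fdr mode never increases the y position
  fdr <- figVolcano(vs, y_mode = "fdr_p")
  expect_true(all(fdr$data$y <= spec$data$y + 1e-12))
  expect_match(fdr$caption, "Benjamini-Hochberg")
  rr <- figVolcano(volcanoStats(trial, "High Dose", "Placebo", "rate_ratio"))
  expect_match(rr$caption, "rate ratio")
})

test_that("lab box figure keeps every visit and annotates n including zero", {
  trial <- fixture_trial(seed = 53, n = 25)
  bs <- visitBoxStats(trial, "CK")
  # force an empty late visit in one arm
  drop <- trial$labs$param_code == "CK" & trial$labs$visit_index == 7 &
    trial$labs$subject_id %in%
      trial$subjects$subject_id[trial$subjects$arm == "Placebo"]
  trial$labs <- trial$labs[!drop, ]
  bs <- visitBoxStats(trial, "CK")
  spec <- figLabBoxes(bs, reference_arm = "Placebo")
  expect_equal(nrow(spec$data), nrow(bs))
  z <- spec$data[spec$data$arm == "Placebo" & spec$data$visit_index == 7, ]
  expect_equal(z$n, 0L)                       # n = 0 still annotated
  expect_match(spec$caption, "1.5 times the interquartile range")
  expect_match(spec$caption, "number of subjects")
})

test_that("prevalence figure carries the n annotation for every arm/visit", {
  trial <- fixture_trial(seed = 54, n = 25)
  prev <- abnormalPrevalence(trial, "CK", side = "high")
  spec <- figAbnormalPrevalence(prev, side = "high")
  expect_equal(nrow(spec$data), nrow(prev))
  expect_match(spec$caption, "Denominator")
})

test_that("spaghetti annotations equal the selected set, limits honest", {
  trial <- fixture_trial(seed = 55, n = 40)
  sel <- unique(selectOutlierSubjects(trial, "CK", multiplier = 3)$subject_id)
  spec <- figSpaghetti(trial, "CK", selected = sel, show_limits = TRUE)
  expect_setequal(spec$meta$selected, sel)
  # CK limits are subject-jittered: lines suppressed, caption says so
  expect_false(spec$meta$common_limits)
  expect_match(spec$caption, "suppressed")
  # CHOL has common limits: no suppression note
  spec2 <- figSpaghetti(trial, "CHOL", selected = character(),
                        show_limits = TRUE)
  expect_true(spec2$meta$common_limits)
  expect_match(spec2$caption, "common limits")
  # empty selection: all-context figure
  spec3 <- figSpaghetti(trial, "CK", selected = character())
  expect_equal(length(spec3$meta$selected), 0)
  expect_error(figSpaghetti(trial, "CK", selected = "NOBODY"))
})

test_that("shift scatter draws one point per pair and the limit lines", {
  trial <- fixture_trial(seed = 56, n = 30)
  pairs <- shiftPairs(trial, "CHOL")
  spec <- figShiftScatter(pairs, lln = 2.0, uln = 6.2)
  expect_equal(nrow(spec$data), nrow(pairs))
  expect_match(spec$caption, "limits of normal")
  nolim <- figShiftScatter(pairs)
  expect_match(nolim$caption, "suppressed")
})

test_that("rendered figures are byte-identical across repeated renders", {
  trial <- fixture_trial(seed = 57, n = 20)
  spec <- figVolcano(volcanoStats(trial, "High Dose", "Placebo"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- renderFigure(spec, file.path(d1, "fig"))
  f2 <- renderFigure(spec, file.path(d2, "fig"))
  for (fmt in c("svg", "csv")) {
    expect_identical(readBin(f1[fmt], "raw", file.size(f1[fmt])),
                     readBin(f2[fmt], "raw", file.size(f2[fmt])),
                     info = fmt)
  }
  expect_true(file.size(f1["png"]) > 0)
})
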