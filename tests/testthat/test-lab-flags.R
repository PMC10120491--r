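test_that("flagAbnormal uses strict limits and resolves missing ones", {
  expect_equal(flagAbnormal(40, 7, 40), "normal")      # at ULN: normal
  expect_equal(flagAbnormal(48, 7, 40), "high")        # 1.2 x ULN
  expect_equal(flagAbnormal(5, 7, 40), "low")
  expect_equal(flagAbnormal(5, 7, NA), "low")          # low-side evaluable
  expect_equal(flagAbnormal(30, 7, NA), "unknown")     # high-side undecidable
  expect_equal(flagAbnormal(30, NA, 40), "unknown")    # low-side undecidable
  expect_equal(flagAbnormal(NA, 7, 40), "unknown")
})

test_that("ctcGrade picks the highest exceeded threshold, strictly", {
  rule <- gradingRule("ALT", "high", c(1.0, 1.5, 2.0, 5.0))
  uln <- 40
  expect_equal(ctcGrade(2.5 * uln, NA, uln, rule), 3L)
  expect_equal(ctcGrade(uln, NA, uln, rule), 0L)        # boundary: not > ULN
  expect_equal(ctcGrade(6 * uln, NA, uln, rule), 4L)
  expect_true(is.na(ctcGrade(100, NA, NA, rule)))       # limit required
  low <- gradingRule("HGB", "low", c(0.9, 0.7, 0.5, 0.3))
  expect_equal(ctcGrade(0.6 * 120, 120, NA, low), 2L)
  expect_equal(ctcGrade(0.2 * 120, 120, NA, low), 4L)
})

test_that("grading thresholds must be strictly monotone", {
  expect_error(gradingRule("X", "high", c(1, 1, 2, 3)), "increasing")
  expect_error(gradingRule("X", "low", c(1, 2, 3, 4)), "decreasing")
})

test_that("flagAbnormal and ctcGrade are monotone in the value", {
  rule <- gradingRule("P", "high", c(1, 2, 4, 8))
  set.seed(11)
  for (i in 1:30) {
    v <- sort(runif(12, 0, 12))
    g <- ctcGrade(v, NA, 1, rule)
    expect_true(all(diff(g) >= 0))
    rank_flag <- c(low = 0, normal = 1, high = 2)
    f <- rank_flag[flagAbnormal(v, 0.5, 1)]
    expect_true(all(diff(f) >= 0))
  }
})

test_that("visitBoxStats reproduces the worked example and edge cases", {
  trial <- tiny_trial()
  trial$labs <- tibble(
    subject_id = c("A1", "A2", "A3", "A4", "A1"),
    param_code = "ALT", param_name = "ALT", visit_index = 1L,
    visit_name = "W2", day = 14L, value = c(1, 2, 3, 4, 100),
    unit = "U/L", lln = 7, uln = 40, baseline_flag = FALSE)
  bs <- visitBoxStats(trial, "ALT")
  row <- bs[bs$arm == "Active" & bs$visit_index == 1, ]
  expect_equal(row$q1, 2)
  expect_equal(row$median, 3)
  expect_equal(row$q3, 4)
  expect_equal(row$whisker_hi, 4)   # fence 4 + 3 = 7; last point within is 4
  expect_equal(row$outlier_values[[1]], 100)
  # the Placebo row is kept with n = 0 and missing statistics
  plc <- bs[bs$arm == "Placebo" & bs$visit_index == 1, ]
  expect_equal(plc$n, 0L)
  expect_true(is.na(plc$median))
})

test_that("a single value collapses the box to a point", {
  trial <- tiny_trial()
  trial$labs <- trial$labs[1, ]
  bs <- visitBoxStats(trial, "ALT")
  row <- bs[bs$n > 0, ]
  expect_equal(row$q1, row$median)
  expect_equal(row$median, row$q3)
  expect_equal(row$whisker_lo, row$whisker_hi)
  expect_equal(length(row$outlier_values[[1]]), 0)
})

test_that("box statistics match the sort-based oracle on small integer sets", {
  # all multisets of {0..4} of sizes 1..6
  for (n in 1:6) {
    sets <- utils::combn(seq_len(n + 4) - 1, n)  # combinations of 0..(n+3)
    for (j in seq_len(ncol(sets))) {
      x <- sets[, j] %% 5
      o <- oracle_box(x)
      got <- dmcreport:::.box5(x)
      expect_equal(got$q1, o$q1)
      expect_equal(got$median, o$median)
      expect_equal(got$q3, o$q3)
      expect_equal(got$whisker_lo, o$whisker_lo)
      expect_equal(got$whisker_hi, o$whisker_hi)
      expect_equal(got$outliers, o$outliers)
    }
  }
})

test_that("quartiles commute with the log transform at order statistics", {
  # linear-interpolation quantiles hit order statistics exactly when
  # (n - 1) * p is an integer; there the monotone-transform invariance that
  # justifies the log-display contract is exact
  trial <- fixture_trial(seed = 4, n = 20)
  x <- trial$labs$value[trial$labs$param_code == "CK" &
                          trial$labs$visit_index == 0]
  x <- x[!is.na(x)][1:9]  # n = 9: quartile indices are integers
  for (p in c(.25, .5, .75)) {
    expect_equal(oracle_quantile(log(x), p), log(oracle_quantile(x, p)),
                 tolerance = 1e-12)
  }
  # between order statistics the discrepancy is bounded and tiny relative
  # to the value, so the display contract still holds to plotting accuracy
  x8 <- x[1:8]
  for (p in c(.25, .5, .75)) {
    expect_lt(abs(oracle_quantile(log(x8), p) - log(oracle_quantile(x8, p))),
              1e-2)
  }
})

test_that("abnormalPrevalence counts evaluable subjects per side", {
  trial <- tiny_trial()
  # at visit 1: A1=60 (high), A2=22 (normal) in Active; B1=80 (high) Placebo
  prev <- abnormalPrevalence(trial, "ALT", side = "high")
  a1 <- prev[prev$arm == "Active" & prev$visit_index == 1, ]
  expect_equal(a1$n, 2L)
  expect_equal(a1$n_abnormal, 1L)
  expect_equal(a1$percent, 50)
  # 'either' never double counts one measurement
  both <- abnormalPrevalence(trial, "ALT", side = "either")
  expect_true(all(both$n_abnormal <= both$n))
  # all limits missing -> nobody evaluable
  t2 <- trial
  t2$labs$lln <- NA_real_
  t2$labs$uln <- NA_real_
  prev2 <- abnormalPrevalence(t2, "ALT", side = "either")
  expect_true(all(prev2$n == 0))
})

test_that("outlier selection is strict at the multiplier boundary", {
  trial <- tiny_trial()
  trial$labs$value[trial$labs$subject_id == "A1" &
                     trial$labs$visit_index == 1] <- 3.0 * 40  # exactly 3x
  trial$labs$value[trial$labs$subject_id == "B1" &
                     trial$labs$visit_index == 1] <- 3.5 * 40
  sel <- selectOutlierSubjects(trial, "ALT", multiplier = 3)
  expect_false("A1" %in% sel$subject_id)   # exactly 3 x ULN: not selected
  expect_true("B1" %in% sel$subject_id)
  expect_match(sel$reason[sel$subject_id == "B1"], "3xULN")
})

test_that("outlier selection recovers the generator's injected subjects", {
  for (seed in c(31, 32)) {
    trial <- fixture_trial(seed = seed, n = 60)
    gt <- attr(trial, "ground_truth")
    injected <- sort(unique(gt$lab_outliers$subject_id[
      gt$lab_outliers$param_code == "CK"]))
    sel <- sort(unique(selectOutlierSubjects(trial, "CK",
                                             multiplier = 3)$subject_id))
    expect_equal(sel, injected)
  }
})

test_that("shiftPairs yields one pair per eligible subject", {
  trial <- tiny_trial()
  pairs <- shiftPairs(trial, "ALT")
  expect_equal(nrow(pairs), 3)                  # A1, A2, B1 all eligible
  expect_equal(anyDuplicated(pairs$subject_id), 0)
  a1 <- pairs[pairs$subject_id == "A1", ]
  expect_equal(a1$baseline_value, 30)
  expect_equal(a1$post_value, 60)               # worst case = max
  expect_equal(a1$baseline_abnormal, "normal")
  expect_equal(a1$post_abnormal, "high")
  last <- shiftPairs(trial, "ALT", post_rule = "last_value")
  expect_equal(last$post_value[last$subject_id == "A1"], 45)

  # subject with no post-baseline value is excluded, not an error
  t2 <- trial
  t2$labs <- t2$labs[!(t2$labs$subject_id == "A2" & !t2$labs$baseline_flag), ]
  expect_equal(nrow(shiftPairs(t2, "ALT")), 2)
})

test_that("the shift table reconstructed from pairs conserves subjects", {
  for (seed in c(41, 42)) {
    trial <- fixture_trial(seed = seed, n = 40)
    for (pc in c("CHOL", "CK")) {
      pairs <- shiftPairs(trial, pc)
      tab <- shiftTable(pairs)
      expect_equal(sum(tab$n), nrow(pairs))
    }
  }
})
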