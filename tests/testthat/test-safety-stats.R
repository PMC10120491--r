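test_that("fisherTwoSided reproduces hand-enumerated tables", {
  expect_equal(fisherTwoSided(0, 5, 0, 5), 1)            # degenerate margin
  expect_equal(fisherTwoSided(5, 0, 0, 5), 2 / 252)      # only a=0 and a=5 as extreme
  expect_equal(fisherTwoSided(3, 1, 1, 3), 34 / 70)      # masses {1,16,36,16,1}/70
  expect_true(is.na(fisherTwoSided(0, 0, 0, 0)))
})

test_that("fisherTwoSided agrees with the enumeration oracle and fisher.test", {
  set.seed(101)
  for (i in 1:150) {
    cells <- as.integer(rmultinom(1, sample(1:30, 1), prob = runif(4)))
    p <- fisherTwoSided(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p, oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    m <- matrix(cells, 2, byrow = TRUE)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-7,
                 info = paste(cells, collapse = ","))
  }
})

test_that("bhAdjust implements the step-up definition", {
  expect_equal(bhAdjust(0.04), 0.04)                       # m = 1 identity
  expect_equal(bhAdjust(rep(0.05, 4)), rep(0.05, 4))       # equal values fixed
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("bhAdjust matches p.adjust and satisfies its invariants", {
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p))                    # never below raw
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in p rank
  }
})

test_that("rateRatio applies continuity only at zero cells and is symmetric", {
  expect_equal(rateRatio(4, 2, 2, 2), 2)
  expect_equal(rateRatio(0, 1, 2, 1), 0.5 / 2.5)
  expect_error(rateRatio(1, 0, 1, 1), "person-years")
  set.seed(3)
  for (i in 1:25) {
    n1 <- sample(1:20, 1); n2 <- sample(1:20, 1)
    py1 <- runif(1, .5, 10); py2 <- runif(1, .5, 10)
    expect_equal(rateRatio(n1, py1, n2, py2) * rateRatio(n2, py2, n1, py1), 1)
    # person-time unit invariance
    k <- runif(1, 0.1, 40)
    expect_equal(rateRatio(n1, py1 * k, n2, py2 * k),
                 rateRatio(n1, py1, n2, py2))
  }
})

test_that("aeIncidence counts subjects once per term and scales by exposure", {
  trial <- tiny_trial()
  inc <- aeIncidence(trial)
  nau <- inc[inc$preferred_term == "Nausea" & inc$arm == "Active", ]
  expect_equal(nau$n_subjects_with_event, 2)   # A1 (3 events) counts once
  expect_equal(nau$n_events, 4)
  expect_equal(nau$n_at_risk, 4)
  expect_equal(nau$percent, 50)
  expect_equal(nau$person_years, 4 * 180 / 365.25)
  expect_equal(nau$rate_per_100py, 100 * 2 / (4 * 180 / 365.25))
  # zero-incidence record still present for the other arm
  nau_p <- inc[inc$preferred_term == "Nausea" & inc$arm == "Placebo", ]
  expect_equal(nau_p$n_subjects_with_event, 0)
  expect_equal(nau_p$percent, 0)
})

test_that("incidence rolls up to system organ class", {
  trial <- tiny_trial()
  soc <- aeIncidence(trial, group_by = "system_organ_class")
  gi <- soc[soc$system_organ_class == "Gastrointestinal disorders" &
              soc$arm == "Active", ]
  expect_equal(gi$n_subjects_with_event, 2)
  expect_equal(gi$n_events, 4)
  expect_false("preferred_term" %in% names(soc))
  expect_true("Nervous system disorders" %in% orderTerms(soc, "Placebo"))
})

test_that("incidence filters restrict events and unknown arms error", {
  trial <- tiny_trial()
  ser <- aeIncidence(trial, filters = list(serious_flag = TRUE))
  expect_equal(sum(ser$n_subjects_with_event), 1)
  fun <- aeIncidence(trial, filters = function(d) d$ctc_grade >= 3)
  expect_equal(sum(fun$n_subjects_with_event), 1)
  expect_error(aeIncidence(trial, arms = c("Active", "NoSuchArm")),
               "unknown arm")
})

test_that("the treatment-emergent window is applied and configurable", {
  trial <- tiny_trial()
  trial$adverse_events <- trial$adverse_events[1, ] |>
    dplyr::mutate(onset_day = 180L + 40L)  # 40 days after last dose
  trial$cutoff_day <- 365L
  expect_equal(nrow(aeIncidence(trial, te_window = 30)), 0)
  expect_equal(sum(aeIncidence(trial, te_window = 60)$n_subjects_with_event), 1)
})

test_that("orderTerms applies the documented tie-breaks", {
  mk <- function(term, arm, pct) tibble(
    preferred_term = term, system_organ_class = "S", arm = arm,
    n_subjects_with_event = 1L, n_at_risk = 10L, percent = pct,
    n_events = 1L, person_years = 1, rate_per_100py = pct)
  rec <- bind_rows(
    mk("A", "X", 10), mk("B", "X", 30), mk("C", "X", 20),
    mk("A", "Y", 5), mk("B", "Y", 8), mk("C", "Y", 1))
  expect_equal(orderTerms(rec, "X"), c("B", "C", "A"))
  # tie in the ordering arm resolved by the comparator arm
  rec2 <- bind_rows(mk("A", "X", 10), mk("B", "X", 10),
                    mk("A", "Y", 5), mk("B", "Y", 8))
  expect_equal(orderTerms(rec2, "X"), c("B", "A"))
  # everything tied: alphabetical
  rec3 <- bind_rows(mk("B", "X", 10), mk("A", "X", 10),
                    mk("B", "Y", 5), mk("A", "Y", 5))
  expect_equal(orderTerms(rec3, "X"), c("A", "B"))
})

test_that("volcanoStats handles balanced terms, single terms and labels", {
  trial <- tiny_trial()
  # Headache: 1/4 in Placebo (B1), 0/4 in Active
  vs <- volcanoStats(trial, "Active", "Placebo")
  expect_true(all(vs$fdr_p >= vs$p_value))
  hd <- vs[vs$preferred_term == "Headache", ]
  expect_equal(hd$estimate, -25)
  expect_equal(hd$p_value, 1)  # 0/4 vs 1/4 enumerates to 1
  expect_false(hd$labeled)

  # single term: fdr equals raw p
  only <- trial
  only$adverse_events <- trial$adverse_events[
    trial$adverse_events$preferred_term == "Nausea", ]
  vs1 <- volcanoStats(only, "Active", "Placebo")
  expect_equal(nrow(vs1), 1)
  expect_equal(vs1$fdr_p, vs1$p_value)

  # top-k labeling
  vs2 <- volcanoStats(trial, "Active", "Placebo", label_rule = list(top_k = 1))
  expect_equal(sum(vs2$labeled), 1)
  expect_equal(vs2$preferred_term[vs2$labeled], vs2$preferred_term[1])
})

test_that("volcanoStats is antisymmetric under arm swap", {
  for (seed in c(21, 22, 23)) {
    trial <- fixture_trial(seed = seed, n = 30)
    ab <- volcanoStats(trial, "High Dose", "Placebo")
    ba <- volcanoStats(trial, "Placebo", "High Dose")
    m <- merge(as.data.frame(ab), as.data.frame(ba), by = "preferred_term")
    expect_equal(m$estimate.x, -m$estimate.y)
    expect_equal(m$p_value.x, m$p_value.y)
    rr_ab <- volcanoStats(trial, "High Dose", "Placebo", "rate_ratio")
    rr_ba <- volcanoStats(trial, "Placebo", "High Dose", "rate_ratio")
    m2 <- merge(as.data.frame(rr_ab), as.data.frame(rr_ba), by = "preferred_term")
    expect_equal(m2$estimate.x, 1 / m2$estimate.y)
  }
})
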