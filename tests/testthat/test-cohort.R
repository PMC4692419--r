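# FACT-Ntx phenotyping and cohort-summary arithmetic.

test_that("percent worsening is the signed fractional score drop", {
  expect_equal(percent_worsening(40, 32), 0.20)
  expect_equal(percent_worsening(40, 40), 0.0)
  expect_equal(percent_worsening(44, 33), 0.25)
  expect_lt(percent_worsening(40, 41), 0)       # improvement is negative
  expect_error(percent_worsening(0, 10), "undefined")
  expect_error(percent_worsening(50, 10), "\\[0, 44\\]")
  expect_error(percent_worsening(40, 45), "\\[0, 44\\]")
})

make_assessments <- function(baseline, followups, id = "P1") {
  tibble::tibble(
    patient_id = id,
    timepoint = c("baseline", c("completion", "month6", "month12")[seq_along(followups)]),
    score = as.integer(c(baseline, followups)))
}

test_that("CIPN classification follows the worst available follow-up", {
  res <- classify_cipn(make_assessments(40, c(34, 31, 36)))
  expect_equal(as.character(res$group), "group1_cipn")
  expect_equal(res$max_worsening, (40 - 31) / 40)

  res <- classify_cipn(make_assessments(40, c(40, 41, 39)))
  expect_equal(as.character(res$group), "group2_stable")
  expect_equal(res$max_worsening, (40 - 39) / 40)

  # boundary: exactly 20% is CIPN (inclusive), just below is stable
  expect_equal(as.character(classify_cipn(make_assessments(40, 32))$group),
               "group1_cipn")
  expect_equal(as.character(classify_cipn(make_assessments(41, 33))$group),
               "group2_stable")
})

test_that("classification rejects missing baseline or follow-ups", {
  no_base <- tibble::tibble(patient_id = "P1", timepoint = "month6",
                            score = 30L)
  expect_error(classify_cipn(no_base), "baseline")
  only_base <- tibble::tibble(patient_id = "P1", timepoint = "baseline",
                              score = 30L)
  expect_error(classify_cipn(only_base), "follow-up")
  dup <- tibble::tibble(patient_id = "P1",
                        timepoint = c("baseline", "month6", "month6"),
                        score = c(40L, 30L, 31L))
  expect_error(classify_cipn(dup), "duplicated")
})

test_that("classification is order-invariant and monotone in follow-ups", {
  set.seed(11)
  for (i in 1:25) {
    base <- sample(20:44, 1)
    fu <- sample(0:44, 3, replace = TRUE)
    a <- make_assessments(base, fu)
    shuffled <- a[c(1, 1 + sample(3)), ]
    expect_identical(classify_cipn(a)$group, classify_cipn(shuffled)$group)
    # lowering any follow-up never flips CIPN back to stable
    if (as.character(classify_cipn(a)$group) == "group1_cipn") {
      j <- sample(3, 1)
      fu2 <- fu
      fu2[j] <- max(0, fu2[j] - sample(0:5, 1))
      expect_equal(as.character(classify_cipn(make_assessments(base, fu2))$group),
                   "group1_cipn")
    }
  }
})

test_that("pooled means reproduce the published overall column", {
  expect_equal(round(pooled_mean(c(48.5, 50.3), c(8, 9)), 1), 49.5)
  expect_equal(round(pooled_mean(c(29.38, 28.22), c(8, 9)), 1), 28.8)
  expect_equal(pooled_mean(5.0, 3), 5.0)
  expect_error(pooled_mean(numeric(0), integer(0)), "at least one")
  expect_error(pooled_mean(c(1, 2), c(1, 0)), ">= 1")
  # identical group means pool to that mean for any sizes
  expect_equal(pooled_mean(c(7.3, 7.3, 7.3), c(2, 9, 1)), 7.3)
})

table1_cohort <- function() {
  race <- c(rep("white", 6), rep("black", 2),      # group 1: 6/8 white
            rep("white", 3), rep("black", 6))      # group 2: 3/9 white
  patients <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:17),
    age_years = c(rep(48.5, 8), rep(50.3, 9)),
    race = factor(race, levels = c("white", "black", "asian")))
  labels <- tibble::tibble(
    patient_id = patients$patient_id,
    group = rep(c("group1_cipn", "group2_stable"), c(8, 9)))
  list(patients = patients, labels = labels)
}

test_that("cohort summary reproduces per-group and overall percentages", {
  fx <- table1_cohort()
  s <- summarize_cohort(fx$patients, fx$labels)
  race <- dplyr::filter(s$categorical, variable == "race")
  expect_equal(race$group1_pct[race$level == "white"], 75.00)
  expect_equal(race$total_pct[race$level == "white"], 52.94)
  expect_equal(race$total_n[race$level == "white"], 9)
  # empty factor level reported as 0 / 0.00%
  expect_equal(race$total_n[race$level == "asian"], 0)
  expect_equal(race$total_pct[race$level == "asian"], 0.00)
  # group percentages sum to 100 up to rounding
  expect_equal(sum(race$group1_pct), 100, tolerance = 0.011)
  expect_equal(sum(race$group2_pct), 100, tolerance = 0.011)
  expect_equal(glance(s)$n_total, 17)
  # continuous summary carries the group means
  age <- dplyr::filter(s$continuous, variable == "age_years",
                       statistic == "mean")
  expect_equal(age$group1, 48.5)
  expect_equal(age$group2, 50.3)
  expect_equal(round(age$total, 1), 49.5)
})

test_that("cohort summary refuses unlabeled patients", {
  fx <- table1_cohort()
  expect_error(summarize_cohort(fx$patients, fx$labels[-1, ]), "unlabeled")
})

test_that("cohort CSV and summary CSV round-trip", {
  cfg <- sim_config(seed = 42)
  cohort <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort$patients, cohort$assessments, path)
  back <- read_cohort(path)
  expect_equal(back$assessments$score, cohort$assessments$score)
  expect_equal(sort(unique(back$patients$patient_id)),
               sort(cohort$patients$patient_id))
  s <- summarize_cohort(cohort$patients,
                        classify_cipn(cohort$assessments))
  out <- withr::local_tempfile(fileext = ".csv")
  write_cohort_summary(s, out)
  re <- readr::read_csv(out, show_col_types = FALSE)
  expect_true(all(c("variable", "level", "group1_n", "total_pct") %in% names(re)))
})
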