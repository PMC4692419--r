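# Cohort phenotyping: FACT-Ntx trajectories, CIPN classification, and the
# demographic summary table.

#' Validate a FACT-Ntx assessment table
#'
#' Assessments are patient-reported neurotoxicity scores on the FACT-Ntx
#' subscale (range 0-44, higher = less neuropathy), one row per patient and
#' time point.
#'
#' @param assessments A data frame with columns `patient_id`, `timepoint`
#'   (one of `"baseline"`, `"completion"`, `"month6"`, `"month12"`) and
#'   `score` (integer in 0-44).
#' @return The validated assessments as a tibble (invisibly usable in a
#'   pipe), with `timepoint` as a factor.
#' @export
validate_assessments <- function(assessments) {
  stop_if_missing_cols(assessments, c("patient_id", "timepoint", "score"),
                       "assessment table")
  out <- as_tibble(assessments)
  bad_tp <- setdiff(unique(as.character(out$timepoint)), fact_timepoints)
  if (length(bad_tp) > 0) {
    abort(sprintf("unknown timepoint(s): %s", paste(bad_tp, collapse = ", ")))
  }
  score <- out$score
  if (any(is.na(score)) || any(score < 0 | score > 44) ||
      any(score != floor(score))) {
    abort("FACT-Ntx scores must be integers within [0, 44]")
  }
  dup <- out %>%
    count(.data$patient_id, .data$timepoint) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicated assessment(s) for patient/timepoint: %s",
                  paste(dup$patient_id, dup$timepoint, sep = "/",
                        collapse = ", ")))
  }
  out$timepoint <- factor(as.character(out$timepoint), levels = fact_timepoints)
  out
}

#' Fractional worsening of a FACT-Ntx score relative to baseline
#'
#' Worsening is `(baseline - followup) / baseline`: positive values mean the
#' score dropped (more neuropathy), negative values mean improvement. A
#' baseline of zero has no defined percent change and is rejected.
#'
#' @param baseline,followup FACT-Ntx scores (vectors recycle as usual).
#' @return A numeric vector of fractional changes.
#' @examples
#' percent_worsening(40, 32)  # 0.20, the classification boundary
#' percent_worsening(44, 33)  # 0.25
#' @export
percent_worsening <- function(baseline, followup) {
  if (any(baseline < 0 | baseline > 44) || any(followup < 0 | followup > 44)) {
    abort("FACT-Ntx scores must lie within [0, 44]")
  }
  if (any(baseline == 0)) {
    abort("baseline score of 0: percent worsening is undefined; review manually")
  }
  (baseline - followup) / baseline
}

#' Classify patients as CIPN or stable from their FACT-Ntx trajectory
#'
#' A patient is labelled `group1_cipn` when the worst (maximum) fractional
#' worsening from baseline to any available follow-up (completion of taxane
#' therapy, 6 months, or 12 months) reaches the threshold, by default >= 20%.
#' Otherwise the patient is `group2_stable`. Missing intermediate follow-ups
#' are allowed; a patient with no baseline or no follow-up at all is an
#' error, never silently stable.
#'
#' @param assessments An assessment table (see [validate_assessments()]).
#' @param threshold Fractional worsening that defines CIPN (default 0.2,
#'   inclusive).
#' @return A tibble with one row per patient: `patient_id`,
#'   `baseline_score`, `max_worsening`, and `group` (factor with levels
#'   `group1_cipn`, `group2_stable`).
#' @export
classify_cipn <- function(assessments, threshold = 0.2) {
  a <- validate_assessments(assessments)
  split_pt <- split(a, a$patient_id)
  rows <- purrr::map(split_pt, function(d) {
    base <- d$score[d$timepoint == "baseline"]
    if (length(base) == 0) {
      abort(sprintf("patient %s has no baseline assessment", d$patient_id[1]))
    }
    fu <- d$score[d$timepoint != "baseline"]
    if (length(fu) == 0) {
      abort(sprintf("patient %s has no follow-up assessment", d$patient_id[1]))
    }
    worst <- max(percent_worsening(base, fu))
    tibble(patient_id = d$patient_id[1],
           baseline_score = base,
           max_worsening = worst,
           group = if (worst >= threshold) "group1_cipn" else "group2_stable")
  })
  out <- bind_rows(rows)
  out$group <- factor(out$group, levels = group_levels)
  arrange(out, .data$patient_id)
}

#' Size-weighted pooled mean of per-group means
#'
#' Combines group-level means into the overall mean the cohort table prints
#' in its total column: `sum(n_i * mean_i) / sum(n_i)`.
#'
#' @param means Numeric vector of group means.
#' @param ns Integer vector of group sizes (all >= 1).
#' @return The pooled mean (a single number, unrounded).
#' @examples
#' pooled_mean(c(48.5, 50.3), c(8, 9))  # 49.5 to one decimal
#' @export
pooled_mean <- function(means, ns) {
  if (length(means) == 0) abort("pooled_mean needs at least one group")
  if (length(means) != length(ns)) abort("means and ns must have equal length")
  if (any(ns < 1)) abort("all group sizes must be >= 1")
  sum(ns * means) / sum(ns)
}

#' Summarize cohort demographics by phenotype group
#'
#' Reproduces the layout of a baseline-characteristics table: per-group and
#' overall counts with percentages (denominator = group size, reported to
#' two decimals) for every categorical variable, and means/SDs for the
#' continuous variables (by default age and BMI).
#'
#' @param patients A data frame with one row per patient, a `patient_id`
#'   column, categorical demographic columns (character or factor) and
#'   numeric columns.
#' @param labels A data frame mapping `patient_id` to `group` (the output of
#'   [classify_cipn()] works directly). Every patient must be labelled.
#' @param continuous Names of numeric columns to summarise with mean/SD;
#'   defaults to all numeric columns other than identifiers.
#' @return An object of class `cohort_summary`: a list with `categorical`
#'   (tibble: variable, level, group1_n, group1_pct, group2_n, group2_pct,
#'   total_n, total_pct), `continuous` (tibble: variable, statistic, group1,
#'   group2, total) and `n` (named group sizes). Percentages are rounded to
#'   2 d.p.; raw counts are retained.
#' @export
summarize_cohort <- function(patients, labels, continuous = NULL) {
  stop_if_missing_cols(patients, "patient_id", "patient table")
  stop_if_missing_cols(labels, c("patient_id", "group"), "label table")
  unlabeled <- setdiff(patients$patient_id, labels$patient_id)
  if (length(unlabeled) > 0) {
    abort(sprintf("unlabeled patient(s): %s", paste(unlabeled, collapse = ", ")))
  }
  df <- left_join(as_tibble(patients),
                  select(as_tibble(labels), "patient_id", "group"),
                  by = "patient_id")
  df$group <- factor(as.character(df$group), levels = group_levels)

  n1 <- sum(df$group == "group1_cipn")
  n2 <- sum(df$group == "group2_stable")
  ntot <- nrow(df)

  value_cols <- setdiff(names(df), c("patient_id", "group"))
  is_num <- vapply(df[value_cols], is.numeric, logical(1))
  if (is.null(continuous)) continuous <- value_cols[is_num]
  categorical <- setdiff(value_cols, continuous)

  pct <- function(k, n) if (n == 0) 0 else round(100 * k / n, 2)

  cat_tab <- purrr::map_dfr(categorical, function(v) {
    levs <- if (is.factor(df[[v]])) levels(df[[v]]) else sort(unique(as.character(df[[v]])))
    purrr::map_dfr(levs, function(lv) {
      x <- as.character(df[[v]]) == lv
      k1 <- sum(x & df$group == "group1_cipn")
      k2 <- sum(x & df$group == "group2_stable")
      tibble(variable = v, level = lv,
             group1_n = k1, group1_pct = pct(k1, n1),
             group2_n = k2, group2_pct = pct(k2, n2),
             total_n = k1 + k2, total_pct = pct(k1 + k2, ntot))
    })
  })

  cont_tab <- purrr::map_dfr(continuous, function(v) {
    g1 <- df[[v]][df$group == "group1_cipn"]
    g2 <- df[[v]][df$group == "group2_stable"]
    tibble(variable = v,
           statistic = c("mean", "sd"),
           group1 = c(mean(g1), sd(g1)),
           group2 = c(mean(g2), sd(g2)),
           total = c(mean(df[[v]]), sd(df[[v]])))
  })

  structure(list(categorical = cat_tab, continuous = cont_tab,
                 n = c(group1_cipn = n1, group2_stable = n2, total = ntot)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d patients (%d CIPN, %d stable)\n",
              x$n[["total"]], x$n[["group1_cipn"]], x$n[["group2_stable"]]))
  print(x$categorical, n = Inf)
  if (nrow(x$continuous) > 0) print(x$continuous, n = Inf)
  invisible(x)
}

#' @rdname summarize_cohort
#' @param x A `cohort_summary` object.
#' @param ... Unused.
#' @method tidy cohort_summary
#' @export
tidy.cohort_summary <- function(x, ...) x$categorical

#' @rdname summarize_cohort
#' @method glance cohort_summary
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble(n_group1 = unname(x$n[["group1_cipn"]]),
         n_group2 = unname(x$n[["group2_stable"]]),
         n_total = unname(x$n[["total"]]))
}

# Cohort CSV I/O ------------------------------------------------------------

#' Read and write the long-format cohort CSV
#'
#' The cohort file holds one row per patient and assessment time point:
#' demographic columns (repeated across a patient's rows) plus `patient_id`,
#' `timepoint` and `fact_ntx`. UTF-8 with a header row.
#'
#' @param path File path.
#' @return `read_cohort()` returns a list with `patients` (one row per
#'   patient, demographics only) and `assessments` (patient_id, timepoint,
#'   score).
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stop_if_missing_cols(raw, c("patient_id", "timepoint", "fact_ntx"),
                       "cohort CSV")
  assessments <- validate_assessments(
    tibble(patient_id = raw$patient_id,
           timepoint = raw$timepoint,
           score = raw$fact_ntx))
  patients <- raw %>%
    select(-"timepoint", -"fact_ntx") %>%
    distinct()
  if (anyDuplicated(patients$patient_id) > 0) {
    abort("inconsistent demographics across a patient's rows")
  }
  list(patients = patients, assessments = assessments)
}

#' @rdname read_cohort
#' @param patients,assessments Tables as returned by [read_cohort()].
#' @export
write_cohort <- function(patients, assessments, path) {
  a <- validate_assessments(assessments)
  out <- left_join(mutate(a, timepoint = as.character(.data$timepoint)),
                   as_tibble(patients), by = "patient_id") %>%
    rename(fact_ntx = "score")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a cohort summary as CSV in the published-table layout
#'
#' Categorical rows carry counts and percentages; continuous variables are
#' appended as mean/sd rows with the percentage columns left empty.
#'
#' @param summary A `cohort_summary` object.
#' @param path Output file.
#' @export
write_cohort_summary <- function(summary, path) {
  stopifnot(inherits(summary, "cohort_summary"))
  cont <- summary$continuous %>%
    mutate(level = .data$statistic,
           group1_n = round(.data$group1, 2), group1_pct = NA_real_,
           group2_n = round(.data$group2, 2), group2_pct = NA_real_,
           total_n = round(.data$total, 2), total_pct = NA_real_) %>%
    select(all_of(names(summary$categorical)))
  readr::write_csv(bind_rows(summary$categorical, cont), path, progress = FALSE)
  invisible(path)
}
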