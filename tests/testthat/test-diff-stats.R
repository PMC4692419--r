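# Normalization, rank testing, BH adjustment, signature combination, PCA.

test_that("library-size normalization equalizes composition, not depth", {
  # 3x2 fixture: column 2 is column 1 with doubled counts
  vals <- matrix(c(2, 4, 6, 4, 8, 12), nrow = 3,
                 dimnames = list(c("A", "B", "C"), c("s1.T0", "s2.T0")))
  qm <- make_qm(vals, groups = c("group1_cipn", "group2_stable"))
  nn <- normalize_quant(qm)
  expect_equal(nn$values[, 1], nn$values[, 2])
  expect_true(nn$normalized)
  # identical columns stay identical
  vals2 <- matrix(c(1, 5, 1, 5), nrow = 2,
                  dimnames = list(c("A", "B"), c("s1.T0", "s2.T0")))
  qm2 <- make_qm(vals2, groups = c("group1_cipn", "group2_stable"))
  nn2 <- normalize_quant(qm2)
  expect_equal(nn2$values[, 1], nn2$values[, 2])
  # all-zero column is an error naming the sample
  vals3 <- matrix(c(1, 2, 0, 0), nrow = 2,
                  dimnames = list(c("A", "B"), c("s1.T0", "s2.T0")))
  expect_error(normalize_quant(make_qm(vals3, groups = c(NA, NA))), "s2.T0")
})

test_that("exact Mann-Whitney p-values match complete enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p_value, 0.10)
  expect_equal(mw$u, 0)
  expect_equal(mw$method, "exact")
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)
  expect_equal(mann_whitney(rep(2, 4), rep(2, 5))$u, 10)   # degenerate: n1*n2/2
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")

  set.seed(41)
  for (i in 1:30) {
    n_a <- sample(2:5, 1)
    n_b <- sample(2:5, 1)
    x <- sample(1000, n_a + n_b)               # distinct -> no ties
    p_pkg <- mann_whitney(x[1:n_a], x[-(1:n_a)])$p_value
    p_orc <- oracle_mann_whitney(x[1:n_a], x[-(1:n_a)])
    expect_equal(p_pkg, p_orc, tolerance = 1e-9)
  }
})

test_that("BH adjustment equals the min-over-suffix definition", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(43)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    # monotone in the p-ordering
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("run_track recovers a strongly planted effect and honors thresholds", {
  cfg <- sim_config(seed = 55, n_proteins = 60, n_differential = 5,
                    effect_log_fold = log(8), timepoints = "T0",
                    shared_peptide_fraction = 0)
  study <- simulate_study(cfg)
  labels <- classify_cipn(study$cohort$assessments)
  an <- suppressMessages(run_analysis(study$psms, study$proteome, labels,
                                      tracks = "protein", q_threshold = 0.3))
  planted <- study$truth$differential$accession
  expect_true(all(planted %in% an$protein_diff$selected))
  # recovered proteins carry the planted direction
  res <- an$protein_diff$results
  expect_equal(res$direction[match(planted, res$feature)],
               study$truth$differential$direction)
  # q_threshold 0 selects nothing
  zero <- run_track(an$protein_matrix, "T0", q_threshold = 0)
  expect_equal(length(zero$selected), 0)
  expect_error(run_track(an$protein_matrix, "T12"), "T12")
})

test_that("track results expose tidy/glance and selection bookkeeping", {
  vals <- matrix(rpois(40, 10) + rep(c(0, 30), each = 20), nrow = 4,
                 dimnames = list(sprintf("F%d", 1:4), sprintf("s%d.T0", 1:10)))
  qm <- make_qm(vals, groups = rep(c("group1_cipn", "group2_stable"), each = 5))
  td <- run_track(qm, "T0", q_threshold = 0.2)
  expect_s3_class(tidy(td), "tbl_df")
  expect_equal(glance(td)$n_features, nrow(td$results))
  expect_true(all(td$results$q_value >= td$results$p_value - 1e-12))
  expect_setequal(td$selected,
                  td$results$feature[td$results$q_value < 0.2])
})

test_that("signature combination obeys inclusion-exclusion", {
  a <- sprintf("PA%02d", 1:11)
  b <- c(a[1:10], sprintf("PB%02d", 1:26))      # overlap of 10, 36 total
  sig <- combine_tracks(a, b)
  expect_equal(length(sig$combined), 37)
  expect_equal(length(sig$overlap), 10)
  g <- glance(sig)
  expect_equal(g$n_combined, g$n_protein_track + g$n_peptide_track - g$n_overlap)

  expect_equal(length(combine_tracks(c("x", "y", "z"), c("u", "v", "w", "q"))$combined), 7)
  sub <- combine_tracks(c("x", "y"), c("x", "y", "z"))
  expect_equal(sub$combined, c("x", "y", "z"))  # A subset of B -> union is B

  set.seed(59)
  for (i in 1:20) {
    a <- sample(letters, sample(1:20, 1))
    b <- sample(letters, sample(1:20, 1))
    s <- combine_tracks(a, b)
    expect_equal(length(s$combined),
                 length(unique(a)) + length(unique(b)) - length(s$overlap))
  }
})

test_that("direction tallies cover the combined signature exactly", {
  res <- tibble::tibble(feature = c("p1", "p2", "p3", "p4"),
                        direction = c("higher_in_group2", "higher_in_group2",
                                      "tied", "higher_in_group1"))
  sig <- combine_tracks(c("p1", "p2"), c("p2", "p3", "p4"))
  tal <- direction_tally(res, sig)
  expect_equal(tal$higher_in_group2, 2)
  expect_equal(tal$tied, 1)
  expect_equal(tal$higher_in_group1 + tal$higher_in_group2 + tal$tied,
               length(sig$combined))
  expect_error(direction_tally(res[1:2, ], sig), "without a result")
})

test_that("PCA separates planted clusters and degrades sanely", {
  set.seed(61)
  n1 <- 5; n2 <- 6
  base <- matrix(rnorm(20 * (n1 + n2), sd = 0.3), nrow = 20)
  base[, seq_len(n1)] <- base[, seq_len(n1)] + 5   # distant tight cluster
  base <- abs(base)
  dimnames(base) <- list(sprintf("F%02d", 1:20),
                         sprintf("s%02d.T0", seq_len(n1 + n2)))
  qm <- make_qm(base, groups = rep(c("group1_cipn", "group2_stable"),
                                   c(n1, n2)), track = "peptide_areas")
  ps <- pca_separation(qm)
  expect_gt(ps$separation, 2)
  expect_s3_class(tidy(ps), "tbl_df")

  # permuted labels give much weaker separation, typically
  perms <- replicate(30, {
    qs <- qm
    qs$samples$group <- sample(qs$samples$group)
    pca_separation(qs)$separation
  })
  expect_lt(median(perms), ps$separation)

  # identical samples are degenerate
  same <- matrix(1, nrow = 3, ncol = 4,
                 dimnames = list(c("A", "B", "C"), sprintf("s%d.T0", 1:4)))
  expect_error(pca_separation(make_qm(same, track = "peptide_areas",
                                      groups = rep(c("group1_cipn",
                                                     "group2_stable"), 2))),
               "identical")
})

test_that("autoplot methods return ggplot objects", {
  vals <- matrix(rpois(60, 8) + rep(c(0, 12), each = 30), nrow = 6,
                 dimnames = list(sprintf("F%d", 1:6), sprintf("s%d.T0", 1:10)))
  qm <- make_qm(vals, groups = rep(c("group1_cipn", "group2_stable"), each = 5))
  td <- run_track(qm, "T0")
  expect_s3_class(ggplot2::autoplot(td), "ggplot")
  expect_s3_class(ggplot2::autoplot(pca_separation(normalize_quant(qm))), "ggplot")
  expect_s3_class(ggplot2::autoplot(combine_tracks(c("a", "b"), c("b", "c"))),
                  "ggplot")
})
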