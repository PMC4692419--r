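# Normalization, Mann-Whitney differential testing under BH FDR control,
# PCA separation, and the dual-track signature combination.

#' Normalize a quantification matrix
#'
#' Two steps: per-sample library-size scaling (each column is rescaled so
#' its total equals the median column total), then the variance-stabilizing
#' `ln(x + 1)` transform. Spectral counts and peak areas both pass through
#' the same procedure; the result is real-valued on the natural-log scale.
#'
#' @param qm A raw `quant_matrix`.
#' @return A `quant_matrix` with `normalized = TRUE`.
#' @export
normalize_quant <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  if (qm$normalized) return(qm)
  totals <- colSums(qm$values)
  if (any(totals == 0)) {
    abort(sprintf("all-zero sample column(s): %s",
                  paste(colnames(qm$values)[totals == 0], collapse = ", ")))
  }
  target <- median(totals)
  scaled <- sweep(qm$values, 2, target / totals, `*`)
  quant_matrix(log1p(scaled), qm$samples, track = qm$track, normalized = TRUE)
}

#' Mann-Whitney-Wilcoxon test between two small groups
#'
#' Two-sided rank-sum test. With no ties the p-value is exact (complete
#' enumeration of rank assignments, feasible at cohort scale: 8 vs 9 gives
#' choose(17, 8) = 24310 arrangements); with ties, mid-ranks with the
#' tie-corrected normal approximation and continuity correction are used.
#' When every value in both groups is identical the test is degenerate and
#' returns U = n_a * n_b / 2 with p = 1.
#'
#' @param a,b Numeric vectors of (normalized) values for the two groups.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`) mode; default
#'   `NULL` chooses exact whenever there are no ties.
#' @return A one-row tibble: `u` (the Mann-Whitney U for group `a`),
#'   `p_value`, `method`.
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  mw <- mw_stat(a, b, exact)
  tibble(u = mw$u, p_value = mw$p_value, method = mw$method)
}

# list-returning core shared by mann_whitney() and the run_track() loop
mw_stat <- function(a, b, exact = NULL) {
  if (length(a) == 0 || length(b) == 0) abort("both groups must be nonempty")
  if (length(unique(c(a, b))) == 1L) {
    return(list(u = length(a) * length(b) / 2, p_value = 1,
                method = "degenerate"))
  }
  ties <- any(duplicated(c(a, b)))
  ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  used_exact <- if (ties || isFALSE(exact)) FALSE
                else isTRUE(exact) || (length(a) < 50 && length(b) < 50)
  list(u = unname(ht$statistic), p_value = ht$p.value,
       method = if (used_exact) "exact" else "normal_approx")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment `q(i) = min_{j >= i} m * p(j) / j` on the sorted
#' p-values, mapped back to the input order and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie within [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Differential testing of one track at one time point
#'
#' Normalizes the matrix (unless already normalized or `normalize = FALSE`),
#' restricts it to one draw time point, tests every feature between the two
#' phenotype groups with [mann_whitney()], adjusts across all features of
#' the track with [bh_adjust()], and selects features with `q < q_threshold`
#' (strict). Direction is called from the group medians of the normalized
#' values; tied medians are `"tied"`.
#'
#' @param qm A `quant_matrix` whose sample table carries phenotype groups.
#' @param timepoint `"T0"` (baseline) or `"T12"` (endpoint).
#' @param q_threshold Selection threshold (default 0.2).
#' @param normalize Apply [normalize_quant()] first (default `TRUE`).
#' @param exact Passed to [mann_whitney()].
#' @return An object of class `track_diff` with per-feature results and the
#'   selected feature set; see [tidy.track_diff()] and
#'   [glance.track_diff()].
#' @export
run_track <- function(qm, timepoint = "T0", q_threshold = 0.2,
                      normalize = TRUE, exact = NULL) {
  stopifnot(inherits(qm, "quant_matrix"))
  timepoint <- match.arg(timepoint, draw_timepoints)
  if (normalize) qm <- normalize_quant(qm)
  keep <- qm$samples$timepoint == timepoint
  if (!any(keep)) abort(sprintf("no samples at timepoint %s", timepoint))
  samples <- qm$samples[keep, , drop = FALSE]
  vals <- qm$values[, samples$sample_col, drop = FALSE]
  g1 <- samples$group == group_levels[1]
  g2 <- samples$group == group_levels[2]
  if (sum(g1) < 2 || sum(g2) < 2) {
    abort("each phenotype group needs at least 2 samples")
  }
  nf <- nrow(vals)
  u <- p <- m1 <- m2 <- numeric(nf)
  method <- character(nf)
  for (i in seq_len(nf)) {
    mw <- mw_stat(vals[i, g1], vals[i, g2], exact = exact)
    u[i] <- mw$u
    p[i] <- mw$p_value
    method[i] <- mw$method
    m1[i] <- median(vals[i, g1])
    m2[i] <- median(vals[i, g2])
  }
  tests <- tibble(
    feature = rownames(vals), u = u, p_value = p, method = method,
    median_group1 = m1, median_group2 = m2,
    direction = dplyr::case_when(m1 > m2 ~ "higher_in_group1",
                                 m2 > m1 ~ "higher_in_group2",
                                 TRUE ~ "tied"))
  tests$q_value <- bh_adjust(tests$p_value)
  tests <- tests %>%
    mutate(track = qm$track, timepoint = timepoint,
           selected = .data$q_value < q_threshold) %>%
    select("feature", "track", "timepoint", "u", "p_value", "q_value",
           "direction", "median_group1", "median_group2", "method",
           "selected") %>%
    arrange(.data$q_value, .data$p_value, .data$feature)
  structure(list(results = tests,
                 selected = tests$feature[tests$selected],
                 track = qm$track, timepoint = timepoint,
                 q_threshold = q_threshold,
                 n_group1 = sum(g1), n_group2 = sum(g2)),
            class = "track_diff")
}

#' @export
print.track_diff <- function(x, ...) {
  cat(sprintf("track_diff [%s, %s]: %d features, %d selected at q < %g (%d vs %d samples)\n",
              x$track, x$timepoint, nrow(x$results), length(x$selected),
              x$q_threshold, x$n_group1, x$n_group2))
  print(head(x$results, 10))
  invisible(x)
}

#' Tidy and summarize differential results
#'
#' @param x A `track_diff` object.
#' @param ... Unused.
#' @return `tidy()` returns the per-feature results tibble; `glance()` a
#'   one-row summary.
#' @method tidy track_diff
#' @export
tidy.track_diff <- function(x, ...) x$results

#' @rdname tidy.track_diff
#' @method glance track_diff
#' @export
glance.track_diff <- function(x, ...) {
  tibble(track = x$track, timepoint = x$timepoint,
         n_features = nrow(x$results), n_selected = length(x$selected),
         q_threshold = x$q_threshold,
         n_group1 = x$n_group1, n_group2 = x$n_group2)
}

#' Combine the protein- and peptide-track selections into one signature
#'
#' The combined signature is the union of the protein-track selection and
#' the peptide-track selection (already rolled up to protein accessions);
#' the overlap is their intersection. Sizes obey inclusion-exclusion:
#' `|combined| = |A| + |B| - |A intersect B|`.
#'
#' @param protein_sel Character vector of protein-group accessions selected
#'   by the protein track.
#' @param peptide_sel Character vector of protein-group accessions selected
#'   by the peptide track after roll-up.
#' @param timepoint,q_threshold Metadata recorded on the signature.
#' @return An object of class `signature`.
#' @export
combine_tracks <- function(protein_sel, peptide_sel, timepoint = "T0",
                           q_threshold = NA_real_) {
  protein_sel <- unique(as.character(protein_sel))
  peptide_sel <- unique(as.character(peptide_sel))
  structure(list(protein_track = sort(protein_sel),
                 peptide_track = sort(peptide_sel),
                 overlap = sort(intersect(protein_sel, peptide_sel)),
                 combined = sort(union(protein_sel, peptide_sel)),
                 timepoint = timepoint, q_threshold = q_threshold),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature [%s]: protein track %d + peptide track %d, overlap %d -> combined %d\n",
              x$timepoint, length(x$protein_track), length(x$peptide_track),
              length(x$overlap), length(x$combined)))
  invisible(x)
}

#' Tidy and summarize a combined signature
#'
#' @param x A `signature` object.
#' @param ... Unused.
#' @return `tidy()` returns one row per combined member with track
#'   membership flags; `glance()` the set sizes.
#' @method tidy signature
#' @export
tidy.signature <- function(x, ...) {
  tibble(protein = x$combined,
         in_protein_track = x$combined %in% x$protein_track,
         in_peptide_track = x$combined %in% x$peptide_track)
}

#' @rdname tidy.signature
#' @method glance signature
#' @export
glance.signature <- function(x, ...) {
  tibble(timepoint = x$timepoint, q_threshold = x$q_threshold,
         n_protein_track = length(x$protein_track),
         n_peptide_track = length(x$peptide_track),
         n_overlap = length(x$overlap),
         n_combined = length(x$combined))
}

#' Tally directions of change over a signature
#'
#' Counts how many signature members are expressed at higher levels in each
#' phenotype group (by group medians of normalized values). Every combined
#' member must have a result row.
#'
#' @param results A tibble with columns `feature` and `direction` (e.g. the
#'   protein-track [tidy.track_diff()] output, optionally augmented with
#'   rolled-up peptide results).
#' @param signature A `signature` object.
#' @return One-row tibble: `higher_in_group1`, `higher_in_group2`, `tied`
#'   (their sum equals the combined size).
#' @export
direction_tally <- function(results, signature) {
  stopifnot(inherits(signature, "signature"))
  stop_if_missing_cols(results, c("feature", "direction"), "results")
  res <- distinct(as_tibble(results), .data$feature, .keep_all = TRUE)
  missing <- setdiff(signature$combined, res$feature)
  if (length(missing) > 0) {
    abort(sprintf("signature member(s) without a result: %s",
                  paste(missing, collapse = ", ")))
  }
  dir <- res$direction[match(signature$combined, res$feature)]
  tibble(higher_in_group1 = sum(dir == "higher_in_group1"),
         higher_in_group2 = sum(dir == "higher_in_group2"),
         tied = sum(dir == "tied"))
}

#' Two-dimensional PCA of samples with a group-separation index
#'
#' Centers features and projects samples onto the top two principal
#' components. The separation index is the distance between the two group
#' centroids divided by the mean distance of samples to their own group
#' centroid in the 2-D score space; well-separated tight clusters give
#' large values.
#'
#' @param qm A `quant_matrix` (normally normalized) with phenotype groups.
#' @param features Optional character vector restricting to a feature set
#'   (e.g. a signature).
#' @param scale_features Scale features to unit variance before projection
#'   (default `FALSE`: centered only).
#' @return An object of class `pca_sep` with `scores` (tibble: sample_col,
#'   sample_id, timepoint, group, pc1, pc2), `separation`, and
#'   `var_explained`.
#' @export
pca_separation <- function(qm, features = NULL, scale_features = FALSE) {
  stopifnot(inherits(qm, "quant_matrix"))
  vals <- qm$values
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(vals))
    if (length(missing) > 0) {
      abort(sprintf("feature(s) absent from matrix: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    vals <- vals[features, , drop = FALSE]
  }
  if (ncol(vals) < 3) abort("PCA needs at least 3 samples")
  if (nrow(vals) < 2) abort("PCA needs at least 2 features")
  x <- t(vals)
  if (all(dist(x) == 0)) abort("all samples identical: PCA undefined")
  pr <- prcomp(x, center = TRUE, scale. = scale_features)
  k <- min(2L, ncol(pr$x))
  if (k < 2) {
    warn("matrix rank < 2: returning 1-D projection")
    scores2 <- cbind(pr$x[, 1], 0)
  } else {
    scores2 <- pr$x[, 1:2]
  }
  scores <- qm$samples %>%
    mutate(pc1 = scores2[match(.data$sample_col, rownames(x)), 1],
           pc2 = scores2[match(.data$sample_col, rownames(x)), 2])
  g <- as.character(scores$group)
  sep <- NA_real_
  if (length(unique(g[!is.na(g)])) == 2) {
    cen <- scores %>%
      group_by(.data$group) %>%
      summarise(c1 = mean(.data$pc1), c2 = mean(.data$pc2), .groups = "drop")
    between <- sqrt(diff(cen$c1)^2 + diff(cen$c2)^2)
    own <- left_join(scores, cen, by = "group")
    within <- mean(sqrt((own$pc1 - own$c1)^2 + (own$pc2 - own$c2)^2))
    sep <- if (within == 0) Inf else between / within
  }
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = scores, separation = sep,
                 var_explained = ve[seq_len(k)]),
            class = "pca_sep")
}

#' @export
print.pca_sep <- function(x, ...) {
  cat(sprintf("pca_sep: separation index %.3f (PC1 %.1f%%, PC2 %.1f%%)\n",
              x$separation, 100 * x$var_explained[1],
              100 * x$var_explained[length(x$var_explained)]))
  invisible(x)
}

#' @rdname pca_separation
#' @param x A `pca_sep` object.
#' @param ... Unused.
#' @method tidy pca_sep
#' @export
tidy.pca_sep <- function(x, ...) x$scores

#' @rdname pca_separation
#' @method glance pca_sep
#' @export
glance.pca_sep <- function(x, ...) {
  tibble(separation = x$separation,
         var_pc1 = x$var_explained[1],
         var_pc2 = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_)
}

#' Write per-feature differential results as TSV
#'
#' Columns: feature, track, timepoint, U, p, q, direction, and selection
#' flags at q < 0.2 and q < 0.3.
#'
#' @param diff A `track_diff` object.
#' @param path Output file.
#' @export
write_diff_results <- function(diff, path) {
  stopifnot(inherits(diff, "track_diff"))
  out <- diff$results %>%
    mutate(selected_q20 = .data$q_value < 0.2,
           selected_q30 = .data$q_value < 0.3)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
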