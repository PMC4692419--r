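# Independent brute-force oracles used to cross-check the analytical
# implementations, plus small fixture builders.

# Exact two-sided Mann-Whitney p-value by complete enumeration of all
# choose(n_a + n_b, n_a) assignments of the pooled ranks to group a.
# Assumes no ties (ranks are a permutation of 1..n).
oracle_mann_whitney <- function(a, b) {
  n_a <- length(a)
  n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(n_a + n_b, n_a)
  all_r <- seq_len(n_a + n_b)
  u_all <- apply(combos, 2, function(idx) sum(all_r[idx])) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  # two-sided: arrangements at least as extreme (in |U - mu|) as observed
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Benjamini-Hochberg by the literal min-over-suffix definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exhaustive threshold scan for the target-decoy filter: try every observed
# score as a cutoff, keep those with decoy/target ratio <= alpha, and pick
# the one accepting the most targets.
oracle_filter_at_fdr <- function(scores, is_decoy, alpha) {
  best <- NULL
  for (t in sort(unique(scores))) {
    n_t <- sum(!is_decoy & scores >= t)
    n_d <- sum(is_decoy & scores >= t)
    if (n_t > 0 && n_d / n_t <= alpha) {
      if (is.null(best) || n_t > best$n_t) best <- list(threshold = t, n_t = n_t)
    }
  }
  best
}

# Minimal valid PSM table with the given score/decoy columns.
make_psm_table <- function(score, is_decoy,
                           sample_id = "S1", replicate_id = 1L,
                           timepoint = "T0", peptide = NULL,
                           peak_area = 1e5, charge = 2L,
                           precursor_error_ppm = 0) {
  n <- length(score)
  tibble::tibble(
    spectrum_id = sprintf("sp%06d", seq_len(n)),
    sample_id = rep_len(sample_id, n),
    replicate_id = rep_len(replicate_id, n),
    timepoint = rep_len(timepoint, n),
    peptide = if (is.null(peptide)) sprintf("PEPTIDEK%03d", seq_len(n))
              else rep_len(peptide, n),
    charge = rep_len(charge, n),
    score = score,
    is_decoy = rep_len(is_decoy, n),
    peak_area = rep_len(peak_area, n),
    precursor_error_ppm = rep_len(precursor_error_ppm, n))
}

# Random protein sequence over the 20 standard residues.
random_sequence <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# A tiny quant_matrix fixture with explicit values and groups.
make_qm <- function(values, groups, timepoint = "T0",
                    track = "protein_counts") {
  n_s <- ncol(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%02d.%s", seq_len(n_s), timepoint)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("F%03d", seq_len(nrow(values)))
  }
  samples <- tibble::tibble(
    sample_col = colnames(values),
    sample_id = sub("\\..*$", "", colnames(values)),
    timepoint = rep_len(timepoint, n_s),
    group = groups)
  quant_matrix(values, samples, track = track)
}
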