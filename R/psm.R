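# Target-decoy FDR filtering of PSM tables, precursor-tolerance screening,
# and technical-replicate merging.

psm_columns <- c("spectrum_id", "sample_id", "replicate_id", "timepoint",
                 "peptide", "charge", "score", "is_decoy", "peak_area",
                 "precursor_error_ppm")

#' Validate a PSM table
#'
#' A PSM (peptide-spectrum match) table holds one row per spectrum-to-peptide
#' assignment with its search score (higher = better), decoy status,
#' integrated precursor peak area, and precursor mass error. Charge states
#' outside 2-6 are rejected at load time with a logged count, mirroring an
#' acquisition that analyzed only 2-6.
#'
#' @param psms A data frame with columns `spectrum_id`, `sample_id`,
#'   `replicate_id`, `timepoint` (`"T0"`/`"T12"`), `peptide`, `charge`,
#'   `score`, `is_decoy` (logical), `peak_area`, `precursor_error_ppm`.
#' @return The validated tibble with out-of-range charges removed.
#' @export
validate_psms <- function(psms) {
  stop_if_missing_cols(psms, psm_columns, "PSM table")
  out <- as_tibble(psms)
  bad_tp <- setdiff(unique(as.character(out$timepoint)), draw_timepoints)
  if (length(bad_tp) > 0) {
    abort(sprintf("unknown draw timepoint(s): %s", paste(bad_tp, collapse = ", ")))
  }
  if (any(!is.finite(out$score))) abort("non-finite PSM score")
  if (any(out$peak_area < 0)) abort("negative peak area")
  off <- out$charge < 2 | out$charge > 6
  if (any(off)) {
    inform(sprintf("removed %d PSM(s) with charge outside 2-6", sum(off)))
    out <- out[!off, , drop = FALSE]
  }
  out
}

#' Precursor mass-tolerance filter
#'
#' Retains PSMs whose absolute precursor error is within the search
#' tolerance (inclusive at the bound). Order is preserved.
#'
#' @param psms A PSM table.
#' @param max_ppm Tolerance in parts-per-million (default 10).
#' @return The filtered PSM tibble.
#' @export
tolerance_filter <- function(psms, max_ppm = 10) {
  stopifnot(max_ppm > 0)
  stop_if_missing_cols(psms, "precursor_error_ppm", "PSM table")
  as_tibble(psms)[abs(psms$precursor_error_ppm) <= max_ppm, , drop = FALSE]
}

#' Decoy-estimated false discovery rate at a score threshold
#'
#' The FDR of the set accepted at `threshold` is estimated from the decoy
#' hits it contains: `#{decoys with score >= t} / #{targets with score >= t}`.
#'
#' @param psms A PSM table (needs `score` and `is_decoy`).
#' @param threshold Score cutoff (accepted means `score >= threshold`).
#' @return The estimated FDR as a fraction.
#' @export
estimate_fdr <- function(psms, threshold) {
  stop_if_missing_cols(psms, c("score", "is_decoy"), "PSM table")
  acc <- psms$score >= threshold
  n_target <- sum(acc & !psms$is_decoy)
  if (n_target == 0) {
    abort("no target PSM at or above the threshold: FDR undefined")
  }
  sum(acc & psms$is_decoy) / n_target
}

#' Filter PSMs at a target-decoy FDR
#'
#' Chooses the smallest observed score threshold `t` whose decoy-estimated
#' FDR is at most `alpha` (maximizing the number of accepted targets;
#' ties at the threshold are all accepted) and returns the accepted target
#' PSMs. Decoys are discarded from downstream analysis. When no threshold
#' reaches `alpha`, an empty set is returned with a warning.
#'
#' @param psms A PSM table.
#' @param alpha Acceptable FDR (default 0.05).
#' @return A list with `accepted` (target PSM tibble), `threshold` (chosen
#'   score cutoff, `NA` if none), and `fdr` (realized decoy-estimated FDR of
#'   the accepted set).
#' @export
filter_at_fdr <- function(psms, alpha = 0.05) {
  stopifnot(alpha >= 0, alpha < 1)
  stop_if_missing_cols(psms, c("score", "is_decoy"), "PSM table")
  psms <- as_tibble(psms)
  cand <- sort(unique(psms$score))
  # counts at 'score >= t' for each candidate t, vectorized over candidates
  ord <- order(psms$score)
  s <- psms$score[ord]
  d <- psms$is_decoy[ord]
  n <- length(s)
  # for candidate t = cand[i], accepted are the suffix starting at the first
  # occurrence of cand[i] in the sorted score vector
  first_ge <- match(cand, s)
  tot_d <- rev(cumsum(rev(as.integer(d))))
  tot_t <- rev(cumsum(rev(as.integer(!d))))
  n_dec <- tot_d[first_ge]
  n_tar <- tot_t[first_ge]
  fdr <- ifelse(n_tar > 0, n_dec / n_tar, Inf)
  ok <- which(n_tar > 0 & fdr <= alpha)
  if (length(ok) == 0) {
    warn(sprintf("no score threshold reaches FDR <= %g; returning empty set",
                 alpha))
    return(list(accepted = psms[0, , drop = FALSE], threshold = NA_real_,
                fdr = NA_real_))
  }
  i <- ok[1]
  list(accepted = psms[!psms$is_decoy & psms$score >= cand[i], , drop = FALSE],
       threshold = cand[i], fdr = fdr[i])
}

#' Merge technical replicates of each sample
#'
#' LC-MS/MS injections of the same sample are pooled before quantification:
#' per (sample, timepoint, peptide, charge), the spectral contribution is
#' the total PSM count across replicates, peak areas are summed, and the
#' best (maximum) score is retained. A duplicated `spectrum_id` within one
#' replicate is an error (it would double-count a spectrum).
#'
#' @param psms A PSM table with `replicate_id` on every row.
#' @return A merged tibble keyed by `sample_id`, `timepoint`, `peptide`,
#'   `charge` with columns `is_decoy`, `n_spectra`, `peak_area`, `score`.
#' @export
merge_replicates <- function(psms) {
  stop_if_missing_cols(psms, c("spectrum_id", "sample_id", "replicate_id",
                               "timepoint", "peptide", "charge", "score",
                               "is_decoy", "peak_area"), "PSM table")
  psms <- as_tibble(psms)
  rep_key <- paste(psms$sample_id, psms$timepoint, psms$replicate_id,
                   psms$spectrum_id, sep = "\r")
  if (anyDuplicated(rep_key) > 0) {
    abort(sprintf("duplicate spectrum_id within a replicate (e.g. %s): refusing to double-count",
                  psms$spectrum_id[which(duplicated(rep_key))[1]]))
  }
  key <- paste(psms$sample_id, psms$timepoint, psms$peptide, psms$charge,
               psms$is_decoy, sep = "\r")
  uk <- unique(key)
  idx <- match(key, uk)
  first <- match(uk, key)
  # max score per key: order by (key, score), take the last row of each run;
  # runs come out in idx order 1..K, matching rowsum's sorted groups
  o <- order(idx, psms$score)
  last_of_run <- o[c(which(diff(idx[o]) != 0), length(o))]
  sums <- rowsum(psms$peak_area, idx)
  tibble(sample_id = psms$sample_id[first],
         timepoint = psms$timepoint[first],
         peptide = psms$peptide[first],
         charge = psms$charge[first],
         is_decoy = psms$is_decoy[first],
         n_spectra = tabulate(idx, length(uk)),
         peak_area = unname(sums[, 1]),
         score = psms$score[last_of_run]) %>%
    arrange(.data$sample_id, .data$timepoint, .data$peptide, .data$charge)
}

# PSM TSV I/O ---------------------------------------------------------------

#' Read and write the PSM TSV
#'
#' Tab-separated with a header row; `is_decoy` is stored as 0/1. Writing a
#' table read from disk reproduces the file exactly (numeric fields are
#' serialized with round-trip precision).
#'
#' @param path File path.
#' @return `read_psms()` returns a validated PSM tibble.
#' @export
read_psms <- function(path) {
  # base strtod parsing is exact to the last ULP, which the bit-exact
  # round-trip contract of this format requires
  out <- utils::read.delim(
    path, sep = "\t", quote = "", stringsAsFactors = FALSE,
    colClasses = c(spectrum_id = "character", sample_id = "character",
                   replicate_id = "integer", timepoint = "character",
                   peptide = "character", charge = "integer",
                   score = "numeric", is_decoy = "integer",
                   peak_area = "numeric", precursor_error_ppm = "numeric"))
  out <- as_tibble(out)
  out$is_decoy <- as.logical(out$is_decoy)
  validate_psms(out)
}

#' @rdname read_psms
#' @param psms A PSM tibble.
#' @export
write_psms <- function(psms, path) {
  stop_if_missing_cols(psms, psm_columns, "PSM table")
  out <- psms %>%
    select(all_of(psm_columns)) %>%
    mutate(is_decoy = as.integer(.data$is_decoy))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
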