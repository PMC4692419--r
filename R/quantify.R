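# The two quantification tracks: unique spectral counts per protein group
# and unique-peptide peak areas.

#' Construct a quantification matrix
#'
#' A `quant_matrix` holds a features-by-samples table of quantitative values
#' for one track: `protein_counts` (unique spectral counts, non-negative
#' integers) or `peptide_areas` (summed peak areas, non-negative reals).
#' Rows that are zero in every sample are dropped with a logged count.
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample column ids).
#' @param samples Tibble describing the columns: `sample_col`, `sample_id`,
#'   `timepoint`, `group`.
#' @param track `"protein_counts"` or `"peptide_areas"`.
#' @param normalized Whether the values have been normalized (see
#'   [normalize_quant()]).
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, samples, track = c("protein_counts", "peptide_areas"),
                         normalized = FALSE) {
  track <- match.arg(track)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  stop_if_missing_cols(samples, c("sample_col", "sample_id", "timepoint", "group"),
                       "sample table")
  if (anyDuplicated(rownames(values)) > 0) abort("duplicate feature ids")
  if (anyDuplicated(colnames(values)) > 0) abort("duplicate sample columns")
  if (!setequal(colnames(values), samples$sample_col) ||
      nrow(samples) != ncol(values)) {
    abort("sample table does not match matrix columns")
  }
  samples <- samples[match(colnames(values), samples$sample_col), , drop = FALSE]
  if (any(values < 0)) abort("quantitative values must be non-negative")
  if (track == "protein_counts" && !normalized &&
      any(values != round(values))) {
    abort("protein_counts values must be integers")
  }
  zero <- rowSums(values != 0) == 0
  if (any(zero)) {
    inform(sprintf("dropped %d all-zero feature row(s)", sum(zero)))
    values <- values[!zero, , drop = FALSE]
  }
  structure(list(values = values, samples = as_tibble(samples), track = track,
                 normalized = normalized),
            class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix [%s%s]: %d features x %d samples\n",
              x$track, if (x$normalized) ", normalized" else "",
              nrow(x$values), ncol(x$values)))
  print(head(x$samples))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Long-form view of a quantification matrix
#'
#' @param x A `quant_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per feature and sample: `feature`,
#'   `sample_col`, `sample_id`, `timepoint`, `group`, `value`, `track`.
#' @method tidy quant_matrix
#' @export
tidy.quant_matrix <- function(x, ...) {
  long <- tibble(
    feature = rep(rownames(x$values), times = ncol(x$values)),
    sample_col = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values))
  long %>%
    left_join(x$samples, by = "sample_col") %>%
    mutate(track = x$track) %>%
    select("feature", "sample_col", "sample_id", "timepoint", "group",
           "value", "track")
}

#' @method as_tibble quant_matrix
#' @export
as_tibble.quant_matrix <- function(x, ...) tidy.quant_matrix(x, ...)

join_sample_col <- function(sample_id, timepoint) {
  paste(sample_id, timepoint, sep = ".")
}

resolve_samples <- function(psms, sample_info) {
  if (is.null(sample_info)) {
    sample_info <- distinct(as_tibble(psms), .data$sample_id, .data$timepoint) %>%
      mutate(group = NA_character_)
  }
  stop_if_missing_cols(sample_info, c("sample_id", "timepoint"), "sample table")
  if (!"group" %in% names(sample_info)) sample_info$group <- NA_character_
  sample_info %>%
    as_tibble() %>%
    distinct(.data$sample_id, .data$timepoint, .keep_all = TRUE) %>%
    mutate(sample_col = join_sample_col(.data$sample_id, .data$timepoint)) %>%
    select("sample_col", "sample_id", "timepoint", "group") %>%
    arrange(.data$sample_col)
}

join_mapping <- function(psms, mapping) {
  stop_if_missing_cols(mapping, c("peptide", "parents", "is_unique"),
                       "peptide map")
  missing <- setdiff(unique(psms$peptide), mapping$peptide)
  if (length(missing) > 0) {
    abort(sprintf("PSM peptide(s) absent from the peptide map: %s%s",
                  paste(head(missing, 5), collapse = ", "),
                  if (length(missing) > 5) ", ..." else ""))
  }
  left_join(as_tibble(psms), as_tibble(mapping), by = "peptide")
}

cross_tab <- function(feature, sample_col, value, all_cols) {
  f_levels <- sort(unique(feature))
  m <- matrix(0, nrow = length(f_levels), ncol = length(all_cols),
              dimnames = list(f_levels, all_cols))
  if (length(feature) == 0) return(m)
  idx <- cbind(match(feature, f_levels), match(sample_col, all_cols))
  # accumulate duplicates
  agg <- rowsum(value, group = paste(idx[, 1], idx[, 2]))
  keys <- do.call(rbind, strsplit(rownames(agg), " "))
  m[cbind(as.integer(keys[, 1]), as.integer(keys[, 2]))] <- agg[, 1]
  m
}

#' Protein-track matrix of unique spectral counts
#'
#' For each protein group and sample, the value is the number of merged PSM
#' observations of peptides *unique* to that group. PSMs of shared peptides
#' contribute to no protein, which removes spectra duplication across
#' homologous proteins entirely.
#'
#' @param psms Accepted, replicate-merged PSMs ([merge_replicates()] output;
#'   an unmerged PSM table also works, each row then counting once).
#' @param mapping Peptide map from [map_peptides()].
#' @param sample_info Optional tibble (`sample_id`, `timepoint`, `group`)
#'   defining the full sample set and phenotype labels; defaults to the
#'   samples present in `psms` with unknown group.
#' @return A `quant_matrix` with track `"protein_counts"`.
#' @export
build_protein_matrix <- function(psms, mapping, sample_info = NULL) {
  samples <- resolve_samples(psms, sample_info)
  df <- join_mapping(psms, mapping) %>% filter(.data$is_unique)
  if (!"n_spectra" %in% names(df)) df$n_spectra <- 1L
  vals <- cross_tab(df$parents,
                    join_sample_col(df$sample_id, df$timepoint),
                    as.numeric(df$n_spectra), samples$sample_col)
  quant_matrix(vals, samples, track = "protein_counts")
}

#' Peptide-track matrix of unique-peptide peak areas
#'
#' Rows are unique peptides only (shared peptides are excluded entirely);
#' the value is the summed peak area of the peptide across charge states in
#' that sample. A peptide not observed in a sample has value 0.
#'
#' @inheritParams build_protein_matrix
#' @return A `quant_matrix` with track `"peptide_areas"`.
#' @export
build_peptide_matrix <- function(psms, mapping, sample_info = NULL) {
  samples <- resolve_samples(psms, sample_info)
  df <- join_mapping(psms, mapping) %>% filter(.data$is_unique)
  vals <- cross_tab(df$peptide,
                    join_sample_col(df$sample_id, df$timepoint),
                    df$peak_area, samples$sample_col)
  quant_matrix(vals, samples, track = "peptide_areas")
}

#' Roll peptide-level test results up to proteins
#'
#' The peptide track reports its findings as proteins: a protein (group) is
#' reported when at least one of its unique peptides passes the significance
#' threshold, and its q-value is the minimum q over its unique peptides
#' (best evidence). The direction attached is that of the best peptide.
#'
#' @param peptide_results Tibble of per-peptide results with columns
#'   `feature` (peptide sequence) and `q_value` (and optionally
#'   `direction`).
#' @param mapping Peptide map from [map_peptides()].
#' @param q_threshold Selection threshold (strict `q < q_threshold`,
#'   default 0.2).
#' @return Tibble with `protein`, `q_value`, `direction` (if available),
#'   `n_peptides` (unique peptides tested) and `selected`.
#' @export
roll_up_peptides <- function(peptide_results, mapping, q_threshold = 0.2) {
  stop_if_missing_cols(peptide_results, c("feature", "q_value"),
                       "peptide results")
  df <- as_tibble(peptide_results) %>%
    rename(peptide = "feature") %>%
    left_join(as_tibble(mapping), by = "peptide")
  if (any(is.na(df$parents))) {
    abort("peptide(s) in results are absent from the peptide map")
  }
  df <- filter(df, .data$is_unique)
  has_dir <- "direction" %in% names(df)
  df %>%
    group_by(protein = .data$parents) %>%
    summarise(
      direction = if (has_dir) .data$direction[which.min(.data$q_value)] else NA_character_,
      n_peptides = dplyr::n(),
      q_value = min(.data$q_value),
      .groups = "drop") %>%
    select("protein", "q_value", "direction", "n_peptides") %>%
    mutate(selected = .data$q_value < q_threshold) %>%
    arrange(.data$q_value, .data$protein)
}

# QuantMatrix I/O -----------------------------------------------------------

#' Read and write a quantification matrix as TSV with a sample sidecar
#'
#' The matrix TSV has the feature id in the first column (`feature`) and one
#' column per sample; the sidecar CSV maps sample columns to `sample_id`,
#' `timepoint` and `group`.
#'
#' @param qm A `quant_matrix`.
#' @param path Matrix TSV path; the sidecar is written beside it as
#'   `<path>.samples.csv`.
#' @export
write_quant_matrix <- function(qm, path) {
  stopifnot(inherits(qm, "quant_matrix"))
  df <- as_tibble(qm$values, rownames = "feature")
  readr::write_tsv(df, path, progress = FALSE)
  side <- mutate(qm$samples, track = qm$track, normalized = qm$normalized)
  readr::write_csv(side, paste0(path, ".samples.csv"), progress = FALSE)
  invisible(path)
}

#' @rdname write_quant_matrix
#' @param path Matrix TSV path written by [write_quant_matrix()].
#' @export
read_quant_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  side <- readr::read_csv(paste0(path, ".samples.csv"), show_col_types = FALSE,
                          progress = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$feature
  quant_matrix(vals, select(side, "sample_col", "sample_id", "timepoint", "group"),
               track = side$track[1], normalized = side$normalized[1])
}
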