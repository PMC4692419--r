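# In-silico fully tryptic digestion, reverse-decoy construction, and
# peptide-to-protein mapping with uniqueness status.

amino_acids <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Fully tryptic in-silico digestion of a protein sequence
#'
#' Cleaves C-terminal to K or R except when the next residue is P (the
#' classical trypsin rule as implemented by the common search engines).
#' Only peptides of at least `min_length` residues are returned; with
#' `missed_cleavages > 0` the concatenations spanning up to that many
#' internal cleavage sites are added. Peptides are returned in order of
#' their position in the parent.
#'
#' @param sequence A single protein sequence over the 20 standard amino
#'   acids (plus `X` for unknown residues).
#' @param min_length Minimum peptide length retained (default 7).
#' @param missed_cleavages Number of missed cleavage sites allowed, 0-2
#'   (default 0).
#' @return Character vector of peptides (possibly with duplicates if the
#'   parent contains repeated stretches).
#' @examples
#' tryptic_digest("AAAKBBBBBBBRCCCCCCC")  # drops the short "AAAK"
#' @export
tryptic_digest <- function(sequence, min_length = 7, missed_cleavages = 0) {
  stopifnot(length(sequence) == 1, min_length >= 1,
            missed_cleavages >= 0, missed_cleavages <= 2)
  if (nchar(sequence) == 0) abort("empty protein sequence")
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), c(amino_acids, "X"))
  if (length(bad) > 0) {
    abort(sprintf("invalid residue symbol(s) in sequence: %s",
                  paste(bad, collapse = ", ")))
  }
  n <- length(chars)
  # cleavage after position i when residue is K/R and successor is not P
  cut_after <- which(chars[-n] %in% c("K", "R") & chars[-1] != "P")
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  segs <- substring(sequence, starts, ends)
  m <- length(segs)
  out <- character(0)
  for (i in seq_len(m)) {
    for (mc in 0:missed_cleavages) {
      j <- i + mc
      if (j > m) break
      pep <- paste(segs[i:j], collapse = "")
      if (nchar(pep) >= min_length) out <- c(out, pep)
    }
  }
  out
}

#' Build a reverse-sequence decoy database
#'
#' One decoy per target protein: the sequence reversed, the accession
#' prefixed with a reserved decoy tag. The result can be concatenated with
#' the target database for a combined target-decoy search.
#'
#' @param db A data frame of proteins with columns `accession` and
#'   `sequence`.
#' @param tag Accession prefix marking decoys (default `"DECOY_"`).
#' @return A tibble of decoy proteins with the same columns.
#' @export
reverse_decoy <- function(db, tag = "DECOY_") {
  stop_if_missing_cols(db, c("accession", "sequence"), "protein database")
  if (nrow(db) == 0) abort("empty protein database")
  if (any(startsWith(db$accession, tag))) {
    abort(sprintf("accession(s) already carry the decoy tag '%s'", tag))
  }
  rev_seq <- vapply(strsplit(db$sequence, ""),
                    function(x) paste(rev(x), collapse = ""), character(1))
  n_palindrome <- sum(rev_seq == db$sequence)
  if (n_palindrome > 0) {
    inform(sprintf("%d palindromic sequence(s): decoy identical to target",
                   n_palindrome))
  }
  tibble(accession = paste0(tag, db$accession), sequence = rev_seq)
}

#' Map digest peptides to protein groups with uniqueness status
#'
#' Digests every protein, merges proteins whose digest peptide sets are
#' identical (indistinguishable by these peptides) into one group whose
#' accession is the sorted member accessions joined with `"+"`, and reports
#' every distinct peptide with its full parent-group set. A peptide is
#' *unique* when it maps to exactly one group; only unique peptides enter
#' the peptide-based quantification track.
#'
#' @inheritParams tryptic_digest
#' @param db A data frame of proteins (`accession`, `sequence`).
#' @return A tibble with columns `peptide`, `parents` (semicolon-joined
#'   sorted group accessions) and `is_unique`, sorted by peptide.
#' @export
map_peptides <- function(db, min_length = 7, missed_cleavages = 0) {
  stop_if_missing_cols(db, c("accession", "sequence"), "protein database")
  if (nrow(db) == 0) abort("empty protein database")
  if (anyDuplicated(db$accession) > 0) abort("duplicate accessions in database")
  peps <- lapply(db$sequence, tryptic_digest,
                 min_length = min_length, missed_cleavages = missed_cleavages)
  pep_sets <- lapply(peps, function(x) sort(unique(x)))
  set_key <- vapply(pep_sets, paste, character(1), collapse = "\r")
  grp_id <- match(set_key, unique(set_key))
  grp_members <- split(db$accession, grp_id)            # ordered 1..k
  grp_acc <- unname(vapply(grp_members, function(a)
    paste(sort(a), collapse = "+"), character(1)))
  # one row per (peptide, group); sets are identical within a group
  rep_idx <- match(seq_along(grp_acc), grp_id)
  n_per_grp <- lengths(pep_sets)[rep_idx]
  pep <- unlist(pep_sets[rep_idx], use.names = FALSE)
  grp <- rep(grp_acc, n_per_grp)
  # aggregate parent groups per distinct peptide
  o <- order(pep, grp)
  pep_o <- pep[o]
  grp_o <- grp[o]
  new_run <- c(TRUE, pep_o[-1] != pep_o[-length(pep_o)])
  run_id <- cumsum(new_run)
  n_parents <- tabulate(run_id)
  parents <- grp_o[new_run]                             # fast path: 1 parent
  multi <- which(n_parents > 1)
  if (length(multi) > 0) {
    parents[multi] <- unname(vapply(split(grp_o, run_id)[multi], paste,
                                    character(1), collapse = ";"))
  }
  tibble(peptide = pep_o[new_run], parents = parents,
         is_unique = n_parents == 1L)
}

# FASTA I/O -----------------------------------------------------------------

#' Read and write protein FASTA files
#'
#' Standard FASTA (`>accession description` headers; wrapped or unwrapped
#' sequence lines). The accession is the first whitespace-delimited token of
#' the header. The writer wraps sequences at 60 columns.
#'
#' @param path File path.
#' @return `read_fasta()` returns a tibble with `accession` and `sequence`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1)
  tibble(accession = acc, sequence = unname(as.character(ss)))
}

#' @rdname read_fasta
#' @param db Protein tibble (`accession`, `sequence`).
#' @export
write_fasta <- function(db, path) {
  stop_if_missing_cols(db, c("accession", "sequence"), "protein database")
  ss <- Biostrings::AAStringSet(setNames(db$sequence, db$accession))
  Biostrings::writeXStringSet(ss, path, width = 60)
  invisible(path)
}

#' Read and write the peptide-map TSV
#'
#' Columns: `peptide`, `parents` (semicolon-joined group accessions),
#' `is_unique` (0/1 in the file).
#'
#' @param mapping A peptide map as returned by [map_peptides()].
#' @param path File path.
#' @export
write_peptide_map <- function(mapping, path) {
  out <- mutate(mapping, is_unique = as.integer(.data$is_unique))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_peptide_map
#' @export
read_peptide_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(peptide = "c", parents = "c",
                                          is_unique = "i")) %>%
    mutate(is_unique = as.logical(.data$is_unique))
}
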