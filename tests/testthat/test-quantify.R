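# Quantification tracks: unique spectral counts and unique-peptide areas.

# Hand-built fixture: P1 owns u1,u2; P2 owns u3; s1 is shared by P1 and P2.
quant_fixture <- function() {
  mapping <- tibble::tibble(
    peptide = c("AAAAAAK", "CCCCCCK", "DDDDDDK", "SSSSSSK"),
    parents = c("P1", "P1", "P2", "P1;P2"),
    is_unique = c(TRUE, TRUE, TRUE, FALSE))
  # merged PSM rows: 10 observations over two samples
  psms <- tibble::tibble(
    sample_id = c("S1", "S1", "S1", "S1", "S2", "S2", "S2", "S2", "S2", "S2"),
    timepoint = "T0",
    peptide = c("AAAAAAK", "CCCCCCK", "DDDDDDK", "SSSSSSK",
                "AAAAAAK", "AAAAAAK", "CCCCCCK", "DDDDDDK", "DDDDDDK", "SSSSSSK"),
    charge = c(2L, 2L, 2L, 2L, 2L, 3L, 2L, 2L, 3L, 2L),
    n_spectra = c(2L, 1L, 3L, 4L, 1L, 1L, 2L, 1L, 1L, 5L),
    peak_area = c(1e6, 2e6, 3e6, 9e9, 1e6, 5e5, 1e6, 2e6, 2e6, 9e9))
  list(mapping = mapping, psms = psms)
}

test_that("protein counts sum unique-peptide spectra and ignore shared peptides", {
  fx <- quant_fixture()
  qm <- build_protein_matrix(fx$psms, fx$mapping)
  # hand-enumerated: S1 P1 = 2+1, P2 = 3; S2 P1 = 1+1+2, P2 = 1+1
  expect_equal(qm$values["P1", "S1.T0"], 3)
  expect_equal(qm$values["P2", "S1.T0"], 3)
  expect_equal(qm$values["P1", "S2.T0"], 4)
  expect_equal(qm$values["P2", "S2.T0"], 2)
  expect_equal(qm$track, "protein_counts")
  # shared-peptide PSMs contribute to no protein: deleting them changes nothing
  no_shared <- dplyr::filter(fx$psms, peptide != "SSSSSSK")
  qm2 <- build_protein_matrix(no_shared, fx$mapping)
  expect_equal(qm$values, qm2$values)
  # column sums never exceed the per-sample PSM totals (equality iff no shared)
  tot <- tapply(fx$psms$n_spectra, fx$psms$sample_id, sum)
  expect_true(all(colSums(qm$values) <= tot[c("S1", "S2")]))
  tot2 <- tapply(no_shared$n_spectra, no_shared$sample_id, sum)
  expect_equal(as.numeric(colSums(qm2$values)),
               as.numeric(tot2[c("S1", "S2")]))
})

test_that("peptide areas sum across charge states and exclude shared peptides", {
  fx <- quant_fixture()
  qm <- build_peptide_matrix(fx$psms, fx$mapping)
  expect_false("SSSSSSK" %in% rownames(qm$values))
  expect_equal(qm$values["AAAAAAK", "S2.T0"], 1.5e6)  # 1e6 (2+) + 5e5 (3+)
  expect_equal(qm$values["CCCCCCK", "S1.T0"], 2e6)
  expect_equal(qm$values["DDDDDDK", "S2.T0"], 4e6)
  # a peptide absent in a sample is an explicit zero
  one_sample <- dplyr::filter(fx$psms, sample_id == "S1" | peptide != "CCCCCCK")
  qm2 <- build_peptide_matrix(one_sample, fx$mapping)
  expect_equal(qm2$values["CCCCCCK", "S2.T0"], 0)
})

test_that("a PSM peptide missing from the map is an error naming it", {
  fx <- quant_fixture()
  bad <- dplyr::mutate(fx$psms, peptide = replace(peptide, 1, "GHOSTPEPK"))
  expect_error(build_protein_matrix(bad, fx$mapping), "GHOSTPEPK")
})

test_that("peptide-track roll-up reports best-evidence protein q-values", {
  mapping <- tibble::tibble(
    peptide = c("AAAAAAK", "CCCCCCK", "DDDDDDK", "EEEEEEK"),
    parents = c("P1", "P1", "P2", "P3"),
    is_unique = TRUE)
  res <- tibble::tibble(
    feature = mapping$peptide,
    q_value = c(0.15, 0.4, 0.35, 0.1),
    direction = c("higher_in_group2", "higher_in_group1",
                  "higher_in_group2", "higher_in_group2"))
  ru <- roll_up_peptides(res, mapping, q_threshold = 0.2)
  expect_equal(ru$q_value[ru$protein == "P1"], 0.15)
  expect_true(ru$selected[ru$protein == "P1"])
  expect_equal(ru$direction[ru$protein == "P1"], "higher_in_group2")
  expect_false(ru$selected[ru$protein == "P2"])          # all q >= 0.3
  expect_equal(sum(ru$protein == "P1"), 1)               # no double count
  expect_equal(nrow(ru), 3)
})

test_that("the matrix reproduces the generator's planted PSM allocation", {
  cfg <- sim_config(seed = 21, n_proteins = 40, shared_peptide_fraction = 0,
                    incorrect_target_fraction = 0, timepoints = "T0",
                    n_group1 = 3, n_group2 = 3)
  study <- simulate_study(cfg)
  mapping <- map_peptides(study$proteome)
  # accept everything: merge only, no FDR filtering
  merged <- merge_replicates(study$psms[!study$psms$is_decoy, ])
  qm <- suppressMessages(build_protein_matrix(merged, mapping))
  alloc <- study$truth$allocation
  for (i in sample(nrow(alloc), 25)) {
    expect_equal(
      qm$values[alloc$accession[i],
                paste(alloc$sample_id[i], alloc$timepoint[i], sep = ".")],
      alloc$n_psm[i])
  }
  expect_equal(sum(qm$values), sum(alloc$n_psm))
})

test_that("quant matrices round-trip through TSV with their sidecar", {
  fx <- quant_fixture()
  samples <- tibble::tibble(sample_col = c("S1.T0", "S2.T0"),
                            sample_id = c("S1", "S2"), timepoint = "T0",
                            group = c("group1_cipn", "group2_stable"))
  qm <- build_protein_matrix(fx$psms, fx$mapping, samples)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quant_matrix(qm, path)
  back <- read_quant_matrix(path)
  expect_equal(back$values, qm$values)
  expect_equal(back$samples, qm$samples)
  expect_equal(back$track, qm$track)
})

test_that("all-zero feature rows are dropped with a message", {
  vals <- matrix(c(0, 0, 3, 1), nrow = 2, byrow = TRUE,
                 dimnames = list(c("Z", "F"), c("a.T0", "b.T0")))
  samples <- tibble::tibble(sample_col = c("a.T0", "b.T0"),
                            sample_id = c("a", "b"), timepoint = "T0",
                            group = NA_character_)
  expect_message(qm <- quant_matrix(vals, samples), "all-zero")
  expect_equal(rownames(qm$values), "F")
  expect_error(quant_matrix(vals * -1, samples), "non-negative")
  expect_error(quant_matrix(matrix(c(0.5, 1, 2, 3), 2,
                                   dimnames = list(c("A", "B"), c("a.T0", "b.T0"))),
                            samples),
               "integers")
})
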