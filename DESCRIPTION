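Package: cipnsig
Title: Dual-Track Serum Exosome Proteomics for Predicting Taxane-Induced
    Peripheral Neuropathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for label-free serum-exosome proteomics
    aimed at predicting chemotherapy-induced peripheral neuropathy (CIPN)
    in taxane-treated breast cancer patients. Classifies CIPN phenotype
    from longitudinal FACT-Ntx patient-reported scores, performs in-silico
    fully tryptic digestion and reverse-decoy construction, filters
    peptide-spectrum matches at a target-decoy false discovery rate,
    builds two quantification tracks (unique spectral counts per protein
    group and unique-peptide peak areas), tests differential abundance
    between phenotype groups with the Mann-Whitney-Wilcoxon test under
    Benjamini-Hochberg FDR control, and combines the two tracks into a
    candidate biomarker signature. A fully seeded synthetic-data generator
    emulates the cohort and PSM-level data structure with ground-truth
    bookkeeping so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
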