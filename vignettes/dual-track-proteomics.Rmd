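---
title: "Dual-track serum exosome proteomics for CIPN prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-track serum exosome proteomics for CIPN prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cipnsig)
```

## The problem

Chemotherapy-induced peripheral neuropathy (CIPN) is a common, sometimes
disabling toxicity of taxanes. If patients at high risk could be recognized
from a pre-treatment blood draw, treatment could be personalized before
damage occurs. `cipnsig` implements a label-free proteomics discovery
pipeline for that setting: serum-exosome protein cargo is profiled by
LC-MS/MS before (T0) and after (T12) taxane therapy, patients are
phenotyped from their longitudinal FACT-Ntx patient-reported scores, and
proteins whose baseline abundance differs between patients who later do and
do not develop CIPN become candidate predictive biomarkers.

The package covers everything downstream of the search engine: it consumes
PSM (peptide-spectrum match) tables with scores, decoy flags and peak
areas; it does not score spectra.

## Phenotype model

The FACT-Ntx subscale ranges 0–44, higher meaning *less* neuropathy. For a
baseline score $b$ and follow-up score $f$ the fractional worsening is

$$ w = \frac{b - f}{b}, $$

positive when the score drops. A patient is classified CIPN
(`group1_cipn`) when the maximum worsening over the available follow-ups
(completion of taxane therapy, 6 months, 12 months) reaches 20% — the
boundary is inclusive because the rule is "at least 20%". Otherwise the
patient is stable (`group2_stable`). Missing intermediate follow-ups are
tolerated; a missing baseline or a patient with no follow-up at all is an
error rather than a silent "stable", and a baseline of 0 is rejected
because the percent change is undefined. The cohort summary follows clinical-table conventions: percentages with the group size as
denominator, rounded to two decimals for reporting only.

## Identification layer

*Digestion.* In-silico digestion is fully tryptic: cleavage C-terminal to
K or R, suppressed when the next residue is proline — the classical rule
the common search engines apply. The minimum peptide length is 7 residues.
Missed cleavages default to 0 and are configurable to 2; the quantification
logic is insensitive to this choice, so it is exposed as configuration
rather than fixed doctrine. I and L are distinct residues (sequence-database
semantics).

*Decoys.* The decoy database holds one reversed sequence per target with a
reserved accession prefix (`DECOY_`). Reversal is an involution and
preserves the length distribution, both of which are tested.

*Peptide mapping.* Proteins whose digest peptide sets are identical are
indistinguishable by these data and are merged into one group whose
accession is the sorted member accessions joined with `+` (the `;` used in
the peptide-map file to join a peptide's parents is thereby kept
unambiguous). A peptide is *unique* when it maps to exactly one group.

*PSM filtering.* Records outside the 10 ppm precursor tolerance (inclusive
bound) or the 2–6 charge window are screened out. Technical replicates of
the same sample are merged per (sample, time point, peptide, charge): PSM
counts add, peak areas add, the best score is kept; a duplicated spectrum
identifier within one replicate is an error because it would double-count
a spectrum. The target-decoy FDR of a score threshold $t$ is estimated as
the accepted decoy/target ratio (matching an FDR "determined based on the
number of accepted decoy" hits, rather than the doubled concatenated-search
estimate), and the filter chooses the smallest observed score whose
estimate is at most $\alpha = 0.05$, maximizing accepted targets; ties at
the threshold are all accepted. FDR is computed at PSM level — the counts
feed spectral counting directly — and in a single pass after replicate
merging.

## Quantification: two tracks

The same accepted PSMs yield two complementary feature matrices:

* **Protein track** — unique spectral counts: for each protein group and
  sample, the number of merged PSM observations of peptides unique to the
  group. Spectra of shared peptides are excluded outright rather than
  fractionally allocated: exclusion is the simplest rule that achieves
  zero double-counting across homologous proteins.
* **Peptide track** — unique-peptide peak areas: rows are unique peptides
  only; areas are summed across charge states of the same peptide, so one
  peptide is one feature.

A feature absent in a sample is a zero, not missing: spectral counting has
a natural zero and the downstream rank test tolerates ties at zero.
All-zero rows are dropped with a logged count.

## Statistics

*Normalization.* Each sample column is scaled so its total equals the
median column total, then transformed $x \mapsto \ln(x+1)$. This is a
stated, deliberately simple substitute for the undocumented normalization
of commercial omics GUIs; consequences are discussed under *Limitations*.

*Testing.* Each feature is compared between the phenotype groups with the
two-sided Mann–Whitney–Wilcoxon test. With no ties the p-value is exact —
at study scale (8 vs 9) the $\binom{17}{8} = 24\,310$ arrangements are
enumerable, and `stats::wilcox.test` computes the exact distribution;
tests confirm equality with a complete enumeration oracle. With ties,
mid-ranks with the tie-corrected normal approximation and continuity
correction are used (no exact-with-ties variant is pretended). A feature
identical in every sample is degenerate: $U = n_1 n_2 / 2$, $p = 1$,
flagged by its `method`.

*Multiplicity.* Benjamini–Hochberg adjustment is applied separately per
track and per time point — track-specific reporting implies separate adjustment — and selection uses a strict inequality ($q < 0.2$,
expanded exploratory list $q < 0.3$, as printed thresholds).

*Direction.* "Higher in group 2" means the group-2 median of the
normalized values exceeds the group-1 median; exact ties are reported as
`tied` rather than forced into a direction. Medians match the rank test's
robustness.

*Signature combination.* The peptide track's findings are rolled up to
proteins: a protein is reported when at least one of its unique peptides
passes, with $q$ the minimum over its unique peptides (best evidence; the
rule is a design choice, as peptide-track results are conventionally
reported as proteins without a stated aggregation). The combined signature
is the union of the two tracks' selections, the overlap their
intersection; sizes obey inclusion–exclusion exactly.

*PCA.* Samples are projected onto the top two principal components of the
feature-centered (not variance-scaled, by default — scaling is a flag)
normalized matrix. The separation index is the distance between group
centroids divided by the mean distance of samples to their own centroid;
a rank-deficient matrix degrades to a flagged 1-D projection, identical
samples are an error.

## The synthetic-data generator

Real raw data for this design would require a full search-engine run and
undocumented vendor normalization, so the generator produces data with the
*statistical structure* the analysis assumes, plus complete ground truth:

* **Cohort**: 8 CIPN and 9 stable patients by default. CIPN patients get a
  worst planted worsening uniform on [0.20, 0.60], stable patients on
  [−0.05, 0.15]; baselines are integers in [30, 44] and follow-ups are
  rounded inward (floor for CIPN, ceiling for stable) so the planted label
  survives integer rounding exactly — the classifier applied to a generated
  cohort reproduces the planted groups by construction. Demographics are
  sampled from realistic category frequencies for a US early-stage
  breast-cancer cohort.
* **Proteome**: 800 proteins by default, each a concatenation of fully
  tryptic peptides (7–20 residues, K/R terminus, no leading proline),
  sequence length roughly 120–600. A configurable fraction of proteins
  (default 5%) receives one peptide copied from another protein, creating
  shared peptides; note both donor and recipient then own a shared
  peptide.
* **PSMs**: per protein, sample and replicate, spectral counts are
  negative-binomial (dispersion parameter 4 by default; Poisson is the
  large-size limit) around a log-normal abundance baseline
  (meanlog $= \ln 2$, sdlog $= 1$ per replicate, a long-tailed serum-like
  distribution giving on the order of $10^4$ PSMs per sample — typical of
  a single-shot Orbitrap run). Twelve differential proteins get a
  $\ln(4)$-fold effect planted at T0 only — modeling the working hypothesis that
  the baseline draw, not the endpoint, separates the groups — with 32/37 of
  effects elevated in the stable group, the direction asymmetry the
  pipeline is designed to detect.
  Peak areas are log-normal and scale with abundance. Correct-target
  scores are Gaussian, shifted `decoy_score_shift` (default 3.5 SD) above
  the matched Gaussian of incorrect targets (default 10% of targets) and
  decoys, whose volumes follow the same law so the decoy estimate of the
  incorrect-target rate is calibrated. No attempt is made to model a real
  search-engine score.

All randomness flows from the single seed in `sim_config()`; equal
configurations give byte-identical output.

### What the generator does not emulate

No retention time or chromatography, no raw spectra, no batch effects, no
missingness mechanism beyond sampling zeros, no correlation between
proteins, and crucially *no compositional constraint*: real MS samples
compete for a roughly fixed number of spectra, whereas the generator
samples absolute abundances. Passing tests therefore demonstrate that the
machinery is correct and well-calibrated under the stated model, not that
the biological findings of any particular cohort are reproducible.

## Problem sizes and numerical choices

Simulation-based tests run the full pipeline — generate, filter at 5% PSM
FDR, quantify, test — at the study's own scale (800 proteins, 8 vs 9
patients, 3 replicates, T0 draw) over 100 seeds for parameter recovery and
51 seeds for the null, which keeps the suite comfortably within a desktop
run while leaving the per-dataset dimensions untouched. At these settings
the protein track recovers a median ≥ 90% of planted effects at $q < 0.3$,
and with a zero effect the typical dataset selects nothing at $q < 0.2$.
Observed false-discovery proportions scatter around the nominal BH level
$q \cdot m_0/m \approx 0.296$; with only ~12–17 selections per dataset the
per-dataset FDP is a small-denominator ratio and individual datasets
fluctuate well above and below it. A subtlety worth knowing: because the
generator samples absolute abundances while the planted effects are
direction-asymmetric, the stable group's column totals run slightly
(~1%) high, and total-count scaling then depresses every null protein in
that group — false discoveries are consequently biased toward
"higher in the CIPN group" and the realized FDP sits a little above the
nominal level. This is a compositional artifact of simple total-count
normalization, the same failure mode that motivates median-of-ratios and
trimmed-mean scaling in count-based differential expression; it is left
visible here rather than papered over, because the normalization is part
of the procedure under study.

Oracles used in tests are genuinely independent routes: complete
enumeration for the exact Mann–Whitney distribution, the literal
min-over-suffix definition for BH, an exhaustive threshold scan for the
target-decoy filter, and the generator's own planted allocation table for
quantification.

Tolerances: oracle comparisons at $10^{-9}$ (enumeration) and $10^{-12}$
(BH); file round-trips are exact — the PSM reader parses doubles with
strtod precision so that read→write reproduces bytes.

## Known limitations

* The normalization is not the vendor tool's; selection counts from any
  real cohort processed with vendor software are therefore not expected
  to be bit-reproducible here, and no such claim is made.
* Protein-level inference is by unique evidence only; a protein with no
  unique peptide is invisible to both tracks.
* The peptide-track roll-up (min-$q$) does not correct for the number of
  peptides per protein; it mirrors best-evidence reporting, not a
  protein-level error rate.
* The endpoint (T12) analysis is implemented for both tracks; with the
  default generator no effect is planted there, so it serves as a
  negative control.
* At study scale the peptide track carries a heavy multiplicity burden:
  an 8-vs-9 exact rank test cannot produce a two-sided p below
  $2/\binom{17}{8} \approx 8.2\times10^{-5}$ (and zero-ties push the
  approximate floor higher), so BH across the tens of thousands of
  observed unique peptides rarely clears $q < 0.3$ in simulation. The
  protein track (hundreds of features) drives recovery; the peptide
  track, roll-up and combination are exercised as machinery, and a
  commercial pipeline reporting many peptide-track hits is implicitly
  testing a far smaller, pre-filtered peptide universe or a different
  q-value computation.
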