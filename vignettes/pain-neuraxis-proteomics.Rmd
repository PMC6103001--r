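---
title: "Methods: region-resolved DIA proteome analysis across the pain neuraxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-resolved DIA proteome analysis across the pain neuraxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuraxprot)
```

## The analytical problem

Data-independent acquisition (DIA) mass spectrometry quantifies
thousands of peptides per run against a spectral library, producing a
long-format table of linear peptide intensities per protein, tissue,
condition and replicate. `neuraxprot` implements the downstream
analysis of such reports for a nervous-system study design: seven
tissues — sciatic nerve (SN) and dorsal root ganglia (DRG) in the
peripheral nervous system (PNS), spinal cord (SC), and four brain
regions (ACC, AMY, PFC, CER) — in two conditions (a control such as
Sham surgery, and a case such as the spared-nerve-injury neuropathic
pain model), with three replicates per cell, each replicate a pool of
four animals.

Four analyses sit on top of the peptide table:

1. **Tissue proteomes.** Peptide intensities are rolled up to
   protein-per-replicate arithmetic means on the linear scale. A
   protein is *detected* in a tissue when every replicate contains at
   least one of its peptides; detected proteins are summarized by
   cross-replicate mean, sample standard deviation (n − 1) and peptide
   count, with single-peptide proteins retained but flagged. Before
   any comparative step, identifiers are restricted to reviewed
   entries and keratin-like contaminants are removed
   (`filter_annotated()`).
2. **Tissue-enriched proteomes.** A protein of a target tissue (SN,
   DRG, or SC) is enriched relative to brain when it is either absent
   from all four brain proteomes (criterion A), or strictly more than
   10-fold above the *maximal* brain-region mean with a one-tailed
   Welch test p < 0.05 on the per-replicate intensities (criterion B).
   An optional secondary brain reference then removes any enriched
   protein seen in an independently analyzed brain dataset unless it
   still clears the same fold/Welch bar there.
3. **Regulation.** For each peptide quantified in all three control
   and all three case replicates of a tissue, three replicate-paired
   ratios log2(case_r/control_r) are formed. Per protein, the pooled
   ratios give the mean log2 fold change and a two-sided one-sample
   t-test against 0; p-values are Benjamini–Hochberg adjusted per
   tissue and calls use strict q < 0.05, flagging single-peptide calls
   as low-confidence.
4. **Reproducibility and comparison.** Pairwise Pearson correlations
   between replicate columns, hierarchical clustering (Euclidean
   distance, average linkage) of log2 z-scored protein rows with a
   flat protein-cluster cut at height 3.4, and identifier-normalized
   percentage overlap / Venn partitioning against external protein
   lists.

## Tunable parameters

All thresholds live in one object:

```{r}
analysis_thresholds()
```

* `fold_threshold = 10` (dimensionless, strict `>`): one order of
  magnitude over the maximal brain region.
* `welch_alpha = 0.05`: one-tailed, because only enrichment *above*
  brain is of interest.
* `q_threshold = 0.05` (strict `<`) on BH-adjusted p-values.
* `cluster_cut_distance = 3.4`: the visualization cut for protein
  co-expression clusters on z-scored log2 rows.
* `n_replicates = 3`, `pool_size = 4`: the study design; `pool_size`
  is metadata only (see below).

## The synthetic-data generator

Every statistical claim the package makes about itself is validated on
`simulate_study()`, whose generative model per measurement is

\[
I_{pjtcr} = A_p \; E_{pt} \; G_{ptc} \; F_j \; N_{pjtcr},
\]

where \(A_p \sim 2^{\mathcal N(\mu, \sigma^2)}\) is the protein base
abundance (defaults \(\mu = 20,\ \sigma = 2\) in log2, i.e. median
intensity around \(10^6\) with a spread typical of MS dynamic range),
\(E_{pt}\) a planted enrichment fold (1 in brain tissues and wherever
nothing is planted), \(G_{ptc} = 2^{\delta}\) the planted condition
effect in the case condition, \(F_j \sim 2^{\mathcal N(0, 1)}\) a
peptide response factor fixed across cells (peptides of one protein
routinely differ several-fold in ionization efficiency), and
\(N\) multiplicative lognormal replicate noise with unit mean and
coefficient of variation `replicate_cv` (default 0.1, a typical
between-replicate CV for pooled-tissue DIA). The CV converts to
log-space sd by the standard lognormal relation
\(\sigma_{\log}^2 = \log(1 + \mathrm{cv}^2)\). Dropout removes
measurements with probability
\(1 - (1 - r)\,(1 - \ell(I))\), where \(r\) is a random rate and
\(\ell\) a logistic function of log2 intensity falling around a
configurable midpoint — low-abundance peptides go missing first, as in
real DIA data. With the slope set to 0 the abundance-dependent term is
off entirely.

Design choices worth making explicit:

* **Pooling is implicit.** Each replicate stands for a pool of four
  animals; pooling compresses biological variance into the single
  replicate CV. The pipeline never sees animal-level data, so
  simulating four latent animals would add parameters no downstream
  operation could distinguish.
* **Randomness.** The whole study is one deterministic function of the
  configuration: the Mersenne-Twister stream is seeded once per
  `simulate_study()` call and consumed in a fixed order, so a given
  `(config, seed)` reproduces byte-identical output.
* **What the generator does not emulate:** retention times, spectra,
  peptide sequences (ids are synthetic labels), between-run intensity
  drift or batch effects, correlated noise across peptides of one
  protein, and interference-driven (rather than abundance-driven)
  missingness. Passing tests therefore demonstrate correctness of the
  downstream statistics under a clean generative model, not robustness
  to every artifact of real instrument data.

## Numerical and procedural choices

* **Detection reading.** "At least one peptide in all three
  replicates" is applied at the protein level: any peptide observation
  satisfies a replicate. The stricter same-peptide-in-all-replicates
  reading is available (`same_peptide = TRUE`).
* **Rollup scale.** Protein-per-replicate intensity is the arithmetic
  mean of linear peptide intensities; log2 happens only where a method
  requires it (clustering, ratios). The cross-replicate protein
  summary averages replicate means by default; averaging pooled
  peptides instead is a switch (`mean_over`), since the two differ
  when peptide counts vary between replicates.
* **Welch scale.** The enrichment test compares linear per-replicate
  abundances; a log2-scale switch exists. With n = 3 per group the
  test is fragile when a sample variance is 0 — exactly constant (or
  numerically near-constant) pairs fall back to a fold-only decision,
  flagged and warned about, rather than fabricating an infinite t.
* **Max-brain tie-break.** Equal maximal means resolve by the fixed
  region order ACC < AMY < PFC < CER, making classifications
  deterministic.
* **Regulation sample unit.** The one-sample t-test runs on all
  peptide-pair ratios of a protein pooled (3 × n_peptides values) by
  default, which keeps single-peptide proteins testable on their three
  ratios — consistent with the existence of single-peptide
  low-confidence calls. Testing the three per-pair protein means
  instead is a switch (`sample_unit = "pair_means"`).
* **Test sidedness.** Two-sided, since both up- and down-regulation
  are reported.
* **Degenerate ratio sets.** All ratios exactly 0 → p = 1 (no
  evidence); a nonzero constant set → no defined statistic, the
  protein is flagged `untestable` and excluded from the BH family.
* **BH family.** Per tissue, after the reviewed/contaminant filter,
  over proteins with a defined p-value.
* **Missing values.** Correlations use pairwise-complete rows;
  clustering uses complete cases only (the standard heatmap-tool
  behavior). Constant rows z-score to all zeros and stay in the
  matrix, flagged, so the row universe is identical between the two
  diagnostics; rows with a single observation have no sd and are
  excluded and flagged.
* **Dendrogram ties.** `stats::hclust` resolves equal-distance merges
  deterministically; no custom tie-break is layered on top, and column
  permutations yield isomorphic trees (verified by cophenetic
  distance).
* **Percent display.** Reported percentages keep full precision in
  tables; the integer display convention is round-half-up
  (`percent_label()`).

## Validation strategy and problem sizes

The test suite closes the loop on synthetic data at sizes chosen to
give stable Monte-Carlo estimates while keeping the suite quick to
run: a 1,000-protein global-null study over 20 seeds for false
discovery control; 100-protein studies with 20 planted log2-effect-1.0
proteins, 20 planted 20-fold and 20 planted 2-fold enrichments (3
peptides each, CV 0.1, no dropout — the recovery questions concern the
statistics, not missingness) over 20 seeds for power, estimation error
and enrichment sensitivity/specificity; and 60-protein two-tissue
studies (half the panel planted 8-fold, CV 0.05) over 20 seeds for
clustering recovery. The core statistics (Welch t, one-sample t, BH
step-up) are additionally checked against independent brute-force
implementations of the textbook formulas on 1,000 random instances
each. `scripts/acceptance.R` recomputes the same quantities from
scratch at a single command.

## Known limitations

* No between-run normalization: intensities are assumed comparable
  across runs, as produced by the upstream DIA software.
* The secondary-reference filter consumes any user-supplied secondary
  proteome table; it does not reconstruct a published brain library.
* Identifier conversion is consumed as a user-supplied mapping table;
  the package performs no network lookups.
* The tissue-preference partition (SN-specific / DRG-specific /
  shared) uses a documented operational rule — enriched in one PNS
  tissue and not detected in the other — because "preferential
  expression" admits several formalizations.
* Venn partitioning is limited to 2–3 sets by design.
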