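Package: neuraxprot
Title: Downstream Analysis of DIA Proteomes Across the Pain Neuraxis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of peptide-level data-independent
    acquisition (DIA) mass-spectrometry reports across nervous-system
    tissues. Rolls peptide intensities up to protein-per-replicate
    intensities, applies a replicate-wise detection rule to assemble
    tissue proteomes, classifies proteins enriched in the peripheral
    nervous system or spinal cord relative to brain regions by a
    two-criterion subtractive procedure (absence from brain, or
    greater-than-10-fold enrichment supported by a one-tailed Welch
    test) with a secondary-reference filter, quantifies case-versus-
    control abundance changes from replicate-paired peptide log2 ratios
    with one-sample t-tests and Benjamini-Hochberg correction, provides
    replicate reproducibility diagnostics (pairwise Pearson correlation,
    hierarchical clustering of z-scored log2 intensities), and compares
    protein lists against external resources via identifier
    normalization, percentage overlap and Venn partitioning. A
    synthetic-data generator with planted ground truth emulates the
    7-tissue, 2-condition, 3-replicate study design so every stage can
    be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
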