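# In-code fixture builders shared across test files.

# one protein, one peptide, one replicate series in a single cell group
cell_measurements <- function(protein, tissue, condition, intensities,
                              peptide = "pep1") {
  tibble::tibble(protein_id = protein,
                 peptide_id = paste0(protein, "_", peptide),
                 tissue = tissue, condition = condition,
                 replicate = seq_along(intensities),
                 intensity = intensities)
}

# tissue proteome from a named list protein -> replicate intensity vector
proteome_from <- function(tissue, values, condition = "control") {
  m <- dplyr::bind_rows(lapply(names(values), function(p) {
    cell_measurements(p, tissue, condition, values[[p]])
  }))
  build_tissue_proteome(m, tissue, condition,
                        n_replicates = length(values[[1]]))
}

brain_proteomes_from <- function(values_by_region, condition = "control") {
  out <- lapply(names(values_by_region), function(reg) {
    proteome_from(reg, values_by_region[[reg]], condition)
  })
  names(out) <- names(values_by_region)
  out
}

# sparse random peptide tables for property-style tests
random_measurements <- function(n_proteins = 8, n_peptides = 2,
                                tissues = c("SN", "ACC"),
                                conditions = "control",
                                n_replicates = 3, p_present = 0.8) {
  grid <- expand.grid(protein_id = sprintf("P%02d", seq_len(n_proteins)),
                      pep = seq_len(n_peptides),
                      tissue = tissues, condition = conditions,
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  grid$peptide_id <- paste0(grid$protein_id, "_pep", grid$pep)
  grid$intensity <- 2^stats::rnorm(nrow(grid), 18, 2)
  keep <- stats::runif(nrow(grid)) < p_present
  tibble::as_tibble(grid[keep, c("protein_id", "peptide_id", "tissue",
                                 "condition", "replicate", "intensity")])
}
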