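# Peptide-to-protein rollup, the detection rule, tissue proteomes.

#' Roll peptide intensities up to protein-per-replicate intensities
#'
#' For every (protein, tissue, condition, replicate) cell with at least
#' one quantified peptide, computes the arithmetic mean of the linear
#' peptide intensities and the number of contributing peptides. Cells
#' without any peptide are simply absent. The rollup happens on the
#' linear scale; downstream steps log-transform where their method
#' requires it.
#'
#' @param measurements Validated measurement tibble.
#' @return Tibble with columns `protein_id`, `tissue`, `condition`,
#'   `replicate`, `mean_intensity`, `n_peptides`.
#' @export
aggregate_protein_intensities <- function(measurements) {
  validate_measurements(measurements)
  measurements |>
    group_by(.data$protein_id, .data$tissue, .data$condition,
             .data$replicate) |>
    summarise(mean_intensity = mean(.data$intensity),
              n_peptides = n(), .groups = "drop") |>
    arrange(.data$protein_id, .data$tissue, .data$condition, .data$replicate)
}

check_tissue_condition <- function(measurements, tissue, condition) {
  known_tissues <- union(neurax_tissues(), unique(measurements$tissue))
  if (!tissue %in% known_tissues) {
    abort(sprintf("unknown tissue: %s", tissue))
  }
  known_cond <- union(c("control", "case"), unique(measurements$condition))
  if (!condition %in% known_cond) {
    abort(sprintf("unknown condition: %s", condition))
  }
  invisible(TRUE)
}

#' Apply the replicate-wise detection rule
#'
#' A protein counts as detected in a (tissue, condition) when every one
#' of the `n_replicates` replicates contains at least one quantified
#' peptide of that protein. By default any peptide satisfies a
#' replicate (the protein-level reading of "at least one peptide in all
#' three replicates"); with `same_peptide = TRUE` one specific peptide
#' must be seen in all replicates (the stricter reading).
#'
#' @param measurements Measurement tibble.
#' @param tissue,condition The cell to evaluate.
#' @param n_replicates Number of replicates that must all be hit.
#' @param same_peptide Require a single peptide across all replicates.
#' @return Sorted character vector of detected protein ids.
#' @export
detect_proteins <- function(measurements, tissue, condition,
                            n_replicates = 3L, same_peptide = FALSE) {
  check_tissue_condition(measurements, tissue, condition)
  m <- measurements[measurements$tissue == tissue &
                      measurements$condition == condition &
                      measurements$replicate <= n_replicates, ]
  if (!nrow(m)) return(character())
  if (same_peptide) {
    hits <- m |>
      distinct(.data$protein_id, .data$peptide_id, .data$replicate) |>
      count(.data$protein_id, .data$peptide_id) |>
      filter(.data$n == n_replicates)
  } else {
    hits <- m |>
      distinct(.data$protein_id, .data$replicate) |>
      count(.data$protein_id) |>
      filter(.data$n == n_replicates)
  }
  sort(unique(hits$protein_id))
}

#' Assemble a tissue proteome
#'
#' Restricts to proteins passing the detection rule in the given
#' (tissue, condition) and summarizes each: cross-replicate mean and
#' sample standard deviation (n-1) of the protein-per-replicate mean
#' intensities, the number of distinct peptides observed across all
#' replicates, and a `single_peptide` flag for proteins resting on
#' exactly one distinct peptide. Single-peptide proteins are included
#' by design, to keep tissue comparisons as stringent as possible.
#'
#' @inheritParams detect_proteins
#' @param mean_over `"replicate_means"` (default): the protein summary
#'   averages the per-replicate rollup means; `"pooled_peptides"`:
#'   mean/sd over all peptide intensities pooled across replicates.
#' @return Object of class `tissue_proteome`: a list with `tissue`,
#'   `condition`, `proteins` (tibble: `protein_id`, `mean_intensity`,
#'   `sd_intensity`, `n_peptides_total`, `single_peptide`) and
#'   `replicate_intensities` (tibble: `protein_id`, `replicate`,
#'   `mean_intensity`), the per-replicate values used by downstream
#'   Welch tests.
#' @export
build_tissue_proteome <- function(measurements, tissue, condition,
                                  n_replicates = 3L, same_peptide = FALSE,
                                  mean_over = c("replicate_means",
                                                "pooled_peptides")) {
  mean_over <- match.arg(mean_over)
  detected <- detect_proteins(measurements, tissue, condition,
                              n_replicates = n_replicates,
                              same_peptide = same_peptide)
  m <- measurements[measurements$tissue == tissue &
                      measurements$condition == condition &
                      measurements$replicate <= n_replicates &
                      measurements$protein_id %in% detected, ]
  reps <- aggregate_protein_intensities(m)[
    c("protein_id", "replicate", "mean_intensity")]
  pep_counts <- m |>
    group_by(.data$protein_id) |>
    summarise(n_peptides_total = n_distinct(.data$peptide_id),
              .groups = "drop")
  summary_tbl <- if (mean_over == "replicate_means") {
    reps |>
      group_by(.data$protein_id) |>
      summarise(sd_intensity = sd(.data$mean_intensity),
                mean_intensity = mean(.data$mean_intensity),
                .groups = "drop")
  } else {
    m |>
      group_by(.data$protein_id) |>
      summarise(sd_intensity = sd(.data$intensity),
                mean_intensity = mean(.data$intensity), .groups = "drop")
  }
  proteins <- summary_tbl[c("protein_id", "mean_intensity", "sd_intensity")] |>
    left_join(pep_counts, by = "protein_id") |>
    mutate(single_peptide = .data$n_peptides_total == 1L) |>
    arrange(.data$protein_id)
  structure(list(tissue = tissue, condition = condition,
                 proteins = proteins,
                 replicate_intensities = reps),
            class = "tissue_proteome")
}

#' @export
print.tissue_proteome <- function(x, ...) {
  cat(sprintf("Tissue proteome: %s (%s), %d proteins (%d single-peptide)\n",
              x$tissue, x$condition, nrow(x$proteins),
              sum(x$proteins$single_peptide)))
  invisible(x)
}

proteome_has <- function(proteome, protein_id) {
  protein_id %in% proteome$proteins$protein_id
}

replicate_values <- function(proteome, protein_id) {
  ri <- proteome$replicate_intensities
  ri$mean_intensity[ri$protein_id == protein_id]
}
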