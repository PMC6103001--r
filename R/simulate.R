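# Synthetic peptide-level study generator with planted ground truth.

#' Configure a synthetic DIA study
#'
#' Describes a peptide-level simulation of the study design: a panel of
#' tissues (default the full 7-region neuraxis) measured in two
#' conditions (control/case, i.e. Sham vs. injury model) with
#' `n_replicates` replicates per cell, each replicate standing for a
#' pool of 4 animals. The generative model per measurement is
#'
#'   intensity = A_p * E_pt * G_pct * F_j * N
#'
#' with A_p a protein base abundance (lognormal in log2 space), E_pt a
#' planted tissue-enrichment fold (1 in brain regions and everywhere
#' not planted), G_pct = 2^log2_effect for planted (protein, tissue)
#' pairs in the case condition (1 otherwise), F_j a peptide-specific
#' response factor fixed across all cells, and N multiplicative
#' replicate noise, lognormal with unit mean and the configured
#' coefficient of variation. Measurements are then removed by dropout:
#' a random component plus a logistic abundance-dependent component
#' that rises as log2 intensity falls below `dropout$midpoint`.
#'
#' @param n_proteins Number of simulated proteins.
#' @param peptides_per_protein Single integer (fixed) or length-2
#'   vector `c(min, max)` for a uniform peptide count per protein.
#' @param base_abundance Length-2 vector `c(meanlog2, sdlog2)` of the
#'   protein base-abundance distribution (log2 scale).
#' @param peptide_response_sd Log2 sd of the per-peptide response
#'   factor (how unevenly peptides of one protein fly).
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   replicate noise, linear scale.
#' @param dropout List with `random_rate` in \[0,1), `slope` >= 0 and
#'   `midpoint` (log2 intensity at which the abundance-dependent
#'   dropout probability is 0.5; inactive when `slope` is 0).
#' @param planted_enriched Tibble/data.frame with columns `protein_id`,
#'   `tissue`, `fold` (> 1); the fold is applied in the named
#'   non-brain tissue, both conditions.
#' @param planted_regulated Tibble/data.frame with columns
#'   `protein_id`, `tissue`, `log2_effect`; applied in the case
#'   condition only.
#' @param contaminant_fraction,unreviewed_fraction Fractions of the
#'   protein panel annotated as contaminant (keratin-like gene symbol)
#'   or as unreviewed entries; planted proteins must be disjoint from
#'   both.
#' @param tissues,conditions Panel of tissues and the two condition
#'   labels.
#' @param n_replicates Replicates per (tissue, condition).
#' @param seed Integer seed; the whole study is a deterministic
#'   function of the configuration including the seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 1000,
                              peptides_per_protein = c(1, 8),
                              base_abundance = c(meanlog2 = 20, sdlog2 = 2),
                              peptide_response_sd = 1,
                              replicate_cv = 0.1,
                              dropout = list(random_rate = 0.05,
                                             slope = 1,
                                             midpoint = 14),
                              planted_enriched = NULL,
                              planted_regulated = NULL,
                              contaminant_fraction = 0.02,
                              unreviewed_fraction = 0.05,
                              tissues = neurax_tissues(),
                              conditions = c("control", "case"),
                              n_replicates = 3L,
                              seed = 1L) {
  stopifnot(n_proteins >= 1, length(conditions) == 2,
            length(tissues) >= 1, n_replicates >= 1,
            peptide_response_sd >= 0, replicate_cv >= 0)
  if (length(peptides_per_protein) == 1) {
    peptides_per_protein <- rep(peptides_per_protein, 2)
  }
  stopifnot(length(peptides_per_protein) == 2,
            peptides_per_protein[1] >= 1,
            peptides_per_protein[2] >= peptides_per_protein[1])
  dropout <- utils::modifyList(list(random_rate = 0, slope = 0, midpoint = 0),
                               dropout)
  if (dropout$random_rate < 0 || dropout$random_rate >= 1) {
    abort("dropout$random_rate must lie in [0, 1)")
  }
  if (dropout$slope < 0) abort("dropout$slope must be >= 0")
  if (!(contaminant_fraction >= 0 && contaminant_fraction < 1 &&
        unreviewed_fraction >= 0 && unreviewed_fraction < 1)) {
    abort("contaminant/unreviewed fractions must lie in [0, 1)")
  }
  planted_enriched <- normalize_planted(planted_enriched,
                                        c("protein_id", "tissue", "fold"))
  planted_regulated <- normalize_planted(planted_regulated,
                                         c("protein_id", "tissue",
                                           "log2_effect"))
  if (nrow(planted_enriched)) {
    if (any(planted_enriched$fold <= 1)) {
      abort("every planted enrichment fold must be > 1")
    }
    if (any(planted_enriched$tissue %in% brain_tissues())) {
      abort("enrichment cannot be planted in a brain tissue")
    }
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 peptides_per_protein = as.integer(peptides_per_protein),
                 base_abundance = base_abundance,
                 peptide_response_sd = peptide_response_sd,
                 replicate_cv = replicate_cv,
                 dropout = dropout,
                 planted_enriched = planted_enriched,
                 planted_regulated = planted_regulated,
                 contaminant_fraction = contaminant_fraction,
                 unreviewed_fraction = unreviewed_fraction,
                 tissues = tissues,
                 conditions = conditions,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

normalize_planted <- function(x, cols) {
  if (is.null(x)) {
    x <- as_tibble(setNames(list(character(), character(), numeric()), cols))
  }
  x <- as_tibble(x)
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols)) {
    abort(sprintf("planted table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  x[cols]
}

#' Simulate a peptide-level study with known ground truth
#'
#' Draws a full peptide report, an annotation table and the matching
#' ground truth from a [simulation_config()]. Two calls with the same
#' configuration (including seed) return identical objects.
#'
#' @param config A [simulation_config()].
#' @return List with elements `measurements` (peptide tibble in the
#'   report schema), `annotations` (see [read_annotations()]) and
#'   `truth`, an object of class `simulation_truth` holding
#'   `tissue_means` (true per-protein linear means per tissue, control
#'   scale), `enrichment` (planted folds, equal to the true fold over
#'   the maximal brain region), `effects` (planted condition
#'   log2 effects) and `dropout` (per-measurement dropout indicator on
#'   the pre-dropout grid).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  protein_ids <- sprintf("P%05d", seq_len(n))

  n_contam <- floor(config$contaminant_fraction * n)
  n_unrev <- floor(config$unreviewed_fraction * n)
  contam_ids <- protein_ids[seq_len(n_contam) + (n - n_contam)]
  unrev_ids <- protein_ids[seq_len(n_unrev) + (n - n_contam - n_unrev)]

  planted_ids <- unique(c(config$planted_enriched$protein_id,
                          config$planted_regulated$protein_id))
  if (length(setdiff(planted_ids, protein_ids))) {
    abort("planted protein id outside the simulated panel")
  }
  if (length(intersect(planted_ids, c(contam_ids, unrev_ids)))) {
    abort("planted proteins must be disjoint from contaminant/unreviewed ones")
  }
  bad_tissue <- setdiff(c(config$planted_enriched$tissue,
                          config$planted_regulated$tissue), config$tissues)
  if (length(bad_tissue)) {
    abort(sprintf("planted tissue(s) not in the panel: %s",
                  paste(unique(bad_tissue), collapse = ", ")))
  }

  pp <- config$peptides_per_protein
  n_pep <- if (pp[1] == pp[2]) rep(pp[1], n) else
    sample(seq(pp[1], pp[2]), n, replace = TRUE)
  base_log2 <- rnorm(n, config$base_abundance[[1]], config$base_abundance[[2]])
  abundance <- setNames(2^base_log2, protein_ids)

  peptides <- tibble(
    protein_id = rep(protein_ids, n_pep),
    peptide_id = paste0(rep(protein_ids, n_pep), "_pep",
                        sprintf("%02d", sequence(n_pep))),
    response = 2^rnorm(sum(n_pep), 0, config$peptide_response_sd))

  grid <- crossing(peptides,
                   tissue = config$tissues,
                   condition = config$conditions,
                   replicate = seq_len(config$n_replicates))

  enr <- config$planted_enriched
  grid$enrich_fold <- 1
  if (nrow(enr)) {
    idx <- match(paste(grid$protein_id, grid$tissue),
                 paste(enr$protein_id, enr$tissue))
    grid$enrich_fold <- ifelse(is.na(idx), 1, enr$fold[idx])
  }
  reg <- config$planted_regulated
  grid$effect <- 0
  if (nrow(reg)) {
    idx <- match(paste(grid$protein_id, grid$tissue),
                 paste(reg$protein_id, reg$tissue))
    grid$effect <- ifelse(is.na(idx) | grid$condition != config$conditions[2],
                          0, reg$log2_effect[idx])
  }

  cv <- config$replicate_cv
  noise <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    exp(rnorm(nrow(grid), -sdlog^2 / 2, sdlog))
  } else {
    rep(1, nrow(grid))
  }
  grid$intensity <- unname(abundance[grid$protein_id]) * grid$enrich_fold *
    2^grid$effect * grid$response * noise

  d <- config$dropout
  p_abund <- if (d$slope > 0) {
    1 / (1 + exp(d$slope * (log2(grid$intensity) - d$midpoint)))
  } else {
    0
  }
  p_drop <- 1 - (1 - d$random_rate) * (1 - p_abund)
  dropped <- runif(nrow(grid)) < p_drop

  measurements <- grid[!dropped, c("protein_id", "peptide_id", "tissue",
                                   "condition", "replicate", "intensity")]
  measurements <- as_tibble(measurements)

  annotations <- tibble(
    protein_id = protein_ids,
    gene = ifelse(protein_ids %in% contam_ids,
                  paste0("Krt", seq_len(n)),
                  paste0("Gene", seq_len(n))),
    reviewed = !(protein_ids %in% unrev_ids),
    contaminant = protein_ids %in% contam_ids)

  tissue_means <- crossing(protein_id = protein_ids, tissue = config$tissues)
  tissue_means$true_mean <- unname(abundance[tissue_means$protein_id])
  if (nrow(enr)) {
    idx <- match(paste(tissue_means$protein_id, tissue_means$tissue),
                 paste(enr$protein_id, enr$tissue))
    tissue_means$true_mean <- tissue_means$true_mean *
      ifelse(is.na(idx), 1, enr$fold[idx])
  }

  truth <- structure(list(
    tissue_means = tissue_means,
    enrichment = enr,
    effects = reg,
    dropout = as_tibble(grid[c("protein_id", "peptide_id", "tissue",
                               "condition", "replicate")]) |>
      mutate(dropped = dropped)),
    class = "simulation_truth")

  list(measurements = measurements, annotations = annotations, truth = truth)
}

#' Write and read simulation ground truth
#'
#' Serializes a `simulation_truth` to a single TSV with a `record`
#' column distinguishing per-protein true tissue means
#' (`tissue_mean`), planted enrichment folds (`enrichment`) and
#' planted condition effects (`regulation`). The per-measurement
#' dropout indicator is an in-memory diagnostic and is not serialized.
#' Writing and re-reading round-trips the three tables losslessly.
#'
#' @param truth A `simulation_truth` (from [simulate_study()]).
#' @param path Output TSV path.
#' @return `path` invisibly (writer); a `simulation_truth` (reader).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  rows <- bind_rows(
    tibble(record = "tissue_mean",
           protein_id = truth$tissue_means$protein_id,
           tissue = truth$tissue_means$tissue,
           value = truth$tissue_means$true_mean),
    tibble(record = "enrichment",
           protein_id = truth$enrichment$protein_id,
           tissue = truth$enrichment$tissue,
           value = truth$enrichment$fold),
    tibble(record = "regulation",
           protein_id = truth$effects$protein_id,
           tissue = truth$effects$tissue,
           value = truth$effects$log2_effect))
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  rows <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            record = readr::col_character(),
                            protein_id = readr::col_character(),
                            tissue = readr::col_character(),
                            value = readr::col_double()))
  pick <- function(what, value_name) {
    out <- rows[rows$record == what, c("protein_id", "tissue", "value")]
    names(out)[3] <- value_name
    as_tibble(out)
  }
  structure(list(tissue_means = pick("tissue_mean", "true_mean"),
                 enrichment = pick("enrichment", "fold"),
                 effects = pick("regulation", "log2_effect"),
                 dropout = NULL),
            class = "simulation_truth")
}
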