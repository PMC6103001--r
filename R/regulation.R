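# Case-vs-control regulation from replicate-paired peptide log2 ratios.

#' Replicate-paired peptide log2 ratios
#'
#' For each peptide of a tissue quantified in all `n_replicates`
#' control and all `n_replicates` case replicates, computes the
#' replicate-paired ratios log2(case_r / control_r), r = 1..3 by
#' default. Peptides missing any of the six cells contribute nothing:
#' pairing by replicate index is only meaningful on complete peptides.
#'
#' @param measurements Measurement tibble (one tissue is selected).
#' @param tissue Tissue to evaluate.
#' @param n_replicates Replicates per condition.
#' @param control,case Condition labels.
#' @return Tibble with `protein_id`, `peptide_id`, `tissue`,
#'   `pair_index`, `log2_ratio`.
#' @export
compute_peptide_ratios <- function(measurements, tissue,
                                   n_replicates = 3L,
                                   control = "control", case = "case") {
  check_tissue_condition(measurements, tissue, control)
  check_tissue_condition(measurements, tissue, case)
  m <- measurements[measurements$tissue == tissue &
                      measurements$condition %in% c(control, case) &
                      measurements$replicate <= n_replicates, ]
  empty <- tibble(protein_id = character(), peptide_id = character(),
                  tissue = character(), pair_index = integer(),
                  log2_ratio = numeric())
  if (!nrow(m)) return(empty)
  complete <- m |>
    distinct(.data$protein_id, .data$peptide_id, .data$condition,
             .data$replicate) |>
    count(.data$protein_id, .data$peptide_id, .data$condition) |>
    filter(.data$n == n_replicates) |>
    count(.data$protein_id, .data$peptide_id) |>
    filter(.data$n == 2L)
  if (!nrow(complete)) return(empty)
  wide <- m |>
    semi_join(complete, by = c("protein_id", "peptide_id")) |>
    select("protein_id", "peptide_id", "condition", "replicate",
           "intensity") |>
    pivot_wider(names_from = "condition", values_from = "intensity")
  tibble(protein_id = wide$protein_id,
         peptide_id = wide$peptide_id,
         tissue = tissue,
         pair_index = as.integer(wide$replicate),
         log2_ratio = log2(wide[[case]] / wide[[control]])) |>
    arrange(.data$protein_id, .data$peptide_id, .data$pair_index)
}

#' Per-protein regulation statistics from peptide-pair ratios
#'
#' Groups the paired peptide ratios by protein and computes the mean
#' log2 fold change and a two-sided one-sample t-test of the ratios
#' against 0. By default the sample unit is all peptide-pair ratios of
#' the protein pooled (3 x n_peptides values), which keeps
#' single-peptide proteins testable on their three ratios;
#' `sample_unit = "pair_means"` instead tests the three per-pair
#' protein means. Degenerate ratio sets are handled explicitly: all
#' ratios exactly 0 give p = 1; a nonzero constant set has no defined
#' t statistic and is flagged `untestable` (excluded from the BH
#' family) rather than fabricating an infinite statistic.
#'
#' @param ratios Ratio tibble from [compute_peptide_ratios()].
#' @param sample_unit `"pooled"` or `"pair_means"`.
#' @return Tibble with `protein_id`, `tissue`, `mean_log2fc`,
#'   `p_value`, `n_peptides`, `n_ratios`, `untestable`.
#' @export
protein_regulation <- function(ratios,
                               sample_unit = c("pooled", "pair_means")) {
  sample_unit <- match.arg(sample_unit)
  if (!nrow(ratios)) {
    return(tibble(protein_id = character(), tissue = character(),
                  mean_log2fc = numeric(), p_value = numeric(),
                  n_peptides = integer(), n_ratios = integer(),
                  untestable = logical()))
  }
  one_protein <- function(d) {
    values <- if (sample_unit == "pooled") {
      d$log2_ratio
    } else {
      tapply(d$log2_ratio, d$pair_index, mean)
    }
    values <- as.numeric(values)
    if (all(values == 0)) {
      p <- 1
      untestable <- FALSE
    } else if (length(values) < 2 || sd(values) == 0) {
      p <- NA_real_
      untestable <- TRUE
    } else {
      # t.test also refuses near-constant data (stderr below ~10 eps of
      # the mean); such ratio sets carry no testable variance either
      ht <- tryCatch(t.test(values, mu = 0), error = function(e) NULL)
      p <- if (is.null(ht)) NA_real_ else ht$p.value
      untestable <- is.null(ht)
    }
    tibble(mean_log2fc = mean(d$log2_ratio),
           p_value = p,
           n_peptides = n_distinct(d$peptide_id),
           n_ratios = nrow(d),
           untestable = untestable)
  }
  ratios |>
    group_by(.data$protein_id, .data$tissue) |>
    group_modify(~ one_protein(.x)) |>
    ungroup() |>
    arrange(.data$protein_id)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a family of p-values with the BH step-up procedure,
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1 and mapped
#' back to the input order. The family should be one tissue's
#' reviewed, non-contaminant proteins with a defined p-value.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` propagates).
#' @return Vector of q-values in input order.
#' @export
bh_adjust <- function(p) {
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    abort(sprintf("p-value outside [0, 1]: %g", p[which(bad)[1]]))
  }
  p.adjust(p, method = "BH")
}

#' Call regulated proteins at the q threshold
#'
#' Attaches BH q-values (computed per tissue over proteins with a
#' defined p-value) and the regulation flags: `regulated` when
#' q < `q_threshold` (strict), and `low_confidence` when a regulated
#' call rests on a single peptide across all six samples.
#'
#' @param records Regulation tibble from [protein_regulation()]; if a
#'   `q_value` column is already present it is used as-is.
#' @param thresholds An [analysis_thresholds()].
#' @return `records` with `q_value`, `regulated`, `low_confidence`.
#' @export
call_regulated <- function(records, thresholds = analysis_thresholds()) {
  if (!"q_value" %in% names(records)) {
    records$q_value <- NA_real_
    for (tis in unique(records$tissue)) {
      idx <- which(records$tissue == tis & !is.na(records$p_value))
      records$q_value[idx] <- bh_adjust(records$p_value[idx])
    }
  }
  records$regulated <- !is.na(records$q_value) &
    records$q_value < thresholds$q_threshold
  records$low_confidence <- records$regulated & records$n_peptides == 1L
  records
}

#' One-shot regulation analysis for a tissue
#'
#' Convenience wrapper: optional annotation filtering, paired peptide
#' ratios, per-protein statistics, BH adjustment and regulation calls.
#'
#' @inheritParams compute_peptide_ratios
#' @param annotations Optional annotation tibble passed to
#'   [filter_annotated()].
#' @param thresholds An [analysis_thresholds()].
#' @param sample_unit See [protein_regulation()].
#' @return Regulation tibble with q-values and flags.
#' @export
quantify_regulation <- function(measurements, tissue,
                                annotations = NULL,
                                thresholds = analysis_thresholds(),
                                sample_unit = c("pooled", "pair_means"),
                                control = "control", case = "case") {
  if (!is.null(annotations)) {
    measurements <- filter_annotated(measurements, annotations)
  }
  ratios <- compute_peptide_ratios(measurements, tissue,
                                   n_replicates = thresholds$n_replicates,
                                   control = control, case = case)
  records <- protein_regulation(ratios, sample_unit = sample_unit)
  call_regulated(records, thresholds)
}

#' Cross-model comparison of regulated protein sets
#'
#' Partitions regulated proteins from two or three pain models into
#' model-exclusive and shared groups, carrying the direction of
#' regulation (up/down by the sign of the mean log2 fold change) per
#' model, e.g. a protein down in one model and up in the other is
#' labeled "down/up".
#'
#' @param models Named list (length 2 or 3) of tibbles, each with
#'   `protein_id` and `mean_log2fc` (or a `direction` column with
#'   values "up"/"down").
#' @return Tibble with `protein_id`, `region` (model names joined by
#'   "&"), and `directions` (per-model labels joined by "/", in the
#'   order of `models`, only for models containing the protein).
#' @export
cross_model_venn <- function(models) {
  if (is.null(names(models)) || any(names(models) == "")) {
    abort("`models` must be a named list")
  }
  if (length(models) < 2 || length(models) > 3) {
    abort("cross_model_venn supports 2 or 3 models")
  }
  dir_of <- function(d) {
    if ("direction" %in% names(d)) return(as.character(d$direction))
    ifelse(d$mean_log2fc >= 0, "up", "down")
  }
  dirs <- lapply(models, function(d) setNames(dir_of(d), d$protein_id))
  all_ids <- sort(unique(unlist(lapply(models, function(d) d$protein_id))))
  membership <- vapply(dirs, function(dd) all_ids %in% names(dd),
                       logical(length(all_ids)))
  membership <- matrix(membership, nrow = length(all_ids),
                       dimnames = list(all_ids, names(models)))
  region <- apply(membership, 1, function(row) {
    paste(names(models)[row], collapse = "&")
  })
  directions <- vapply(all_ids, function(pid) {
    present <- names(models)[membership[pid, ]]
    paste(vapply(present, function(mn) unname(dirs[[mn]][pid]),
                 character(1)), collapse = "/")
  }, character(1))
  tibble(protein_id = all_ids, region = unname(region),
         directions = unname(directions))
}
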