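# Readers, writers, annotation filtering and threshold configuration.

peptide_report_columns <- c("protein_id", "peptide_id", "tissue",
                            "condition", "replicate", "intensity")

#' Analysis thresholds
#'
#' Bundles the tunable constants of the pipeline. Defaults are the
#' study's published operating points: strict greater-than 10-fold
#' enrichment over the maximal brain region, one-tailed Welch test at
#' alpha 0.05, Benjamini-Hochberg q below 0.05 for regulation calls, a
#' dendrogram cut distance of 3.4 for protein co-expression clusters,
#' and a 3-replicate design in which each replicate pools 4 animals
#' (`pool_size` is metadata only; pooling is never modeled explicitly).
#'
#' @param fold_threshold Enrichment fold threshold (strict `>`).
#' @param welch_alpha One-tailed Welch test significance level.
#' @param q_threshold BH-adjusted p-value threshold (strict `<`).
#' @param cluster_cut_distance Flat-cluster cut height for protein
#'   dendrograms on z-scored log2 intensities.
#' @param n_replicates Replicates per tissue and condition.
#' @param pool_size Animals pooled per replicate (metadata).
#' @return An object of class `analysis_thresholds`.
#' @export
analysis_thresholds <- function(fold_threshold = 10,
                                welch_alpha = 0.05,
                                q_threshold = 0.05,
                                cluster_cut_distance = 3.4,
                                n_replicates = 3L,
                                pool_size = 4L) {
  stopifnot(is.numeric(fold_threshold), length(fold_threshold) == 1,
            fold_threshold > 0,
            is.numeric(cluster_cut_distance), cluster_cut_distance > 0,
            is.numeric(n_replicates), n_replicates >= 1,
            is.numeric(pool_size), pool_size > 0)
  if (!(welch_alpha > 0 && welch_alpha < 1)) {
    abort("`welch_alpha` must lie in (0, 1).")
  }
  if (!(q_threshold > 0 && q_threshold < 1)) {
    abort("`q_threshold` must lie in (0, 1).")
  }
  structure(list(fold_threshold = fold_threshold,
                 welch_alpha = welch_alpha,
                 q_threshold = q_threshold,
                 cluster_cut_distance = cluster_cut_distance,
                 n_replicates = as.integer(n_replicates),
                 pool_size = as.integer(pool_size)),
            class = "analysis_thresholds")
}

#' Read an analysis configuration file
#'
#' A flat YAML file with two optional top-level blocks: `thresholds`
#' (any field of [analysis_thresholds()]) and `columns` (a dialect map
#' for [read_peptide_report()], canonical name -> file column name).
#'
#' @param path Path to a YAML file.
#' @return List with elements `thresholds` and `dialect`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  thr <- do.call(analysis_thresholds, as.list(cfg$thresholds %||% list()))
  dialect <- unlist(cfg$columns %||% list())
  list(thresholds = thr, dialect = if (length(dialect)) dialect else NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

validate_measurements <- function(x, call_site = "measurements") {
  missing_cols <- setdiff(peptide_report_columns, names(x))
  if (length(missing_cols)) {
    abort(sprintf("%s is missing required column(s): %s",
                  call_site, paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(x$intensity)) || any(x$intensity <= 0)) {
    abort("all intensities must be finite and strictly positive")
  }
  key <- paste(x$protein_id, x$peptide_id, x$tissue, x$condition,
               x$replicate, sep = "\r")
  dup <- anyDuplicated(key)
  if (dup) {
    abort(sprintf(
      "duplicate measurement key: protein %s, peptide %s, %s/%s replicate %s",
      x$protein_id[dup], x$peptide_id[dup], x$tissue[dup],
      x$condition[dup], x$replicate[dup]))
  }
  invisible(x)
}

#' Read a long-format peptide quantification report
#'
#' Loads a tab-separated DIA-style peptide report with one quantified
#' peptide intensity per (protein, peptide, tissue, condition,
#' replicate) cell. Intensities are consumed on the linear scale; log2
#' transforms are applied only inside the downstream operations that
#' need them. Rows whose intensity is missing, non-numeric or not
#' strictly positive are dropped (non-detection semantics of DIA
#' exports) and counted in the load report, retrievable with
#' [load_report()].
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect Optional named character vector mapping canonical
#'   column names (`protein_id`, `peptide_id`, `tissue`, `condition`,
#'   `replicate`, `intensity`) to the column names used in the file.
#' @return A tibble of validated measurements with a `load_report`
#'   attribute (`rows_in`, `rows_loaded`, `rows_dropped`).
#' @export
read_peptide_report <- function(path, dialect = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE, col_types = readr::cols())
  file_names <- peptide_report_columns
  if (!is.null(dialect)) {
    unknown <- setdiff(names(dialect), peptide_report_columns)
    if (length(unknown)) {
      abort(sprintf("dialect maps unknown field(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    file_names[match(names(dialect), peptide_report_columns)] <- unname(dialect)
  }
  missing_cols <- setdiff(file_names, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("peptide report is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(
    protein_id = as.character(raw[[file_names[1]]]),
    peptide_id = as.character(raw[[file_names[2]]]),
    tissue     = as.character(raw[[file_names[3]]]),
    condition  = as.character(raw[[file_names[4]]]),
    replicate  = as.integer(raw[[file_names[5]]]),
    intensity  = suppressWarnings(as.numeric(raw[[file_names[6]]]))
  )
  keep <- is.finite(out$intensity) & out$intensity > 0
  dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  validate_measurements(out, call_site = path)
  attr(out, "load_report") <- list(rows_in = nrow(raw),
                                   rows_loaded = nrow(out),
                                   rows_dropped = dropped)
  out
}

#' @rdname read_peptide_report
#' @param x A measurement tibble returned by [read_peptide_report()] or
#'   [filter_annotated()].
#' @export
load_report <- function(x) attr(x, "load_report")

#' Write measurements back to a peptide report TSV
#'
#' Inverse of [read_peptide_report()]: writing and re-reading yields an
#' identical collection.
#'
#' @param measurements Measurement tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_report <- function(measurements, path) {
  validate_measurements(measurements)
  readr::write_tsv(measurements[peptide_report_columns], path, progress = FALSE)
  invisible(path)
}

#' Read a protein annotation table
#'
#' Expects a TSV with columns `protein_id`, `gene`, `reviewed` and
#' optionally `contaminant` (0/1 or logical). When no contaminant
#' column is present, the keratin convenience rule flags any gene
#' symbol starting with "Krt" (case-insensitive), mirroring routine
#' removal of keratin contamination from tissue proteomes.
#'
#' @param path Path to the annotation TSV.
#' @return Tibble with columns `protein_id`, `gene`, `reviewed`,
#'   `contaminant` (logical).
#' @export
read_annotations <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols())
  need <- c("protein_id", "gene", "reviewed")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("annotation table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  contaminant <- if ("contaminant" %in% names(raw)) {
    as.logical(as.integer(raw$contaminant))
  } else {
    grepl("^krt", as.character(raw$gene), ignore.case = TRUE)
  }
  out <- tibble(protein_id = as.character(raw$protein_id),
                gene = as.character(raw$gene),
                reviewed = as.logical(as.integer(raw$reviewed)),
                contaminant = contaminant)
  if (anyDuplicated(out$protein_id)) {
    abort(sprintf("duplicate protein_id in annotation table: %s",
                  out$protein_id[anyDuplicated(out$protein_id)]))
  }
  out
}

#' @rdname read_annotations
#' @param annotations Annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}

#' Restrict measurements to reviewed, non-contaminant proteins
#'
#' Applies the identifier hygiene step used before every comparative
#' analysis: only proteins whose annotation is a reviewed entry and not
#' flagged as contamination (e.g. keratins) are retained. Counts
#' removed by each rule are attached as the `filter_report` attribute.
#'
#' @param measurements Measurement tibble.
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param unannotated What to do with proteins lacking an annotation
#'   record: `"drop"` (default, with a warning) or `"error"`.
#' @return Filtered measurement tibble with a `filter_report`
#'   attribute listing `removed_unannotated`, `removed_unreviewed`,
#'   `removed_contaminant` (protein counts) and `rows_removed`.
#' @export
filter_annotated <- function(measurements, annotations,
                             unannotated = c("drop", "error")) {
  unannotated <- match.arg(unannotated)
  validate_measurements(measurements)
  proteins <- unique(measurements$protein_id)
  missing_ann <- setdiff(proteins, annotations$protein_id)
  if (length(missing_ann) && unannotated == "error") {
    abort(sprintf("%d protein(s) have no annotation record (first: %s)",
                  length(missing_ann), missing_ann[1]))
  }
  if (length(missing_ann)) {
    warn(sprintf("dropping %d unannotated protein(s)", length(missing_ann)))
  }
  ann <- annotations[match(proteins, annotations$protein_id), ]
  keep_protein <- proteins[!is.na(ann$protein_id) & ann$reviewed &
                             !ann$contaminant]
  n_unreviewed <- sum(!is.na(ann$protein_id) & !ann$reviewed)
  n_contaminant <- sum(!is.na(ann$protein_id) & ann$reviewed & ann$contaminant)
  out <- measurements[measurements$protein_id %in% keep_protein, ,
                      drop = FALSE]
  attr(out, "load_report") <- attr(measurements, "load_report")
  attr(out, "filter_report") <- list(
    removed_unannotated = length(missing_ann),
    removed_unreviewed = n_unreviewed,
    removed_contaminant = n_contaminant,
    rows_removed = nrow(measurements) - nrow(out))
  out
}

#' @rdname filter_annotated
#' @param x A filtered measurement tibble.
#' @export
filter_report <- function(x) attr(x, "filter_report")
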