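# PNS/SC-enriched proteome classification against the brain reference.

#' Maximal brain-region abundance of a protein
#'
#' Among the brain regions in which the protein passes the detection
#' rule (i.e. is listed in the region's proteome), returns the region
#' with the highest cross-replicate mean intensity. Ties are broken by
#' the fixed region order ACC < AMY < PFC < CER so results are
#' deterministic.
#'
#' @param brain_proteomes Named list of `tissue_proteome` objects for
#'   the brain regions (any subset of ACC, AMY, PFC, CER).
#' @param protein_id Protein accession.
#' @return List with `region` and `mean_intensity`, or `NULL` when the
#'   protein is detected in no brain region.
#' @export
max_brain_abundance <- function(brain_proteomes, protein_id) {
  order_ref <- brain_tissues()
  regions <- vapply(brain_proteomes, function(p) p$tissue, character(1))
  ord <- order(match(regions, order_ref))
  best <- NULL
  for (p in brain_proteomes[ord]) {
    rows <- p$proteins[p$proteins$protein_id == protein_id, ]
    if (!nrow(rows)) next
    if (is.null(best) || rows$mean_intensity[1] > best$mean_intensity) {
      best <- list(region = p$tissue, mean_intensity = rows$mean_intensity[1])
    }
  }
  best
}

#' One-tailed Welch's t-test
#'
#' Unequal-variance two-sample t-test with the alternative that the
#' mean of `a` exceeds the mean of `b` (upper tail), as used to back
#' the fold-enrichment criterion. Degenerate inputs do not produce a
#' statistic: fewer than two values in either sample, or two
#' zero-variance samples, yield `NA` with a `reason`.
#'
#' @param a,b Numeric vectors of per-replicate intensities.
#' @return List with `t`, `df`, `p` and `reason` (`"ok"`,
#'   `"insufficient_n"` or `"zero_variance"`).
#' @export
welch_one_tailed <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                reason = "insufficient_n"))
  }
  if (var(a) == 0 && var(b) == 0) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                reason = "zero_variance"))
  }
  # t.test also refuses near-constant samples (combined stderr below
  # ~10 eps of the mean difference); treat those like zero variance
  ht <- tryCatch(t.test(a, b, alternative = "greater", var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(ht)) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                reason = "zero_variance"))
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), reason = "ok")
}

#' Classify tissue-enriched proteins against the brain reference
#'
#' Implements the two-criterion subtractive definition of a
#' PNS-enriched (target SN or DRG) or SC-enriched (target SC)
#' proteome. For each protein of the target proteome:
#'
#' * criterion A (`A_absent_in_brain`): the protein is detected in
#'   none of the supplied brain proteomes;
#' * criterion B (`B_fold_enriched`): its target mean is strictly more
#'   than `fold_threshold`-fold above the maximal brain-region mean
#'   and a one-tailed Welch test of the target replicate intensities
#'   against that region's replicate intensities gives
#'   p < `welch_alpha`;
#' * otherwise `rejected`.
#'
#' When both replicate vectors have zero variance the Welch statistic
#' is undefined and the decision falls back to the fold criterion
#' alone (noted in the `note` column, with a warning).
#'
#' @param target_proteome `tissue_proteome` of the target tissue.
#' @param brain_proteomes Named list of brain `tissue_proteome`s.
#' @param thresholds An [analysis_thresholds()].
#' @param log2_scale Run the Welch test on log2 replicate intensities
#'   instead of the linear scale.
#' @param absence_rule How criterion A judges brain absence:
#'   `"detection_rule"` (default; absent from every brain proteome) or
#'   `"any_peptide"` (absent if no single brain peptide measurement
#'   exists; requires `brain_measurements`).
#' @param brain_measurements Raw measurement tibble covering the brain
#'   tissues; only needed for `absence_rule = "any_peptide"`.
#' @return Tibble of decisions: `protein_id`, `target_tissue`,
#'   `criterion`, `fold_enrichment`, `welch_p`, `secondary_filter`
#'   (initially `"not_applied"`), `note`.
#' @export
classify_enriched <- function(target_proteome, brain_proteomes,
                              thresholds = analysis_thresholds(),
                              log2_scale = FALSE,
                              absence_rule = c("detection_rule",
                                               "any_peptide"),
                              brain_measurements = NULL) {
  absence_rule <- match.arg(absence_rule)
  if (absence_rule == "any_peptide" && is.null(brain_measurements)) {
    abort("absence_rule = \"any_peptide\" requires `brain_measurements`")
  }
  brain_seen <- if (absence_rule == "any_peptide") {
    unique(brain_measurements$protein_id[
      brain_measurements$tissue %in% brain_tissues()])
  } else NULL

  proteins <- target_proteome$proteins
  n <- nrow(proteins)
  criterion <- character(n)
  fold <- rep(NA_real_, n)
  welch_p <- rep(NA_real_, n)
  note <- rep(NA_character_, n)
  zero_var_seen <- FALSE

  for (i in seq_len(n)) {
    pid <- proteins$protein_id[i]
    mb <- max_brain_abundance(brain_proteomes, pid)
    absent <- if (absence_rule == "any_peptide") {
      !(pid %in% brain_seen)
    } else {
      is.null(mb)
    }
    if (absent) {
      criterion[i] <- "A_absent_in_brain"
      next
    }
    if (is.null(mb)) {
      # seen in brain by a stray peptide but never passing detection:
      # no abundance to compare against, cannot be fold-enriched
      criterion[i] <- "rejected"
      note[i] <- "brain_presence_without_abundance"
      next
    }
    fold[i] <- proteins$mean_intensity[i] / mb$mean_intensity
    if (fold[i] > thresholds$fold_threshold) {
      a <- replicate_values(target_proteome, pid)
      b <- replicate_values(brain_proteomes[[
        which(vapply(brain_proteomes, function(p) p$tissue,
                     character(1)) == mb$region)[1]]], pid)
      if (log2_scale) {
        a <- log2(a)
        b <- log2(b)
      }
      w <- welch_one_tailed(a, b)
      welch_p[i] <- w$p
      if (w$reason == "zero_variance") {
        criterion[i] <- "B_fold_enriched"
        note[i] <- "zero_variance_fold_only"
        zero_var_seen <- TRUE
      } else if (w$reason == "insufficient_n") {
        criterion[i] <- "rejected"
        note[i] <- "untestable"
      } else {
        criterion[i] <- if (w$p < thresholds$welch_alpha)
          "B_fold_enriched" else "rejected"
      }
    } else {
      criterion[i] <- "rejected"
    }
  }
  if (zero_var_seen) {
    warn("zero-variance replicate pair(s): fold-only enrichment decision")
  }
  tibble(protein_id = proteins$protein_id,
         target_tissue = target_proteome$tissue,
         criterion = criterion,
         fold_enrichment = fold,
         welch_p = welch_p,
         secondary_filter = "not_applied",
         note = note)
}

#' Subtract a secondary brain reference from an enriched list
#'
#' Cross-checks every enriched protein against an independently
#' analyzed brain dataset (e.g. a deep reference brain proteome
#' re-searched with an in-silico library). A protein seen in any
#' secondary brain tissue is removed from the enriched list unless it
#' still clears the fold/Welch enrichment criteria against the
#' secondary maximal brain abundance. Partial brain observations in
#' the raw secondary data (peptides seen in fewer than all replicates)
#' count as brain presence when `secondary_measurements` is supplied,
#' making the subtraction stricter than the detection rule.
#'
#' @param decisions Decision tibble from [classify_enriched()].
#' @param target_proteome The target `tissue_proteome` (for replicate
#'   intensities and means).
#' @param secondary_brain Named list of secondary brain
#'   `tissue_proteome`s, or `NULL` (decisions pass unchanged with a
#'   warning and `secondary_filter = "not_applied"`).
#' @param thresholds An [analysis_thresholds()].
#' @param secondary_measurements Optional raw secondary measurement
#'   tibble used to count partial brain observations as presence.
#' @param log2_scale Welch test scale, as in [classify_enriched()].
#' @return The decision tibble with `secondary_filter` set to
#'   `"passed"` or `"removed"` for enriched proteins.
#' @export
apply_secondary_filter <- function(decisions, target_proteome,
                                   secondary_brain,
                                   thresholds = analysis_thresholds(),
                                   secondary_measurements = NULL,
                                   log2_scale = FALSE) {
  if (is.null(secondary_brain) || !length(secondary_brain)) {
    warn("no secondary brain data supplied; secondary filter not applied")
    decisions$secondary_filter <- "not_applied"
    return(decisions)
  }
  seen_secondary <- if (!is.null(secondary_measurements)) {
    unique(secondary_measurements$protein_id[
      secondary_measurements$tissue %in% brain_tissues()])
  } else NULL

  for (i in seq_len(nrow(decisions))) {
    if (decisions$criterion[i] == "rejected") next
    pid <- decisions$protein_id[i]
    present <- if (!is.null(seen_secondary)) {
      pid %in% seen_secondary
    } else {
      any(vapply(secondary_brain, proteome_has, logical(1),
                 protein_id = pid))
    }
    if (!present) {
      decisions$secondary_filter[i] <- "passed"
      next
    }
    mb <- max_brain_abundance(secondary_brain, pid)
    if (is.null(mb)) {
      # present only as partial observations: no abundance to beat
      decisions$secondary_filter[i] <- "removed"
      next
    }
    target_mean <- target_proteome$proteins$mean_intensity[
      target_proteome$proteins$protein_id == pid]
    fold2 <- target_mean / mb$mean_intensity
    ok <- FALSE
    if (length(fold2) && fold2 > thresholds$fold_threshold) {
      a <- replicate_values(target_proteome, pid)
      b <- replicate_values(secondary_brain[[
        which(vapply(secondary_brain, function(p) p$tissue,
                     character(1)) == mb$region)[1]]], pid)
      if (log2_scale) {
        a <- log2(a)
        b <- log2(b)
      }
      w <- welch_one_tailed(a, b)
      ok <- (w$reason == "zero_variance") ||
        (w$reason == "ok" && w$p < thresholds$welch_alpha)
    }
    decisions$secondary_filter[i] <- if (ok) "passed" else "removed"
  }
  decisions
}

#' Final enriched protein set of a decision table
#'
#' Proteins classified under criterion A or B that were not removed by
#' the secondary filter.
#'
#' @param decisions Decision tibble.
#' @return Character vector of protein ids.
#' @export
enriched_proteins <- function(decisions) {
  sort(decisions$protein_id[decisions$criterion != "rejected" &
                              decisions$secondary_filter != "removed"])
}

#' Partition PNS-enriched proteins by tissue preference
#'
#' Labels each PNS-enriched protein as SN-specific, DRG-specific or
#' shared. A protein is tissue-specific when it is enriched in one PNS
#' tissue and not even detected in the other tissue's proteome;
#' proteins enriched in both, or enriched in one but detected in the
#' other, are shared.
#'
#' @param decisions_sn,decisions_drg Decision tibbles for SN and DRG.
#' @param proteome_sn,proteome_drg The corresponding tissue proteomes.
#' @return Tibble with `protein_id` and `preference` in
#'   `{"SN_specific", "DRG_specific", "shared"}`.
#' @export
partition_tissue_preference <- function(decisions_sn, decisions_drg,
                                        proteome_sn, proteome_drg) {
  enr_sn <- enriched_proteins(decisions_sn)
  enr_drg <- enriched_proteins(decisions_drg)
  all_ids <- sort(union(enr_sn, enr_drg))
  pref <- vapply(all_ids, function(pid) {
    in_sn <- pid %in% enr_sn
    in_drg <- pid %in% enr_drg
    if (in_sn && !in_drg && !proteome_has(proteome_drg, pid)) {
      "SN_specific"
    } else if (in_drg && !in_sn && !proteome_has(proteome_sn, pid)) {
      "DRG_specific"
    } else {
      "shared"
    }
  }, character(1))
  tibble(protein_id = all_ids, preference = unname(pref))
}
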