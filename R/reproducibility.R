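# Replicate-level QC: correlations, densities, hierarchical clustering.

#' Build a protein-by-sample intensity matrix
#'
#' Arranges protein-per-replicate mean intensities (from
#' [aggregate_protein_intensities()]) into a matrix with one row per
#' protein and one column per selected sample (tissue x condition x
#' replicate). Proteins unobserved in a sample carry `NA`.
#'
#' @param replicate_intensities Tibble from
#'   [aggregate_protein_intensities()].
#' @param samples Optional tibble with columns `tissue`, `condition`,
#'   `replicate` selecting and ordering the columns; default all
#'   samples present, in tissue-panel order. Duplicate selections are
#'   an error.
#' @return Object of class `intensity_matrix`: list with `values`
#'   (numeric matrix), `transform` (`"linear"`), and empty
#'   `constant_rows` / `degenerate_rows` flags.
#' @export
build_intensity_matrix <- function(replicate_intensities, samples = NULL) {
  ri <- replicate_intensities
  if (is.null(samples)) {
    samples <- ri |>
      distinct(.data$tissue, .data$condition, .data$replicate) |>
      arrange(match(.data$tissue, neurax_tissues()), .data$condition,
              .data$replicate)
  }
  samples <- as_tibble(samples)[c("tissue", "condition", "replicate")]
  if (!nrow(samples)) abort("empty sample selection")
  key <- paste(samples$tissue, samples$condition, samples$replicate)
  if (anyDuplicated(key)) {
    abort(sprintf("sample selected twice: %s", key[anyDuplicated(key)]))
  }
  labels <- paste(samples$tissue, samples$condition,
                  paste0("r", samples$replicate), sep = "_")
  proteins <- sort(unique(ri$protein_id))
  values <- matrix(NA_real_, nrow = length(proteins), ncol = nrow(samples),
                   dimnames = list(proteins, labels))
  ri_key <- paste(ri$tissue, ri$condition, ri$replicate)
  for (j in seq_len(nrow(samples))) {
    sel <- ri[ri_key == key[j], ]
    values[sel$protein_id, j] <- sel$mean_intensity
  }
  structure(list(values = values, transform = "linear",
                 constant_rows = character(),
                 degenerate_rows = character()),
            class = "intensity_matrix")
}

#' Log2-transform and z-score an intensity matrix by row
#'
#' The normalization used ahead of heatmap clustering: each protein
#' row is log2-transformed, centered on its mean and divided by its
#' sample standard deviation (computed over non-missing entries).
#' Constant rows (sd 0) become all-zero and are flagged in
#' `constant_rows` instead of being dropped, keeping the row universe
#' stable. Rows with a single non-missing value have no defined sd;
#' they are set to `NA` and flagged in `degenerate_rows`, so
#' complete-case clustering excludes them. Applying the transform
#' twice is an error.
#'
#' @param m An `intensity_matrix` in linear state.
#' @return The matrix in `log2_zscored` state.
#' @export
log2_zscore <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$transform != "linear") {
    abort(sprintf("matrix is already transformed (state: %s)", m$transform))
  }
  x <- log2(m$values)
  constant_rows <- character()
  degenerate_rows <- character()
  for (i in seq_len(nrow(x))) {
    obs <- !is.na(x[i, ])
    n_obs <- sum(obs)
    if (n_obs < 2) {
      x[i, ] <- NA_real_
      degenerate_rows <- c(degenerate_rows, rownames(x)[i])
      next
    }
    s <- sd(x[i, obs])
    if (s == 0) {
      x[i, obs] <- 0
      constant_rows <- c(constant_rows, rownames(x)[i])
    } else {
      x[i, obs] <- (x[i, obs] - mean(x[i, obs])) / s
    }
  }
  structure(list(values = x, transform = "log2_zscored",
                 constant_rows = constant_rows,
                 degenerate_rows = degenerate_rows),
            class = "intensity_matrix")
}

#' Pairwise Pearson correlation between samples
#'
#' Pearson r for every pair of columns over the rows non-missing in
#' both (pairwise-complete). Pairs sharing fewer than two rows have no
#' defined correlation and yield `NA` with a warning. The diagonal
#' is 1.
#'
#' @param m An `intensity_matrix` (any transform state).
#' @return Symmetric correlation matrix.
#' @export
pairwise_pearson <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  x <- m$values
  shared <- crossprod(!is.na(x))
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  if (any(shared[upper.tri(shared)] < 2)) {
    warn("sample pair(s) share fewer than 2 proteins; correlation undefined")
  }
  r[shared < 2] <- NA_real_
  diag(r) <- 1
  r
}

#' Hierarchical clustering of samples and proteins
#'
#' Agglomerative clustering with Euclidean distance and average
#' (UPGMA) linkage, run separately over columns (samples) and rows
#' (proteins) of a z-scored matrix. Rows containing any missing value
#' are excluded (complete-case, the standard heatmap-tool behavior).
#' Flat protein clusters are cut at `cut_distance` (default 3.4, the
#' visualization threshold for co-expression clusters).
#'
#' @param m An `intensity_matrix` in `log2_zscored` state.
#' @param cut_distance Cut height for flat protein clusters.
#' @return List of class `sample_clustering`: `sample_dendrogram` and
#'   `protein_dendrogram` (hclust objects), `protein_clusters` (named
#'   integer vector), `excluded_rows`.
#' @export
cluster_samples <- function(m, cut_distance = 3.4) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (m$transform != "log2_zscored") {
    abort("cluster_samples expects a log2 z-scored matrix; see log2_zscore()")
  }
  complete <- rowSums(is.na(m$values)) == 0
  x <- m$values[complete, , drop = FALSE]
  if (nrow(x) < 2) abort("fewer than 2 complete protein rows")
  if (ncol(x) < 2) abort("fewer than 2 samples")
  sample_hc <- hclust(dist(t(x)), method = "average")
  protein_hc <- hclust(dist(x), method = "average")
  structure(list(sample_dendrogram = sample_hc,
                 protein_dendrogram = protein_hc,
                 protein_clusters = cutree(protein_hc, h = cut_distance),
                 excluded_rows = rownames(m$values)[!complete]),
            class = "sample_clustering")
}

#' Kernel density estimates of sample intensity distributions
#'
#' Gaussian-kernel density of the log2 intensities of each sample
#' (Silverman's rule-of-thumb bandwidth), for visualizing whether
#' replicate intensity distributions agree.
#'
#' @param m An `intensity_matrix` in linear state.
#' @param n Grid points per density curve.
#' @return Tibble with `sample`, `x` (log2 intensity), `density`.
#' @export
intensity_density <- function(m, n = 512) {
  stopifnot(inherits(m, "intensity_matrix"), m$transform == "linear")
  out <- lapply(colnames(m$values), function(cn) {
    v <- log2(m$values[, cn])
    v <- v[is.finite(v)]
    d <- density(v, bw = "nrd0", n = n)
    tibble(sample = cn, x = d$x, density = d$y)
  })
  bind_rows(out)
}
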