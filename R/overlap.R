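# Protein-list normalization, percentage overlap, Venn partitioning.

#' Named protein list
#'
#' A deduplicated set of protein accessions in a common identifier
#' space, with bookkeeping from identifier normalization.
#'
#' @param accessions Character vector of accessions (deduplicated,
#'   input order preserved).
#' @param name List name used in reports.
#' @param source_count Pre-normalization size of the raw list.
#' @param unmapped_ids Raw identifiers that mapped to nothing.
#' @param multi_mapped_count Raw identifiers that mapped to more than
#'   one accession (all targets retained).
#' @return Object of class `protein_list`.
#' @export
protein_list <- function(accessions, name = "list",
                         source_count = length(accessions),
                         unmapped_ids = character(),
                         multi_mapped_count = 0L) {
  accessions <- unique(as.character(accessions))
  structure(list(name = name,
                 accessions = accessions,
                 source_count = as.integer(source_count),
                 unmapped_count = length(unmapped_ids),
                 unmapped_ids = as.character(unmapped_ids),
                 multi_mapped_count = as.integer(multi_mapped_count)),
            class = "protein_list")
}

#' @export
print.protein_list <- function(x, ...) {
  cat(sprintf("Protein list '%s': %d accessions (from %d raw ids, %d unmapped)\n",
              x$name, length(x$accessions), x$source_count, x$unmapped_count))
  invisible(x)
}

as_accessions <- function(x) {
  if (inherits(x, "protein_list")) x$accessions else unique(as.character(x))
}

#' Read a plain-text protein list
#'
#' One accession per line; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path File path.
#' @param name List name; defaults to the file name.
#' @return A [protein_list()].
#' @export
read_protein_list <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  protein_list(lines, name = name, source_count = length(lines))
}

#' Read a raw-identifier to accession mapping table
#'
#' Two-column TSV (`raw`, `accession`), with or without a header row.
#'
#' @param path File path.
#' @return Tibble with columns `raw`, `accession`.
#' @export
read_id_mapping <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("raw", "accession"),
                         show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) && identical(tolower(unlist(raw[1, ])),
                             c(raw = "raw", accession = "accession"))) {
    raw <- raw[-1, ]
  }
  as_tibble(raw)
}

#' Normalize raw identifiers into an accession set
#'
#' Converts raw identifiers (gene symbols, foreign accessions, ...) to
#' the common accession space through a user-supplied mapping table,
#' mirroring offline conversion to reviewed UniProt identifiers.
#' Mapped accessions are deduplicated into a set; raw ids mapping to
#' several accessions keep all targets (union semantics, conservative
#' for overlap claims) and are counted; unmapped ids are counted and
#' listed, since conversion typically loses some identifiers.
#'
#' @param ids Character vector of raw identifiers.
#' @param mapping Data frame with columns `raw`, `accession`.
#' @param name Name for the resulting list.
#' @return A [protein_list()].
#' @export
normalize_ids <- function(ids, mapping, name = "list") {
  ids <- as.character(ids)
  stopifnot(all(c("raw", "accession") %in% names(mapping)))
  hits <- mapping[mapping$raw %in% ids, ]
  n_targets <- table(factor(hits$raw, levels = unique(ids)))
  unmapped <- names(n_targets)[n_targets == 0]
  multi <- sum(n_targets > 1)
  protein_list(hits$accession, name = name,
               source_count = length(ids),
               unmapped_ids = unmapped,
               multi_mapped_count = multi)
}

#' Percentage overlap between two protein lists
#'
#' Intersection size and both directional percentages,
#' 100 * |a intersect b| / |x|. Percentages are reported at full
#' precision; [percent_label()] applies the round-half-up integer
#' display convention. An empty list leaves its directional
#' percentage undefined (`NA`) with a warning.
#'
#' @param a,b [protein_list()]s or character vectors.
#' @return One-row tibble: `list_a`, `list_b`, `n_a`, `n_b`,
#'   `n_intersection`, `pct_of_a`, `pct_of_b`.
#' @export
percentage_overlap <- function(a, b) {
  name_of <- function(x, default) {
    if (inherits(x, "protein_list")) x$name else default
  }
  sa <- as_accessions(a)
  sb <- as_accessions(b)
  n_int <- length(intersect(sa, sb))
  if (!length(sa) || !length(sb)) {
    warn("empty protein list: directional percentage undefined")
  }
  tibble(list_a = name_of(a, "a"), list_b = name_of(b, "b"),
         n_a = length(sa), n_b = length(sb),
         n_intersection = n_int,
         pct_of_a = if (length(sa)) 100 * n_int / length(sa) else NA_real_,
         pct_of_b = if (length(sb)) 100 * n_int / length(sb) else NA_real_)
}

#' Round-half-up integer percent label
#'
#' The display convention for report text (e.g. 1306/4103 -> "31%").
#'
#' @param pct Numeric percentage.
#' @return Integer vector.
#' @export
percent_label <- function(pct) as.integer(floor(pct + 0.5))

#' Exclusive Venn partition of 2 or 3 protein lists
#'
#' Partitions the union of the input lists into all 2^k - 1 exclusive
#' regions. Region names join the names of the containing lists with
#' `&`. Counts sum exactly to the union size.
#'
#' @param lists Named list of 2 or 3 [protein_list()]s or character
#'   vectors.
#' @return Tibble with `region`, `n`, and a `members` list-column.
#' @export
venn_partition <- function(lists) {
  if (length(lists) < 2 || length(lists) > 3) {
    abort("venn_partition supports exactly 2 or 3 lists")
  }
  if (is.null(names(lists)) || any(names(lists) == "")) {
    names(lists) <- LETTERS[seq_along(lists)]
  }
  sets <- lapply(lists, as_accessions)
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    inc <- unlist(combos[i, ])
    members <- Reduce(intersect, sets[inc])
    for (s in sets[!inc]) members <- setdiff(members, s)
    tibble(region = paste(names(sets)[inc], collapse = "&"),
           n = length(members), members = list(sort(members)))
  })
  bind_rows(rows) |> arrange(desc(nchar(.data$region)), .data$region)
}

#' Subtract an atlas presence list from an enriched proteome
#'
#' Set difference enriched \\ atlas: the proteins of an enriched list
#' without reliable expression evidence in a body-wide protein atlas,
#' i.e. putative candidates for tissue-enriched expression in humans.
#'
#' @param enriched,atlas_present [protein_list()]s or character
#'   vectors.
#' @return A [protein_list()] of the remaining accessions.
#' @export
atlas_subtraction <- function(enriched, atlas_present) {
  name_of <- function(x, default) {
    if (inherits(x, "protein_list")) x$name else default
  }
  remaining <- setdiff(as_accessions(enriched), as_accessions(atlas_present))
  protein_list(remaining,
               name = paste0(name_of(enriched, "enriched"), "_minus_",
                             name_of(atlas_present, "atlas")))
}
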