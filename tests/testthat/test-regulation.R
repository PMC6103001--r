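ratio_tbl <- function(ratios, protein = "P1", peptide = "pep1",
                      tissue = "DRG") {
  tibble::tibble(protein_id = protein,
                 peptide_id = paste0(protein, "_", peptide),
                 tissue = tissue,
                 pair_index = seq_along(ratios),
                 log2_ratio = ratios)
}

test_that("peptide ratios pair case and control by replicate index", {
  m <- dplyr::bind_rows(
    cell_measurements("P1", "DRG", "case", c(200, 200, 200)),
    cell_measurements("P1", "DRG", "control", c(100, 100, 100)))
  r <- compute_peptide_ratios(m, "DRG")
  expect_equal(r$log2_ratio, c(1, 1, 1))
  expect_equal(r$pair_index, 1:3)

  m2 <- dplyr::bind_rows(
    cell_measurements("P1", "DRG", "case", c(100, 200, 400)),
    cell_measurements("P1", "DRG", "control", c(100, 100, 100)))
  expect_equal(compute_peptide_ratios(m2, "DRG")$log2_ratio, c(0, 1, 2))

  # a peptide missing one control replicate contributes nothing
  m3 <- m[!(m$condition == "control" & m$replicate == 2), ]
  expect_equal(nrow(compute_peptide_ratios(m3, "DRG")), 0)
})

test_that("a protein absent from any of the six cells yields no record", {
  m <- dplyr::bind_rows(
    cell_measurements("P1", "DRG", "case", c(110, 120, 130)),
    cell_measurements("P1", "DRG", "control", c(100, 100, 100)),
    cell_measurements("P2", "DRG", "case", c(50, 60, 70)))
  reg <- quantify_regulation(m, "DRG")
  expect_equal(reg$protein_id, "P1")
})

test_that("one-sample t on pooled ratios matches the closed form", {
  reg <- protein_regulation(ratio_tbl(c(0.5, 0.6, 0.7)))
  expect_equal(reg$mean_log2fc, 0.6)
  o <- oracle_one_sample_t(c(0.5, 0.6, 0.7))
  expect_equal(o$t, 10.392305, tolerance = 1e-6)
  expect_equal(reg$p_value, o$p, tolerance = 1e-10)
  expect_equal(reg$p_value, 0.00913, tolerance = 1e-3)

  sym <- protein_regulation(ratio_tbl(c(-1, 0, 1)))
  expect_equal(sym$mean_log2fc, 0)
  expect_equal(sym$p_value, 1)
})

test_that("degenerate ratio sets follow the zero-variance policy", {
  zeros <- protein_regulation(ratio_tbl(c(0, 0, 0)))
  expect_equal(zeros$p_value, 1)
  expect_false(zeros$untestable)
  expect_false(call_regulated(zeros)$regulated)

  const <- protein_regulation(ratio_tbl(c(0.5, 0.5, 0.5)))
  expect_true(is.na(const$p_value))
  expect_true(const$untestable)
  called <- call_regulated(const)
  expect_true(is.na(called$q_value))
  expect_false(called$regulated)
})

test_that("the per-pair-mean sample unit is available as a switch", {
  two_peps <- dplyr::bind_rows(ratio_tbl(c(0.2, 0.4, 0.6), peptide = "a"),
                               ratio_tbl(c(0.4, 0.6, 0.8), peptide = "b"))
  pooled <- protein_regulation(two_peps)
  pair_means <- protein_regulation(two_peps, sample_unit = "pair_means")
  expect_equal(pooled$mean_log2fc, pair_means$mean_log2fc)
  expect_equal(pair_means$p_value,
               oracle_one_sample_t(c(0.3, 0.5, 0.7))$p, tolerance = 1e-10)
  expect_equal(pooled$p_value,
               oracle_one_sample_t(c(0.2, 0.4, 0.6, 0.4, 0.6, 0.8))$p,
               tolerance = 1e-10)
  expect_equal(pooled$n_ratios, 6L)
  expect_equal(pooled$n_peptides, 2L)
})

test_that("BH step-up adjustment reproduces hand computations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.005, 0.05)), c(0.01, 0.05))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")

  withr::local_seed(8)
  for (i in 1:25) {
    p <- stats::runif(sample(2:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_false(is.unsorted(q[order(p)])) # q preserves the order of p
  }
})

test_that("regulated calls use strict q < 0.05 with single-peptide flag", {
  records <- tibble::tibble(
    protein_id = c("Col14a1", "Apoh", "Edge"),
    tissue = "DRG",
    mean_log2fc = c(0.28, 0.35, 0.10),
    p_value = c(1e-4, 0.2, 0.04),
    n_peptides = c(1L, 4L, 2L),
    n_ratios = c(3L, 12L, 6L),
    untestable = FALSE,
    q_value = c(0.001, 0.265, 0.05))
  out <- call_regulated(records)
  expect_equal(out$regulated, c(TRUE, FALSE, FALSE)) # q = 0.05 is not < 0.05
  expect_equal(out$low_confidence, c(TRUE, FALSE, FALSE))
})

test_that("swapping case and control negates fold changes, keeps p and q", {
  withr::local_seed(19)
  m <- random_measurements(n_proteins = 10, n_peptides = 3,
                           tissues = "SN", conditions = c("control", "case"),
                           p_present = 0.9)
  fwd <- quantify_regulation(m, "SN")
  swapped <- dplyr::mutate(m, condition = ifelse(condition == "case",
                                                 "control", "case"))
  rev <- quantify_regulation(swapped, "SN")
  expect_equal(fwd$protein_id, rev$protein_id)
  expect_equal(fwd$mean_log2fc, -rev$mean_log2fc, tolerance = 1e-12)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
  expect_equal(fwd$q_value, rev$q_value, tolerance = 1e-12)
})

test_that("cross-model comparison partitions shared and exclusive hits", {
  models <- list(
    SNI = tibble::tibble(protein_id = c("P1", "P2"),
                         mean_log2fc = c(0.5, -0.4)),
    CFA = tibble::tibble(protein_id = c("P2", "P3"),
                         mean_log2fc = c(0.3, 0.8)))
  v <- cross_model_venn(models)
  expect_equal(v$region[v$protein_id == "P2"], "SNI&CFA")
  expect_equal(v$directions[v$protein_id == "P2"], "down/up")
  expect_equal(v$region[v$protein_id == "P1"], "SNI")
  expect_equal(v$region[v$protein_id == "P3"], "CFA")

  disjoint <- cross_model_venn(list(
    A = tibble::tibble(protein_id = "P1", mean_log2fc = 1),
    B = tibble::tibble(protein_id = "P2", mean_log2fc = 1)))
  expect_false(any(disjoint$region == "A&B"))

  identical_sets <- cross_model_venn(list(
    A = tibble::tibble(protein_id = c("P1", "P2"), mean_log2fc = 1),
    B = tibble::tibble(protein_id = c("P1", "P2"), mean_log2fc = 1)))
  expect_true(all(identical_sets$region == "A&B"))
})
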