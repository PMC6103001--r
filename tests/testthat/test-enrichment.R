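test_that("maximal brain abundance picks the top detected region", {
  brains <- brain_proteomes_from(list(
    ACC = list(P1 = c(99, 100, 101)),
    AMY = list(P1 = c(49, 50, 51), P2 = c(10, 10, 10))))
  top <- max_brain_abundance(brains, "P1")
  expect_equal(top$region, "ACC")
  expect_equal(top$mean_intensity, 100)
  expect_null(max_brain_abundance(brains, "P9"))

  # exact tie resolves by the fixed region order ACC < AMY < PFC < CER
  tied <- brain_proteomes_from(list(
    AMY = list(P1 = c(100, 100, 100)),
    ACC = list(P1 = c(100, 100, 100))))
  expect_equal(max_brain_abundance(tied, "P1")$region, "ACC")
})

test_that("one-tailed Welch test matches the textbook formulas", {
  w <- welch_one_tailed(c(8, 10, 12), c(1, 2, 3))
  expect_equal(w$t, 6.19677, tolerance = 1e-5)
  expect_equal(w$df, 50 / 17, tolerance = 1e-6) # Welch-Satterthwaite
  expect_lt(w$p, 0.05)
  o <- oracle_welch(c(8, 10, 12), c(1, 2, 3))
  expect_equal(w$t, o$t, tolerance = 1e-10)
  expect_equal(w$df, o$df, tolerance = 1e-10)
  expect_equal(w$p, o$p, tolerance = 1e-10)

  same <- welch_one_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)

  shifted <- welch_one_tailed(c(1, 2, 3) + 50, c(1, 2, 3))
  expect_lt(shifted$p, same$p)

  expect_equal(welch_one_tailed(c(1), c(1, 2))$reason, "insufficient_n")
  expect_equal(welch_one_tailed(c(1, 1), c(2, 2))$reason, "zero_variance")
})

test_that("classification applies strict >10-fold with Welch support", {
  brains <- brain_proteomes_from(list(ACC = list(
    P10 = c(99, 100, 101), P11 = c(99, 100, 101))))

  # fold exactly 10 fails the strict inequality
  target <- proteome_from("DRG", list(P10 = c(999, 1000, 1001)))
  dec <- classify_enriched(target, brains)
  expect_equal(dec$criterion, "rejected")
  expect_equal(dec$fold_enrichment, 10)

  # fold barely above 10 with a tiny Welch p passes criterion B
  target2 <- proteome_from("DRG", list(P11 = c(1000, 1001, 1002)))
  dec2 <- classify_enriched(target2, brains)
  expect_equal(dec2$criterion, "B_fold_enriched")
  expect_lt(dec2$welch_p, 0.05)

  # absent from every brain proteome: criterion A regardless of fold
  target3 <- proteome_from("SN", list(P99 = c(5, 6, 7)))
  dec3 <- classify_enriched(target3, brains)
  expect_equal(dec3$criterion, "A_absent_in_brain")
})

test_that("zero-variance replicate pairs fall back to the fold decision", {
  brains <- brain_proteomes_from(list(ACC = list(P1 = c(100, 100, 100))))
  target <- proteome_from("SN", list(P1 = c(2000, 2000, 2000)))
  expect_warning(dec <- classify_enriched(target, brains), "zero-variance")
  expect_equal(dec$criterion, "B_fold_enriched")
  expect_equal(dec$note, "zero_variance_fold_only")
})

test_that("classification is invariant to a global intensity rescaling", {
  withr::local_seed(14)
  m <- random_measurements(n_proteins = 12, n_peptides = 2,
                           tissues = c("SN", brain_tissues()),
                           p_present = 0.85)
  build_all <- function(meas) {
    target <- build_tissue_proteome(meas, "SN", "control")
    brains <- lapply(stats::setNames(nm = brain_tissues()), function(t) {
      build_tissue_proteome(meas, t, "control")
    })
    classify_enriched(target, brains)
  }
  dec1 <- build_all(m)
  m_scaled <- dplyr::mutate(m, intensity = intensity * 1000)
  dec2 <- build_all(m_scaled)
  expect_equal(dec1$criterion, dec2$criterion)
  expect_equal(dec1$fold_enrichment, dec2$fold_enrichment, tolerance = 1e-12)
  expect_equal(dec1$welch_p, dec2$welch_p, tolerance = 1e-12)
})

test_that("dropping a brain region never demotes an enriched protein", {
  withr::local_seed(77)
  for (i in 1:10) {
    m <- random_measurements(n_proteins = 10, n_peptides = 2,
                             tissues = c("DRG", brain_tissues()),
                             p_present = 0.7)
    target <- build_tissue_proteome(m, "DRG", "control")
    brains <- lapply(stats::setNames(nm = brain_tissues()), function(t) {
      build_tissue_proteome(m, t, "control")
    })
    full <- suppressWarnings(classify_enriched(target, brains))
    enriched_full <- enriched_proteins(full)
    for (drop_region in brain_tissues()) {
      fewer <- suppressWarnings(
        classify_enriched(target, brains[setdiff(brain_tissues(),
                                                 drop_region)]))
      expect_true(all(enriched_full %in% enriched_proteins(fewer)))
    }
  }
})

test_that("the secondary brain reference subtracts unconfirmed proteins", {
  brains <- brain_proteomes_from(list(ACC = list(P2 = c(99, 100, 101))))
  target <- proteome_from("SN", list(P1 = c(280, 300, 320),
                                     P2 = c(2000, 2100, 2200),
                                     P3 = c(480, 500, 520)))
  dec <- classify_enriched(target, brains)
  expect_equal(dec$criterion[dec$protein_id == "P1"], "A_absent_in_brain")

  secondary <- brain_proteomes_from(list(
    PFC = list(P1 = c(890, 900, 910),   # 3-fold below the target: removed
               P2 = c(99, 100, 101))))  # still >10-fold enriched: kept
  out <- apply_secondary_filter(dec, target, secondary)
  expect_equal(out$secondary_filter[out$protein_id == "P1"], "removed")
  expect_equal(out$secondary_filter[out$protein_id == "P2"], "passed")
  expect_equal(out$secondary_filter[out$protein_id == "P3"], "passed")
  expect_setequal(enriched_proteins(out), c("P2", "P3"))

  expect_warning(none <- apply_secondary_filter(dec, target, NULL),
                 "secondary")
  expect_true(all(none$secondary_filter == "not_applied"))
})

test_that("tissue preference separates SN- and DRG-specific proteins", {
  brains <- brain_proteomes_from(list(ACC = list(P3 = c(100, 100, 110))))
  prot_sn <- proteome_from("SN", list(P1 = c(10, 11, 12),
                                      P3 = c(2000, 2100, 2050)))
  prot_drg <- proteome_from("DRG", list(P2 = c(20, 21, 22),
                                        P3 = c(90, 100, 110)))
  dec_sn <- classify_enriched(prot_sn, brains)
  dec_drg <- classify_enriched(prot_drg, brains)
  pref <- partition_tissue_preference(dec_sn, dec_drg, prot_sn, prot_drg)
  # P1 enriched (A) in SN, absent from the DRG proteome
  expect_equal(pref$preference[pref$protein_id == "P1"], "SN_specific")
  # P2 enriched (A) in DRG, absent from the SN proteome
  expect_equal(pref$preference[pref$protein_id == "P2"], "DRG_specific")
  # P3 enriched in SN but detected (not enriched) in DRG: shared
  expect_equal(pref$preference[pref$protein_id == "P3"], "shared")
})
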