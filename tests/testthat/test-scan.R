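test_that("cofactor selection finds strong QTL markers, obeys the cap", {
  cross <- simulate_scenario(unlinked_qtl_scenario(n = 200), seed = 17)
  cof <- select_cofactors(cross)
  # the four simulated QTL markers (or immediate neighbours) dominate
  qtl_mk <- c("C1M3", "C2M6", "C3M4", "C4M4")
  neighb <- unlist(lapply(qtl_mk, function(m) {
    i <- as.integer(sub(".*M", "", m))
    ch <- sub("M.*", "", sub("C", "", m))
    paste0("C", ch, "M", pmax(1, i + (-1:1)))
  }))
  expect_gte(sum(cof$marker %in% neighb), 3)
  expect_lte(nrow(cof), 10)
  # pure noise selects nothing (BIC never improves)
  noise <- cross
  set.seed(5)
  noise$pheno <- rnorm(200)
  expect_equal(nrow(select_cofactors(noise)), 0)
  # explicit zero cap
  expect_equal(nrow(select_cofactors(cross, max_cofactors = 0)), 0)
})

test_that("IM, CIM with no cofactors, and BetaCIM at beta -> 0 coincide", {
  cross <- make_small_bc(n = 120, seed = 23)
  s_im <- genome_scan(cross, "im", step = 5)
  s_cim <- genome_scan(cross, "cim", cofactors = NULL, step = 5)
  s_b <- genome_scan(cross, "betacim", beta = 1e-8, cofactors = NULL,
                     step = 5)
  expect_equal(s_im$lod, s_cim$lod, tolerance = 1e-12)
  expect_lt(max(abs(s_im$lod - s_b$lod)), 1e-3)
  expect_equal(nrow(s_im),
               length(seq(0, 50, 5)) * 2)
})

test_that("the cofactor exclusion window is honoured", {
  cross <- simulate_scenario(unlinked_qtl_scenario(n = 200), seed = 29)
  cof <- select_cofactors(cross)
  expect_true("C1M3" %in% cof$marker)
  # structurally: nothing within the window survives the filter
  inc <- betaqtl:::included_cofactors(cof, "1", 20, window = 10)
  on_c1 <- cof[cof$chrom == "1", ]
  expect_false(any(abs(on_c1$pos[on_c1$marker %in% inc] - 20) <= 10))
  # functionally: a cofactor placed 10 cM from the tested position is
  # excluded at window = 10 but admitted at window = 9, where it absorbs
  # linked signal and deflates the LOD
  cof_nb <- tibble::tibble(step = 1L, marker = "C1M4", chrom = "1",
                           pos = 30, bic = NA_real_)
  class(cof_nb) <- class(cof)
  at <- tibble::tibble(chrom = "1", pos = 20)
  est_w10 <- effect_estimates(cross, at, method = "cim", cofactors = cof_nb,
                              window = 10)
  est_w9 <- effect_estimates(cross, at, method = "cim", cofactors = cof_nb,
                             window = 9)
  expect_gt(est_w10$lod, 5)
  expect_lt(est_w9$lod, est_w10$lod)
})

test_that("permutation thresholds: determinism, edge alpha, plausible range", {
  cross <- make_small_bc(n = 100, seed = 31)
  t1 <- permutation_threshold(cross, "im", n_perm = 30, seed = 99, step = 10)
  t2 <- permutation_threshold(cross, "im", n_perm = 30, seed = 99, step = 10)
  expect_equal(t1$threshold, t2$threshold)
  expect_equal(t1$maxima, t2$maxima)
  tall <- permutation_threshold(cross, "im", n_perm = 30, alpha = 1,
                                seed = 99, step = 10)
  expect_equal(tall$threshold, min(tall$maxima))
  # conventional order of magnitude for a small genome at alpha = 0.05
  expect_gt(t1$threshold, 0.5)
  expect_lt(t1$threshold, 6)
})

test_that("false-positive rate at the permutation threshold is calibrated", {
  mp <- sim_map(1, 6, 10)
  null_max <- vapply(1:200, function(s) {
    cr <- sim_cross(mp, 60, "bc", seed = 4000 + s)
    cr$pheno <- rnorm(60)
    max(genome_scan(cr, "im", step = 10)$lod)
  }, numeric(1))
  cr1 <- sim_cross(mp, 60, "bc", seed = 4001)
  cr1$pheno <- rnorm(60)
  thr <- permutation_threshold(cr1, "im", n_perm = 200, seed = 77, step = 10)
  fpr <- mean(null_max > thr$threshold)
  expect_gt(fpr, 0.05 - 1.96 * sqrt(0.05 * 0.95 / 200) - 0.02)
  expect_lt(fpr, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 200) + 0.02)
})

test_that("peak calling keeps separated local maxima and annotates markers", {
  cross <- simulate_scenario(unlinked_qtl_scenario(n = 250), seed = 37)
  sc <- genome_scan(cross, "im", step = 10)
  pk <- call_peaks(sc, threshold = 3)
  expect_true(all(pk$lod > 3))
  # at most one peak per chromosome arm here; QTL chromosomes show up
  expect_true(all(table(pk$chrom) <= 2))
  expect_true("C1M3" %in% pk$marker)
  # peaks at grid resolution carry their nearest marker position
  expect_true(all(abs(pk$pos - pk$marker_pos) <= 5))
  # threshold object is accepted too
  thr <- list(threshold = 3)
  class(thr) <- "qtl_threshold"
  expect_equal(call_peaks(sc, thr), pk)
})

test_that("betacim with auto beta runs end to end on contaminated data", {
  cross <- simulate_scenario(unlinked_qtl_scenario(n = 150), seed = 41,
                             contamination = 0.05)
  cof <- select_cofactors(cross)
  sc <- genome_scan(cross, "betacim", beta = "auto", cofactors = cof,
                    step = 10)
  expect_gt(attr(sc, "beta"), 0)
  expect_true(all(is.finite(sc$lod)))
  # the QTL marker stands out
  expect_gt(sc$lod[sc$chrom == "1" & sc$pos == 20], 3)
})
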