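test_that("panels are deterministic given the seed", {
  s <- panel_spec(n_samples = 30, n_loci = 100, K = 2, F = 0.2)
  p1 <- generate_panel(s, seed = 99)
  p2 <- generate_panel(s, seed = 99)
  expect_identical(p1$genotypes$dose, p2$genotypes$dose)
  expect_identical(p1$map, p2$map)
  expect_identical(p1$truth$Q, p2$truth$Q)
  p3 <- generate_panel(s, seed = 100)
  expect_false(identical(p3$genotypes$dose, p1$genotypes$dose))

  l1 <- generate_linked_panel(panel_spec(n_samples = 20, n_loci = 60, K = 1,
                                         chromosomes = "1A"), seed = 5)
  l2 <- generate_linked_panel(panel_spec(n_samples = 20, n_loci = 60, K = 1,
                                         chromosomes = "1A"), seed = 5)
  expect_identical(l1$genotypes$dose, l2$genotypes$dose)
})

test_that("truth objects satisfy their invariants", {
  p <- generate_panel(panel_spec(n_samples = 50, n_loci = 300, K = 3,
                                 F = 0.2, alpha = 0.1), seed = 4)
  expect_equal(unname(rowSums(p$truth$Q)), rep(1, 50), tolerance = 1e-12)
  expect_true(all(p$truth$P >= 0 & p$truth$P <= 1))
  expect_true(all(p$genotypes$dose %in% c(0L, 1L, 2L, NA)))
  expect_equal(nrow(p$map), 300)
})

test_that("vanishing divergence yields a vanishing realized G_ST", {
  p <- generate_panel(panel_spec(n_samples = 100, n_loci = 2000, K = 3,
                                 F = 1e-6, alpha = 5, missing_rate = 0),
                      seed = 17)
  expect_lt(p$truth$realized_G_ST, 0.01)
})

test_that("strong divergence with small alpha gives assignable samples", {
  p <- generate_panel(panel_spec(n_samples = 200, n_loci = 500, K = 2,
                                 F = 0.3, alpha = 0.05), seed = 18)
  qb <- apply(p$truth$Q, 1, max)
  expect_gte(mean(qb > 0.7), 0.9)
})

test_that("the realized MAF spectrum has a sub-5% tail", {
  removed <- vapply(1:5, function(seed) {
    p <- generate_panel(panel_spec(n_samples = 150, n_loci = 1000, K = 3),
                        seed = seed)
    fr <- filter_markers(p$genotypes)
    fr$n_removed_maf + fr$n_removed_missing
  }, numeric(1))
  expect_true(all(removed > 0))
})

test_that("realized differentiation approaches the F-model expectation", {
  K <- 3; F <- 0.15
  p <- generate_panel(panel_spec(n_samples = 50, n_loci = 5000, K = K,
                                 F = F), seed = 77)
  # E[H_S] = (1-F) E[2 p0 q0]; E[H_T] = (1 - F/K) E[2 p0 q0]
  expected <- 1 - (1 - F) / (1 - F / K)
  expect_lt(abs(p$truth$realized_G_ST - expected), 0.02)
})

test_that("selfing controls panel homozygosity", {
  p_in <- generate_panel(panel_spec(n_samples = 100, n_loci = 500, K = 1,
                                    selfing_rate = 0.98, missing_rate = 0),
                         seed = 8)
  p_out <- generate_panel(panel_spec(n_samples = 100, n_loci = 500, K = 1,
                                     selfing_rate = 0, missing_rate = 0),
                          seed = 8)
  het_in <- mean(p_in$genotypes$dose == 1L)
  het_out <- mean(p_out$genotypes$dose == 1L)
  expect_lt(het_in, 0.02)
  expect_gt(het_out, 0.2)
})

test_that("linked panels decay in LD with distance, unlinked do not", {
  spec0 <- panel_spec(n_samples = 120, n_loci = 120, K = 1,
                      chromosomes = c("1A", "1B"), chrom_length_cM = 60,
                      n_founders = 6, missing_rate = 0, selfing_rate = 1)
  # near-zero recombination: no decay across the chromosome
  spec_c0 <- spec0; spec_c0$recomb_rate <- 1e-6
  lp <- generate_linked_panel(spec_c0, seed = 41)
  st <- locus_stats(lp$genotypes)
  gm <- lp$genotypes[, !is.na(st$maf) & st$maf >= 0.1]
  lt <- ld_scan(gm, lp$map, window_cM = 60, test = FALSE)
  near <- lt$r2[lt$dist_cM < 15]
  far <- lt$r2[lt$dist_cM > 40]
  expect_lt(abs(mean(near) - mean(far)), 0.1)
  expect_gt(mean(far), 0.05)  # founder-pool LD persists

  # strong recombination: adjacent-marker LD collapses to the unlinked level
  spec_hi <- spec0; spec_hi$recomb_rate <- 5
  lh <- generate_linked_panel(spec_hi, seed = 41)
  sth <- locus_stats(lh$genotypes)
  gmh <- lh$genotypes[, !is.na(sth$maf) & sth$maf >= 0.1]
  lth <- ld_scan(gmh, lh$map, window_cM = 60, test = FALSE)
  expect_lt(mean(lth$r2), 1 / 120 + 3 * stats::sd(lth$r2) / sqrt(nrow(lth)) + 0.02)

  # monotone decay: mean r2 non-increasing across distance bins (Spearman)
  spec_mid <- spec0; spec_mid$recomb_rate <- 0.15
  reps <- vapply(1:6, function(seed) {
    lm_ <- generate_linked_panel(spec_mid, seed = seed)
    stm <- locus_stats(lm_$genotypes)
    gmm <- lm_$genotypes[, !is.na(stm$maf) & stm$maf >= 0.1]
    ltm <- ld_scan(gmm, lm_$map, window_cM = 60, test = FALSE)
    bins <- cut(ltm$dist_cM, breaks = seq(0, 60, 6), include.lowest = TRUE)
    mr <- tapply(ltm$r2, bins, mean)
    mr <- mr[!is.na(mr)]
    stats::cor(seq_along(mr), mr, method = "spearman")
  }, numeric(1))
  expect_true(mean(reps < 0) >= 0.95 || all(reps < 0))
})
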