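test_that("EM haplotype frequencies reduce to direct counts without double hets", {
  # perfectly co-varying homozygous panel
  a <- c(0L, 0L, 2L, 2L, 0L, 2L)
  hf <- haplotype_freqs_em(a, a)
  expect_equal(unname(hf$freq),
               matrix(c(0.5, 0, 0, 0.5), 2, 2), tolerance = 1e-12)
  expect_equal(hf$iterations, 0L)

  # single hets but no double het: still direct counting
  a2 <- c(0L, 1L, 2L, 0L, 2L)
  b2 <- c(0L, 0L, 2L, 2L, 2L)
  hf2 <- haplotype_freqs_em(a2, b2)
  # gamete hand count: (0,0)->2x h00; (1,0)->h00+h10; (2,2)->2x h11;
  # (0,2)->2x h01; (2,2)->2x h11  =>  h00=3 h01=2 h10=1 h11=4 of 10
  expected <- matrix(c(3, 1, 2, 4), 2, 2) / 10
  expect_equal(unname(hf2$freq), expected, tolerance = 1e-12)
})

test_that("EM resolves double heterozygotes toward the MLE", {
  # only double heterozygotes: coupling and repulsion are equally likely,
  # EM stays at the symmetric D = 0 solution
  a <- rep(1L, 8); b <- rep(1L, 8)
  hf <- haplotype_freqs_em(a, b)
  expect_equal(unname(hf$freq), matrix(0.25, 2, 2), tolerance = 1e-9)
  expect_equal(ld_r2(hf)$D, 0, tolerance = 1e-9)

  # strong coupling signal plus double hets: EM pushes D positive
  a2 <- c(rep(0L, 10), rep(2L, 10), rep(1L, 4))
  b2 <- c(rep(0L, 10), rep(2L, 10), rep(1L, 4))
  hf2 <- haplotype_freqs_em(a2, b2)
  expect_gt(ld_r2(hf2)$D, 0.2)
})

test_that("r2 follows the haplotype-frequency closed form", {
  cc <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  expect_equal(ld_r2(cc)$r2, 1)
  ind <- outer(c(0.6, 0.4), c(0.3, 0.7))
  expect_equal(ld_r2(ind)$D, 0, tolerance = 1e-12)
  expect_equal(ld_r2(ind)$r2, 0, tolerance = 1e-12)
  hf <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)
  expect_equal(ld_r2(hf)$D, 0.15)
  expect_equal(ld_r2(hf)$r2, 0.15^2 / 0.0625)
  mono <- matrix(c(0.6, 0.4, 0, 0), 2, 2)
  expect_true(is.na(ld_r2(mono)$r2))
})

test_that("r2 equals brute-force squared correlation when phase is known", {
  for (seed in 1:10) {
    gm <- random_gm(40, 2, selfing = 1, seed = seed + 100)
    a <- gm$dose[, 1]; b <- gm$dose[, 2]
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    hf <- haplotype_freqs_em(a, b)
    expect_equal(ld_r2(hf)$r2, r2_bruteforce_hom(a, b), tolerance = 1e-9)
  }
})

test_that("significance agrees with exact and asymptotic oracles", {
  perfect <- matrix(c(10, 0, 0, 10), 2, 2)
  p <- ld_significance(perfect, method = "fisher")
  expect_lt(p, 1e-4)
  expect_equal(p, fisher_2x2_enum(perfect), tolerance = 1e-12)
  expect_equal(p, stats::fisher.test(perfect)$p.value, tolerance = 1e-12)

  flat <- matrix(c(5, 5, 5, 5), 2, 2)
  expect_equal(ld_significance(flat, method = "fisher"), 1)
  expect_equal(ld_significance(flat, method = "auto"), 1)  # chisq branch

  # chi-square approximation within an order of magnitude at n = 200
  set.seed(1)
  for (i in 1:5) {
    tab <- matrix(stats::rmultinom(1, 200, c(0.3, 0.2, 0.2, 0.3)), 2, 2)
    pf <- ld_significance(tab, method = "fisher")
    pc <- ld_significance(tab, method = "chisq")
    expect_lt(abs(log10(pf) - log10(pc)), 1)
  }

  # fractional EM counts are resolved by largest-remainder rounding
  frac <- matrix(c(10.6, 2.4, 3.4, 9.6), 2, 2)
  expect_equal(ld_significance(frac, method = "fisher"),
               stats::fisher.test(matrix(c(11, 2, 3, 10), 2, 2))$p.value)
})

test_that("the scan honours the window and flags perfect duplicates", {
  gm <- random_gm(30, 3, selfing = 1, seed = 11)
  gm$dose[, 3] <- gm$dose[, 1]  # duplicated marker column
  map <- genetic_map(locus_ids(gm), rep("5A", 3), c(0, 60, 0.5))
  lt <- ld_scan(gm, map, window_cM = 50)
  pairs <- paste(lt$locus_a, lt$locus_b)
  expect_false(any(lt$dist_cM > 50))
  # the 0 vs 60 cM pair is not evaluated
  expect_equal(nrow(lt), 1)
  expect_equal(lt$r2, 1, tolerance = 1e-12)
  expect_lt(lt$p_value, 1e-6)
})

test_that("unlinked unstructured panels give mean r2 near 1/n", {
  r2m <- vapply(1:6, function(seed) {
    gm <- random_gm(60, 40, selfing = 1, seed = seed)
    st <- locus_stats(gm)
    gm <- gm[, st$maf >= 0.1]
    map <- map_for(gm, spacing = 1)
    lt <- ld_scan(gm, map, window_cM = 50, test = FALSE)
    mean(lt$r2)
  }, numeric(1))
  expect_lt(abs(mean(r2m) - 1 / 60), 3 * stats::sd(r2m) / sqrt(6) + 0.004)
})

test_that("critical r2 pools pairs within each genome", {
  lt <- data.frame(locus_a = "x", locus_b = "y",
                   chromosome = c(rep("1A", 10), rep("2A", 30), rep("1B", 5)),
                   genome = c(rep("A", 40), rep("B", 5)),
                   dist_cM = 1, r2 = c(rep(0.1, 10), rep(0.3, 30), rep(0, 5)),
                   p_value = 0.5)
  class(lt) <- c("ld_table", "data.frame")
  crit <- critical_r2_per_genome(lt)
  expect_equal(unname(crit["A"]), 0.25)  # weighted pooling over pairs
  expect_equal(unname(crit["B"]), 0)
})

test_that("LOESS decay inverts a known exponential decay", {
  set.seed(3)
  d <- runif(400, 0, 6)
  lt <- data.frame(locus_a = "x", locus_b = "y", chromosome = "1A",
                   genome = "A", dist_cM = d, r2 = exp(-d), p_value = NA)
  class(lt) <- c("ld_table", "data.frame")
  fit <- fit_ld_decay(lt, "1A", critical_r2 = exp(-1))
  expect_false(fit$censored)
  expect_equal(fit$decay_cM, 1)

  # flat r2 below the critical value: decay 0
  lt$r2 <- 0.05
  fit0 <- fit_ld_decay(lt, "1A", critical_r2 = 0.2)
  expect_equal(fit0$decay_cM, 0)

  # never crossing: censored at the maximum observed distance
  lt$r2 <- 0.9
  fitc <- fit_ld_decay(lt, "1A", critical_r2 = 0.2)
  expect_true(fitc$censored)

  # too few pairs: undefined with a warning
  expect_warning(fit_ld_decay(lt[1:5, ], "1A", 0.2), "decay undefined")
})

test_that("a monotone decay curve crosses the critical value once", {
  set.seed(8)
  d <- sort(runif(300, 0, 10))
  r2 <- 0.8 / (1 + d) + rnorm(300, 0, 0.01)
  lt <- data.frame(locus_a = "x", locus_b = "y", chromosome = "2B",
                   genome = "B", dist_cM = d, r2 = pmax(r2, 0), p_value = NA)
  class(lt) <- c("ld_table", "data.frame")
  crit <- 0.3
  fit <- fit_ld_decay(lt, "2B", crit)
  # bisection oracle on the fitted curve around the reported crossing
  expect_gt(fit$curve(max(0, fit$decay_cM - 1)), crit * 0.9)
  expect_lt(fit$curve(fit$decay_cM + 1), crit * 1.1)
  # closed-form inversion of the underlying curve: 0.8/(1+d) = 0.3 -> d = 5/3
  expect_lt(abs(fit$decay_cM - 5 / 3), 1.5)
})
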