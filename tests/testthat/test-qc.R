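test_that("locus stats match hand counts", {
  # calls {AA x6, AB x2, BB x2}: p = (2*2 + 2)/20 ... B-allele freq 0.3
  dose <- cbind(c(rep(0L, 6), rep(1L, 2), rep(2L, 2)),
                rep(0L, 10),
                c(rep(NA_integer_, 4), rep(c(0L, 2L), 3)))
  gm <- gm_from_dose(dose)
  st <- locus_stats(gm)
  expect_equal(st$maf[1], 0.3)
  expect_equal(st$maf[2], 0)
  expect_equal(st$missing_rate, c(0, 0, 0.4))
})

test_that("an all-missing locus has undefined MAF, never 0", {
  dose <- cbind(rep(NA_integer_, 4), c(0L, 1L, 2L, 0L))
  st <- locus_stats(gm_from_dose(dose))
  expect_true(is.na(st$maf[1]))
})

test_that("filter thresholds use strict 'more than' / 'lower than'", {
  # 10 samples; locus 1 maf exactly 0.05 (retained under strict '<'),
  # locus 2 missing 0.3 (removed), loci 3-4 clean
  dose <- cbind(c(1L, rep(0L, 9)),
                c(rep(NA_integer_, 3), rep(0L, 5), 1L, 2L),
                c(rep(0L, 8), 1L, 1L),
                c(rep(0L, 5), rep(2L, 5)))
  gm <- gm_from_dose(dose)
  fr <- filter_markers(gm, max_missing = 0.25, min_maf = 0.05)
  expect_equal(fr$n_removed_missing, 1)
  expect_equal(fr$n_removed_maf, 0)
  expect_equal(fr$n_retained, 3)

  fr2 <- filter_markers(gm, max_missing = 0.25, min_maf = 0.06)
  expect_equal(fr2$n_removed_maf, 1)  # the maf-0.05 locus now fails

  # a locus failing both thresholds is counted once, under missingness
  dose3 <- cbind(c(rep(NA_integer_, 4), 1L, rep(0L, 5)),
                 c(rep(0L, 5), rep(2L, 5)))
  fr3 <- filter_markers(gm_from_dose(dose3))
  expect_equal(fr3$n_removed_missing, 1)
  expect_equal(fr3$n_removed_maf, 0)
})

test_that("filter counting identity and idempotence hold on random panels", {
  for (seed in 1:5) {
    gm <- random_gm(30, 80, selfing = 0.9, missing_rate = 0.15, seed = seed)
    for (th in list(c(0.25, 0.05), c(0.10, 0.10), c(0.5, 0.01))) {
      fr <- filter_markers(gm, th[1], th[2])
      expect_equal(fr$n_input,
                   fr$n_removed_missing + fr$n_removed_maf + fr$n_retained)
      fr2 <- filter_markers(fr$genotypes, th[1], th[2])
      expect_equal(fr2$n_removed_missing + fr2$n_removed_maf, 0)
      expect_equal(fr2$n_retained, fr$n_retained)
    }
  }
})

test_that("polymorphism partition follows the within-group definition", {
  # locus 1: polymorphic in both; locus 2: only group 1; locus 3: only
  # group 2; locus 4: fixed A in group 1, fixed B in group 2 -> in neither
  g1 <- rbind(c(0L, 0L, 0L, 0L),
              c(2L, 2L, 0L, 0L),
              c(0L, 0L, 0L, 0L))
  g2 <- rbind(c(0L, 2L, 0L, 2L),
              c(2L, 2L, 2L, 2L),
              c(0L, 2L, 0L, 2L))
  gm <- gm_from_dose(rbind(g1, g2), era = rep(c("a", "b"), each = 3))
  pp <- partition_polymorphism(gm)
  expect_equal(pp$n_total_union, 3)
  expect_equal(pp$n_common, 1)
  expect_equal(pp$n_only_group1, 1)
  expect_equal(pp$n_only_group2, 1)
})

test_that("partition identities match a brute-force per-locus scan", {
  set.seed(42)
  gm <- random_gm(24, 50, selfing = 0.7, missing_rate = 0.1, seed = 42)
  groups <- rep(c("x", "y"), each = 12)
  pp <- partition_polymorphism(gm, groups)
  brute <- sapply(seq_len(50), function(j) {
    alleles_in <- function(rows) {
      d <- gm$dose[rows, j]
      d <- d[!is.na(d)]
      u <- unique(unlist(lapply(d, function(x) {
        switch(as.character(x), "0" = c(0, 0), "1" = c(0, 1), "2" = c(1, 1))
      })))
      length(u) >= 2
    }
    c(alleles_in(1:12), alleles_in(13:24))
  })
  expect_equal(pp$n_common, sum(brute[1, ] & brute[2, ]))
  expect_equal(pp$n_total_union, sum(brute[1, ] | brute[2, ]))
  expect_equal(pp$n_total_union,
               pp$n_common + pp$n_only_group1 + pp$n_only_group2)
})

test_that("decay thinning keeps the greedy left-to-right spacing", {
  gm <- random_gm(5, 5, seed = 3)
  map <- genetic_map(locus_ids(gm), rep("3B", 5), 0:4)
  expect_identical(thin_by_decay(gm, map, 2),
                   locus_ids(gm)[c(1, 3, 5)])
  expect_identical(thin_by_decay(gm, map, 0), locus_ids(gm))

  # property: retained neighbours are >= decay apart, on random maps
  for (seed in 1:5) {
    set.seed(seed)
    gm2 <- random_gm(5, 60, seed = seed)
    map2 <- genetic_map(locus_ids(gm2),
                        sample(c("1A", "2B"), 60, TRUE),
                        round(runif(60, 0, 100), 2))
    kept <- thin_by_decay(gm2, map2, 7)
    km <- map2[map2$locus_id %in% kept, ]
    for (ch in unique(km$chromosome)) {
      pos <- sort(km$cM[km$chromosome == ch])
      if (length(pos) > 1) expect_true(all(diff(pos) >= 7))
    }
  }
})

test_that("unmapped markers are excluded from thinning with a message", {
  gm <- random_gm(5, 4, seed = 1)
  map <- genetic_map(locus_ids(gm)[1:3], rep("1A", 3), c(0, 5, 10))
  expect_message(kept <- thin_by_decay(gm, map, 4), "without map position")
  # positions 0, 5, 10 with spacing 4: all three retained
  expect_identical(kept, locus_ids(gm)[1:3])
})
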