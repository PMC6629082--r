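test_that("simple matching distance counts genotype-state mismatches", {
  dose <- rbind(s1 = c(0L, 1L, 2L, 0L),
                s2 = c(0L, 1L, 2L, 0L),
                s3 = c(2L, 0L, 1L, 2L))
  gm <- genotype_matrix(dose)
  D <- suppressWarnings(simple_matching_distance(gm))
  expect_equal(D["s1", "s2"], 0)
  expect_equal(D["s1", "s3"], 1)  # differs at every locus
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D, t(D))

  # 10 loci, 4 mismatches among 8 comparable (2 missing in one sample)
  a <- c(rep(0L, 6), rep(2L, 4))
  b <- c(rep(0L, 4), 2L, 2L, rep(0L, 2), NA_integer_, NA_integer_)
  gm2 <- genotype_matrix(rbind(a = a, b = b))
  D2 <- suppressWarnings(simple_matching_distance(gm2))
  expect_equal(D2["a", "b"], 0.5)
})

test_that("pairs without comparable loci are an error, sparse ones a warning", {
  dose <- rbind(c(0L, NA_integer_), c(NA_integer_, 2L), c(0L, 2L))
  expect_error(simple_matching_distance(genotype_matrix(dose)),
               "no comparable locus")
  gm <- random_gm(4, 5, seed = 1)
  expect_warning(simple_matching_distance(gm, min_loci = 10), "fewer than")
})

test_that("neighbour joining recovers additive trees exactly", {
  D <- additive_4taxon(a = 1, b = 2, c = 1.5, d = 2.5, e = 1)
  tree <- neighbor_joining(D)
  expect_equal(nrow(tree$edge), 5)  # 2n - 3 edges
  # the true split AB|CD is recovered: exhaustive check over the 3
  # possible quartet topologies via the induced path-length matrix
  pd <- stats::cophenetic(tree)[rownames(D), colnames(D)]
  expect_lt(max(abs(pd - D)), 1e-9)
  expect_true(all(tree$edge.length >= 0))

  # ultrametric 3-taxon star resolves with the correct lengths
  D3 <- matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(D3)
  expect_equal(nrow(t3$edge), 3)
  expect_equal(sort(t3$edge.length), rep(1, 3))
})

test_that("neighbour joining matches the reference implementation", {
  set.seed(14)
  for (rep in 1:5) {
    tr0 <- ape::rtree(8, br = function(n) runif(n, 0.2, 1))
    tr0 <- ape::unroot(tr0)
    D <- stats::cophenetic(tr0)
    ours <- neighbor_joining(D)
    ref <- ape::nj(D)
    expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
    pd <- stats::cophenetic(ours)[rownames(D), colnames(D)]
    expect_lt(max(abs(pd - D)), 1e-9)
  }
})

test_that("neighbour joining is invariant to input permutation", {
  set.seed(15)
  gm <- random_gm(12, 60, selfing = 1, seed = 15)
  D <- simple_matching_distance(gm)
  t1 <- neighbor_joining(D)
  perm <- sample(nrow(D))
  t2 <- neighbor_joining(D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})

test_that("negative NJ branch lengths are clamped with deficit transfer", {
  # a non-additive matrix known to produce a negative branch estimate
  D <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 0.2,
                9, 10, 0.2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tree <- neighbor_joining(D)
  expect_true(all(tree$edge.length >= 0))
})

test_that("PCoA reconstructs Euclidean configurations", {
  set.seed(16)
  pts <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(stats::dist(pts))
  rownames(D) <- colnames(D) <- paste0("p", 1:5)
  pc <- pcoa(D, n_axes = 2)
  expect_lt(max(abs(as.matrix(stats::dist(pc$coordinates)) - D)), 1e-9)
  expect_equal(unname(colMeans(pc$coordinates)), c(0, 0), tolerance = 1e-9)
  expect_true(all(diff(pc$eigenvalues) <= 1e-9))

  # all-equal distances: the regular simplex, all positive eigenvalues equal
  De <- matrix(1, 4, 4); diag(De) <- 0
  pce <- pcoa(De, n_axes = 3)
  pos <- pce$eigenvalues[pce$eigenvalues > 1e-9]
  expect_equal(max(pos) / min(pos), 1, tolerance = 1e-9)

  # requesting more axes than positive eigenvalues truncates with a warning
  expect_warning(pc1 <- pcoa(De, n_axes = 4), "positive eigenvalue")
  expect_lte(ncol(pc1$coordinates), 3)

  # distances between samples are invariant to axis sign flips
  flipped <- pc$coordinates %*% diag(c(-1, 1))
  expect_equal(as.matrix(stats::dist(flipped)),
               as.matrix(stats::dist(pc$coordinates)), tolerance = 1e-12)
})

test_that("PCoA separates diverged populations on the first axis", {
  panel <- generate_panel(
    panel_spec(n_samples = 80, n_loci = 400, K = 2, F = 0.3, alpha = 0.05,
               missing_rate = 0.02),
    seed = 30)
  lab <- panel$truth$labels
  D <- simple_matching_distance(panel$genotypes)
  pc <- pcoa(D, 2)
  x <- pc$coordinates[, 1]
  ok <- !is.na(lab)
  # axis-1 silhouette of the true grouping
  sil <- vapply(which(ok), function(i) {
    same <- setdiff(which(ok & lab == lab[i]), i)
    other <- which(ok & lab != lab[i])
    own <- mean(abs(x[i] - x[same]))
    oth <- mean(abs(x[i] - x[other]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil, na.rm = TRUE), 0.5)
})
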