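# Independent oracles and small fixture builders used across the suite.

# two-sided Fisher exact p for a 2x2 table by direct hypergeometric
# enumeration (sum of all tables with probability <= observed, standard
# two-sided rule)
fisher_2x2_enum <- function(tab) {
  tab <- as.matrix(tab)
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p0 <- stats::dhyper(x, m, n2, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# r^2 as the squared Pearson correlation of phase-known haplotype
# indicator variables (valid when every sample is homozygous at both loci)
r2_bruteforce_hom <- function(dose_a, dose_b) {
  ok <- !is.na(dose_a) & !is.na(dose_b) & dose_a != 1 & dose_b != 1
  stats::cor(dose_a[ok] / 2, dose_b[ok] / 2)^2
}

# genotype matrix from an explicit dose matrix
gm_from_dose <- function(dose, era = NULL) {
  genotype_matrix(dose, era = era)
}

# random fully-genotyped panel of unlinked loci, optionally inbred
random_gm <- function(n = 20, L = 50, p = NULL, selfing = 1,
                      missing_rate = 0, seed = 1) {
  set.seed(seed)
  if (is.null(p)) p <- stats::runif(L, 0.1, 0.9)
  c1 <- matrix(stats::runif(n * L) < rep(p, each = n), n, L)
  dup <- matrix(stats::runif(n * L) < selfing, n, L)
  c2 <- ifelse(dup, c1, matrix(stats::runif(n * L) < rep(p, each = n), n, L))
  dose <- matrix(as.integer(c1) + as.integer(c2), n, L)
  if (missing_rate > 0)
    dose[matrix(stats::runif(n * L) < missing_rate, n, L)] <- NA_integer_
  genotype_matrix(dose)
}

# simple single-chromosome map for a genotype matrix
map_for <- function(gm, chromosome = "1A", spacing = 1) {
  L <- length(locus_ids(gm))
  genetic_map(locus_ids(gm), rep(chromosome, L), (seq_len(L) - 1) * spacing)
}

# distance matrix of an additive (tree-realisable) 4-taxon metric with
# split AB|CD: external a,b,c,d and internal e
additive_4taxon <- function(a = 1, b = 2, c = 1.5, d = 2.5, e = 1) {
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- a + b
  D["A", "C"] <- a + e + c
  D["A", "D"] <- a + e + d
  D["B", "C"] <- b + e + c
  D["B", "D"] <- b + e + d
  D["C", "D"] <- c + d
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}
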