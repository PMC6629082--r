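#' Specification of a synthetic SNP panel
#'
#' Describes a structured inbred SNP panel in the style of a Mediterranean
#' bread-wheat diversity collection: `K` latent subpopulations diverged
#' under the Balding-Nichols F-model, Dirichlet admixture, high
#' homozygosity from selfing, a minor-allele-frequency spectrum with a
#' sub-5% tail, moderate missingness, and markers mapped to 21 chromosomes
#' in 3 genomes.  Defaults mirror the panel the package's analyses are
#' tuned to: 354 inbred lines, 11196 mapped SNPs, 6 subpopulations.
#'
#' @param n_samples number of lines (default 354).
#' @param n_loci number of mapped biallelic SNPs (default 11196).
#' @param K number of latent subpopulations (default 6).
#' @param F divergence parameter per subpopulation (recycled to length K;
#'   default 0.15).
#' @param alpha Dirichlet admixture concentration (default 0.2; small
#'   values give mostly-pure lines as observed in germplasm panels).
#' @param selfing_rate probability that a line's second allele copy
#'   duplicates the first (default 0.98, inbred lines).
#' @param missing_rate i.i.d. per-call missingness (default 0.03, must be
#'   `<= 0.25`).
#' @param chromosomes chromosome names (default the 21 wheat chromosomes).
#' @param chrom_length_cM genetic length per chromosome (default 160).
#' @param n_founders founder haplotypes per subpopulation for the linked
#'   generator (default 8).
#' @param recomb_rate recombination intensity per cM for the linked
#'   generator (default 0.05).
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(n_samples = 354, n_loci = 11196, K = 6, F = 0.15,
                       alpha = 0.2, selfing_rate = 0.98, missing_rate = 0.03,
                       chromosomes = wheat_chromosomes(),
                       chrom_length_cM = 160, n_founders = 8,
                       recomb_rate = 0.05) {
  F <- rep_len(F, K)
  stopifnot(n_samples >= 2, n_loci >= 1, K >= 1,
            all(F >= 0), all(F < 1),
            alpha > 0, selfing_rate >= 0, selfing_rate <= 1,
            missing_rate >= 0, missing_rate <= 0.25,
            chrom_length_cM > 0, n_founders >= 2, recomb_rate >= 0)
  structure(list(n_samples = n_samples, n_loci = n_loci, K = K, F = F,
                 alpha = alpha, selfing_rate = selfing_rate,
                 missing_rate = missing_rate, chromosomes = chromosomes,
                 chrom_length_cM = rep_len(chrom_length_cM,
                                           length(chromosomes)),
                 n_founders = n_founders, recomb_rate = recomb_rate),
            class = "panel_spec")
}

rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  g[g < 1e-300] <- 1e-300
  g / rowSums(g)
}

# ancestral + subpopulation allele frequencies under the F-model
draw_frequencies <- function(spec) {
  p0 <- stats::runif(spec$n_loci, 0.05, 0.95)
  P <- matrix(NA_real_, spec$n_loci, spec$K)
  for (k in seq_len(spec$K)) {
    Fk <- spec$F[k]
    if (Fk == 0) {
      P[, k] <- p0
    } else {
      P[, k] <- stats::rbeta(spec$n_loci,
                             p0 * (1 - Fk) / Fk,
                             (1 - p0) * (1 - Fk) / Fk)
    }
  }
  list(p0 = p0, P = P)
}

random_map <- function(spec) {
  chrom <- sample(spec$chromosomes, spec$n_loci, replace = TRUE)
  len <- stats::setNames(spec$chrom_length_cM, spec$chromosomes)
  pos <- stats::runif(spec$n_loci, 0, len[chrom])
  genetic_map(sprintf("mk%05d", seq_len(spec$n_loci)), chrom, pos,
              chromosomes = spec$chromosomes)
}

panel_truth <- function(Q, P, sample_ids = NULL, locus_ids = NULL) {
  if (!is.null(sample_ids)) rownames(Q) <- sample_ids
  if (!is.null(locus_ids)) rownames(P) <- locus_ids
  pbar <- rowMeans(P)
  ht <- 2 * pbar * (1 - pbar)
  hs <- rowMeans(2 * P * (1 - P))
  fst <- ifelse(ht > 0, (ht - hs) / ht, NA_real_)
  lab <- max.col(Q, ties.method = "first")
  qb <- Q[cbind(seq_len(nrow(Q)), lab)]
  list(Q = Q, P = P,
       realized_fst = fst,
       realized_G_ST = (mean(ht) - mean(hs)) / mean(ht),
       labels = ifelse(qb > 0.5, lab, NA_integer_))
}

#' Generate a structured unlinked SNP panel
#'
#' Draws a panel under the Balding-Nichols F-model: ancestral frequencies
#' `p0 ~ U(0.05, 0.95)`; subpopulation frequencies
#' `p_k ~ Beta(p0 (1-F)/F, (1-p0)(1-F)/F)`; admixture rows
#' `Q_i ~ Dirichlet(alpha)`; each line's first allele copy is drawn from
#' the mixture `sum_k q_ik p_k` and the second duplicates it with
#' probability `selfing_rate` (otherwise drawn independently); calls are
#' masked missing i.i.d.  Loci are unlinked: marker positions on the map
#' carry no LD.  Deterministic given the seed.
#'
#' @param spec a [panel_spec()].
#' @param seed integer seed (default 1).
#' @return List with `genotypes` (a [genotype_matrix()]), `map` (a
#'   `genetic_map`) and `truth` (true `Q`, subpopulation frequencies `P`
#'   (loci x K), `realized_fst` per locus, `realized_G_ST`, and `labels`,
#'   the q>0.5 assignment with `NA` for admixed lines).
#' @export
generate_panel <- function(spec = panel_spec(), seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  fr <- draw_frequencies(spec)
  Q <- rdirichlet(spec$n_samples, rep(spec$alpha, spec$K))
  m <- Q %*% t(fr$P)  # n x L mixture allele frequency
  n <- spec$n_samples; L <- spec$n_loci
  c1 <- matrix(stats::runif(n * L) < m, n, L)
  dup <- matrix(stats::runif(n * L) < spec$selfing_rate, n, L)
  c2i <- matrix(stats::runif(n * L) < m, n, L)
  c2 <- ifelse(dup, c1, c2i)
  dose <- matrix(as.integer(c1) + as.integer(c2), n, L)
  if (spec$missing_rate > 0)
    dose[matrix(stats::runif(n * L) < spec$missing_rate, n, L)] <- NA_integer_
  map <- random_map(spec)
  gm <- genotype_matrix(dose,
                        sample_ids = sprintf("line%04d", seq_len(n)),
                        locus_ids = sprintf("mk%05d", seq_len(L)))
  list(genotypes = gm, map = map,
       truth = panel_truth(Q, fr$P, sample_ids(gm), locus_ids(gm)))
}

#' Generate a structured panel with along-chromosome linkage
#'
#' As [generate_panel()], but each subpopulation carries a pool of
#' `n_founders` founder haplotypes (drawn from its subpopulation
#' frequencies) and every gamete is a mosaic of founders: walking along a
#' chromosome, the founder is switched to a uniformly random one with
#' probability `1 - exp(-c * delta_d)` between adjacent markers separated
#' by `delta_d` cM, where `c = recomb_rate`.  Expected r-squared therefore
#' decays with genetic distance; small `c` gives chromosome-wide LD, large
#' `c` approaches the unlinked panel.  Each line's subpopulation of origin
#' is drawn from its admixture vector; selfing duplicates the first gamete
#' as in the unlinked generator.
#'
#' @inheritParams generate_panel
#' @return Same shape as [generate_panel()].
#' @export
generate_linked_panel <- function(spec = panel_spec(), seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  fr <- draw_frequencies(spec)
  Q <- rdirichlet(spec$n_samples, rep(spec$alpha, spec$K))
  map <- random_map(spec)
  ord <- match(map$locus_id, sprintf("mk%05d", seq_len(spec$n_loci)))
  P <- fr$P[ord, , drop = FALSE]  # frequencies in map order
  n <- spec$n_samples; L <- spec$n_loci; H <- spec$n_founders
  # founder haplotypes per subpopulation, in map order
  founders <- lapply(seq_len(spec$K), function(k)
    matrix(stats::runif(H * L) < rep(P[, k], each = H), H, L))
  pop <- apply(Q, 1, function(q) sample.int(spec$K, 1, prob = q))
  chrom_idx <- split(seq_len(L), map$chromosome)

  one_gamete <- function(k) {
    g <- logical(L)
    fh <- founders[[k]]
    for (idx in chrom_idx) {
      dpos <- diff(map$cM[idx])
      sw <- c(TRUE, stats::runif(length(dpos)) <
                1 - exp(-spec$recomb_rate * dpos))
      cur <- 0L
      for (t in seq_along(idx)) {
        if (sw[t]) cur <- sample.int(H, 1)
        g[idx[t]] <- fh[cur, idx[t]]
      }
    }
    g
  }
  dose <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    g1 <- one_gamete(pop[i])
    g2 <- if (stats::runif(1) < spec$selfing_rate) g1 else one_gamete(pop[i])
    dose[i, ] <- as.integer(g1) + as.integer(g2)
  }
  if (spec$missing_rate > 0)
    dose[matrix(stats::runif(n * L) < spec$missing_rate, n, L)] <- NA_integer_
  gm <- genotype_matrix(dose,
                        sample_ids = sprintf("line%04d", seq_len(n)),
                        locus_ids = map$locus_id)
  list(genotypes = gm, map = map,
       truth = panel_truth(Q, P, sample_ids(gm), locus_ids(gm)))
}

#' Simulate a preset germplasm panel
#'
#' Convenience wrapper with presets emulating the composition of a
#' Mediterranean wheat collection: `"landrace-like"` (170 lines, 3
#' subpopulations), `"modern-like"` (184 lines, 3 more strongly diverged
#' subpopulations) and `"combined"` (354 lines, 6 subpopulations, with an
#' era label splitting the panel into a landrace-like and a modern-like
#' half).
#'
#' @param preset one of `"combined"`, `"landrace-like"`, `"modern-like"`.
#' @param n_loci marker count (default 2000 for tractable examples).
#' @param seed integer seed.
#' @param ... overrides passed to [panel_spec()].
#' @return As [generate_panel()]; the `"combined"` preset also sets the
#'   genotype matrix's `era` labels.
#' @export
simulate_panel <- function(preset = c("combined", "landrace-like",
                                      "modern-like"),
                           n_loci = 2000, seed = 1, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "landrace-like" = list(n_samples = 170, K = 3, F = 0.12, alpha = 0.25),
    "modern-like" = list(n_samples = 184, K = 3, F = 0.17, alpha = 0.25),
    "combined" = list(n_samples = 354, K = 6, F = 0.15, alpha = 0.2))
  args$n_loci <- n_loci
  args <- utils::modifyList(args, list(...))
  panel <- generate_panel(do.call(panel_spec, args), seed = seed)
  if (preset == "combined") {
    # era follows the dominant ancestry: SP1-3 landrace-like, SP4-6 modern
    lab <- max.col(panel$truth$Q, ties.method = "first")
    panel$genotypes$era <- factor(ifelse(lab <= 3, "landrace", "modern"))
  }
  panel
}
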