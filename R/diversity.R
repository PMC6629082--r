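#' Polymorphic information content of a biallelic locus
#'
#' Botstein's PIC for a biallelic marker with allele frequency `p`:
#' `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2` with `q = 1 - p`.  Symmetric in
#' `p <-> q`, zero at monomorphism and maximal (0.375) at `p = 0.5`.
#'
#' @param p allele frequency (vectorised), in `[0, 1]`.
#' @return PIC value(s).
#' @export
pic_locus <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("allele frequency outside [0, 1]")
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Nei gene diversity of a biallelic locus
#'
#' Expected heterozygosity `H = 1 - p^2 - q^2 = 2pq`, maximal (0.5) at
#' `p = 0.5`.
#'
#' @inheritParams pic_locus
#' @return Gene diversity value(s).
#' @export
gene_diversity_locus <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("allele frequency outside [0, 1]")
  2 * p * (1 - p)
}

#' Gene flow from the differentiation coefficient
#'
#' McDonald-McDermott estimator `Nm = 0.5 (1 - G_ST) / G_ST`, strictly
#' decreasing in `G_ST`.  Undefined (returned as `NA` with a warning) for
#' `G_ST <= 0`.
#'
#' @param g_st differentiation coefficient(s) in `(0, 1]`.
#' @return Gene-flow estimate(s).
#' @export
gene_flow <- function(g_st) {
  out <- 0.5 * (1 - g_st) / g_st
  bad <- !is.na(g_st) & g_st <= 0
  if (any(bad)) {
    warning("Nm is undefined for G_ST <= 0")
    out[bad] <- NA_real_
  }
  out
}

# per-group B-allele frequencies and individual counts for each locus.
# returns list(p = loci x K matrix, n = loci x K called-individual counts,
#              ho = loci x K observed heterozygosity)
group_allele_freqs <- function(gm, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  L <- ncol(gm$dose)
  p <- n <- ho <- matrix(NA_real_, L, length(lev),
                         dimnames = list(locus_ids(gm), lev))
  for (k in seq_along(lev)) {
    d <- gm$dose[groups == lev[k], , drop = FALSE]
    nc <- colSums(!is.na(d))
    p[, k] <- colSums(d, na.rm = TRUE) / (2 * nc)
    n[, k] <- nc
    ho[, k] <- colSums(d == 1L, na.rm = TRUE) / nc
  }
  list(p = p, n = n, ho = ho)
}

#' Nei diversity partition and gene flow for a grouping
#'
#' Partitions gene diversity into within- and between-subpopulation
#' components following Nei: per locus the total diversity `H_T` is computed
#' from the mean of the subpopulation allele frequencies and the within
#' component `H_S` as the mean of the subpopulation diversities.  Both are
#' averaged over loci first; `D_ST = H_T - H_S`, `G_ST = D_ST / H_T` and
#' `Nm = 0.5 (1 - G_ST) / G_ST` are then formed from the locus means, so the
#' published closed-form identities hold exactly on the reported values.
#'
#' By default subpopulations are weighted equally (Nei's convention); set
#' `weighted = TRUE` to weight frequencies and diversities by sample size.
#' `correct_bias = TRUE` applies the Nei & Chesser small-sample corrections
#' (using per-group individual counts and observed heterozygosity), which
#' removes the downward plug-in bias of `H_S` in small groups; the default
#' (`FALSE`) is the uncorrected plug-in estimator.
#'
#' Loci with an undefined frequency in any group (no non-missing calls) are
#' excluded; their count is reported in the result.
#'
#' @param gm a [genotype_matrix()].
#' @param groups factor of subpopulation labels over samples (>= 2 levels,
#'   each with >= 2 samples).  Samples with `NA` labels are dropped.
#' @param weighted weight subpopulations by sample size (default `FALSE`).
#' @param correct_bias apply Nei & Chesser small-sample corrections
#'   (default `FALSE`).
#' @return An object of class `nei_partition` with fields `H_T`, `H_S`,
#'   `D_ST`, `G_ST`, `Nm`, `n_loci`, `n_excluded`, `n_samples`, and the
#'   per-locus component table `per_locus`.
#' @export
diversity_partition <- function(gm, groups = gm$era, weighted = FALSE,
                                correct_bias = FALSE) {
  if (is.null(groups)) stop("no group labels supplied")
  keep <- !is.na(groups)
  gm <- gm[keep, ]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2) stop("need at least two subpopulations")
  if (any(table(groups) < 2)) stop("every subpopulation needs >= 2 samples")
  fr <- group_allele_freqs(gm, groups)
  ok <- rowSums(!is.finite(fr$p)) == 0
  n_excl <- sum(!ok)
  if (n_excl) message(n_excl, " locus/loci with undefined group frequency excluded")
  p <- fr$p[ok, , drop = FALSE]
  n <- fr$n[ok, , drop = FALSE]
  ho <- fr$ho[ok, , drop = FALSE]
  if (!nrow(p)) stop("no usable loci")
  w <- if (weighted) table(groups) / length(groups) else
    rep(1 / nlevels(groups), nlevels(groups))
  w <- as.numeric(w)
  pbar <- drop(p %*% w)
  hs_k <- 2 * p * (1 - p)
  if (correct_bias) {
    # Nei & Chesser (1983): Hs_k = n/(n-1) (1 - sum p^2 - Ho/(2n));
    # Ht gains + mean(Hs)/(n~ K) - mean(Ho)/(2 n~ K) with n~ the harmonic
    # mean group size (per locus).
    hs_k <- n / (n - 1) * (hs_k - ho / (2 * n))
    nh <- ncol(n) / rowSums(1 / n)
    K <- ncol(p)
    hs_l <- drop(hs_k %*% w)
    ht_l <- 2 * pbar * (1 - pbar) + hs_l / (nh * K) -
      drop(ho %*% w) / (2 * nh * K)
  } else {
    hs_l <- drop(hs_k %*% w)
    ht_l <- 2 * pbar * (1 - pbar)
  }
  nei_partition(mean(ht_l), mean(hs_l),
                n_loci = nrow(p), n_excluded = n_excl,
                n_samples = length(groups),
                per_locus = data.frame(locus_id = rownames(p),
                                       H_T = ht_l, H_S = hs_l,
                                       row.names = NULL))
}

#' Build a Nei partition from mean diversities
#'
#' Completes the partition chain `D_ST = H_T - H_S`, `G_ST = D_ST / H_T`,
#' `Nm = 0.5 (1 - G_ST) / G_ST` from already-averaged total and
#' within-subpopulation gene diversities — e.g. values published in a report
#' table.
#'
#' @param H_T mean total gene diversity.
#' @param H_S mean within-subpopulation gene diversity (`<= H_T`).
#' @param ... further fields stored on the object (e.g. `n_samples`).
#' @return A `nei_partition` object.
#' @export
nei_partition <- function(H_T, H_S, ...) {
  stopifnot(is.finite(H_T), is.finite(H_S), H_T >= 0)
  d_st <- H_T - H_S
  g_st <- if (H_T > 0) d_st / H_T else NA_real_
  nm <- if (!is.na(g_st) && g_st > 0) 0.5 * (1 - g_st) / g_st else NA_real_
  out <- list(H_T = H_T, H_S = H_S, D_ST = d_st, G_ST = g_st, Nm = nm, ...)
  class(out) <- "nei_partition"
  out
}

#' @export
print.nei_partition <- function(x, digits = 4, ...) {
  cat("Nei diversity partition\n")
  if (!is.null(x$n_samples))
    cat(sprintf("  samples: %d   loci: %d\n", x$n_samples, x$n_loci))
  cat(sprintf("  H_T = %.*f   H_S = %.*f   D_ST = %.*f\n",
              digits, x$H_T, digits, x$H_S, digits, x$D_ST))
  cat(sprintf("  G_ST = %.*f   Nm = %s\n", digits, x$G_ST,
              if (is.na(x$Nm)) "undefined" else sprintf("%.2f", x$Nm)))
  invisible(x)
}

#' Diversity summary by chromosome and genome
#'
#' Undivided (single-population) gene diversity and PIC per chromosome, per
#' genome and overall, computed from whole-panel allele frequencies.  Genome
#' and total rows aggregate their chromosomes' markers exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param map a `genetic_map` covering the analysed loci.
#' @return data.frame with columns `region`, `level`
#'   (chromosome/genome/total), `N`, `H_T`, `PIC`.
#' @export
summarize_by_region <- function(gm, map) {
  ids <- locus_ids(gm)
  map <- map[match(ids, map$locus_id), , drop = FALSE]
  if (anyNA(map$locus_id))
    stop("loci without map position: ",
         paste(utils::head(ids[is.na(map$locus_id)], 5), collapse = ", "))
  st <- locus_stats(gm)
  p <- st$maf  # H and PIC are symmetric in p <-> q
  called <- !is.na(p)
  ht <- gene_diversity_locus(p[called])
  pic <- pic_locus(p[called])
  key_ch <- map$chromosome[called]
  key_g <- map$genome[called]
  row_for <- function(keys, label, level) {
    sel <- keys == label
    data.frame(region = label, level = level, N = sum(sel),
               H_T = mean(ht[sel]), PIC = mean(pic[sel]),
               stringsAsFactors = FALSE)
  }
  chroms <- intersect(wheat_chromosomes(), unique(key_ch))
  out <- do.call(rbind, c(
    lapply(chroms, function(ch) row_for(key_ch, ch, "chromosome")),
    lapply(sort(unique(key_g)), function(g) row_for(key_g, g, "genome")),
    list(data.frame(region = "Total", level = "total", N = sum(called),
                    H_T = mean(ht), PIC = mean(pic),
                    stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}
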