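#' EM estimate of two-locus haplotype frequencies from unphased genotypes
#'
#' Maximum-likelihood 2x2 haplotype frequencies for a pair of unphased
#' biallelic genotype vectors.  All genotype configurations except the
#' double heterozygote determine their two haplotypes; double heterozygotes
#' are split between the coupling (ab/AB) and repulsion (aB/Ab) phases by
#' EM, iterated to `tol` or `max_iter`.  On a fully homozygous (inbred)
#' panel there are no double heterozygotes and the EM reduces to direct
#' haplotype counting.
#'
#' @param dose_a,dose_b integer dose vectors (0/1/2/NA) of equal length.
#' @param max_iter,tol EM controls.
#' @return List with `freq` (2x2 matrix of haplotype frequencies, rows =
#'   locus-a allele 0/1, cols = locus-b allele 0/1), `counts` (expected
#'   haplotype counts, same layout), `n_pairs` (complete observations) and
#'   `iterations`.
#' @export
haplotype_freqs_em <- function(dose_a, dose_b, max_iter = 100, tol = 1e-8) {
  ok <- !is.na(dose_a) & !is.na(dose_b)
  a <- dose_a[ok]; b <- dose_b[ok]
  n <- length(a)
  if (n < 2) stop("need >= 2 samples with both loci non-missing")
  # genotype-pair counts: g[i+1, j+1] = #(dose_a == i & dose_b == j)
  g <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) g[i + 1, j + 1] <- sum(a == i & b == j)
  ndh <- g[2, 2]  # double heterozygotes
  # fixed haplotype counts contributed by unambiguous configurations
  base <- matrix(0, 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
  base[1, 1] <- 2 * g[1, 1] + g[1, 2] + g[2, 1]
  base[1, 2] <- 2 * g[1, 3] + g[1, 2] + g[2, 3]
  base[2, 1] <- 2 * g[3, 1] + g[3, 2] + g[2, 1]
  base[2, 2] <- 2 * g[3, 3] + g[3, 2] + g[2, 3]
  tot <- 2 * n
  f <- (base + ndh / 2) / tot  # start: split double hets evenly
  it <- 0L
  if (ndh > 0) {
    repeat {
      it <- it + 1L
      pc <- f[1, 1] * f[2, 2]  # coupling 00/11
      pr <- f[1, 2] * f[2, 1]  # repulsion 01/10
      w <- if (pc + pr > 0) pc / (pc + pr) else 0.5
      cnt <- base
      cnt[1, 1] <- cnt[1, 1] + ndh * w
      cnt[2, 2] <- cnt[2, 2] + ndh * w
      cnt[1, 2] <- cnt[1, 2] + ndh * (1 - w)
      cnt[2, 1] <- cnt[2, 1] + ndh * (1 - w)
      fn <- cnt / tot
      delta <- max(abs(fn - f))
      f <- fn
      if (delta < tol || it >= max_iter) break
    }
  }
  list(freq = f, counts = f * tot, n_pairs = n, iterations = it)
}

#' D and r-squared from 2x2 haplotype frequencies
#'
#' `D = p11 - pA pB` and `r^2 = D^2 / (pA (1-pA) pB (1-pB))`, with `pA`,
#' `pB` the marginal frequencies of allele 1 at the two loci.  Undefined
#' (`NA`) when a marginal frequency is 0 or 1.
#'
#' @param hf 2x2 haplotype frequency matrix (layout of
#'   [haplotype_freqs_em()]), or the list that function returns.
#' @return List with elements `D` and `r2`.
#' @export
ld_r2 <- function(hf) {
  if (is.list(hf)) hf <- hf$freq
  pa <- hf[2, 1] + hf[2, 2]
  pb <- hf[1, 2] + hf[2, 2]
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1)
    return(list(D = NA_real_, r2 = NA_real_))
  D <- hf[2, 2] - pa * pb
  list(D = D, r2 = D^2 / (pa * (1 - pa) * pb * (1 - pb)))
}

# largest-remainder rounding of nonnegative values to integers preserving
# the (integer) total
round_largest_remainder <- function(x) {
  total <- round(sum(x))
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  fl
}

#' Significance test for a 2x2 haplotype count table
#'
#' Two-sided Fisher exact test on integer haplotype counts, with a Pearson
#' chi-square (no continuity correction) used for tables whose cells are
#' all at least 5 when `method = "auto"`.  Fractional expected counts from
#' the EM are first rounded by largest remainder.
#'
#' @param counts 2x2 numeric matrix of haplotype counts.
#' @param method `"auto"`, `"fisher"` or `"chisq"`.
#' @return p-value in `(0, 1]`.
#' @export
ld_significance <- function(counts, method = c("auto", "fisher", "chisq")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2), all(counts >= 0), sum(counts) >= 2)
  if (any(abs(counts - round(counts)) > 1e-9))
    counts[] <- round_largest_remainder(as.numeric(counts))
  counts <- round(counts)
  if (method == "auto")
    method <- if (all(counts >= 5)) "chisq" else "fisher"
  if (method == "chisq") {
    p <- suppressWarnings(
      stats::chisq.test(counts, correct = FALSE)$p.value)
    if (is.na(p)) p <- 1
    return(min(max(p, .Machine$double.xmin), 1))
  }
  stats::fisher.test(counts)$p.value
}

# pair-level haplotype counts for a whole chromosome block.
# haploidize = TRUE: treat the panel as inbred lines -- for each pair use
# only individuals homozygous at both loci, one haplotype per line.  This
# avoids pseudo-replication of duplicated gametes in selfing panels.
# Returns 2x2 counts (n00,n01,n10,n11) per pair via crossproducts.
chrom_pair_counts <- function(dose, haploidize) {
  if (haploidize) {
    A1 <- (dose == 2L); A0 <- (dose == 0L)
    A1[is.na(A1)] <- FALSE; A0[is.na(A0)] <- FALSE
    mode(A1) <- "numeric"; mode(A0) <- "numeric"
    list(n00 = crossprod(A0), n01 = crossprod(A0, A1),
         n10 = crossprod(A1, A0), n11 = crossprod(A1))
  } else {
    NULL
  }
}

#' Intra-chromosomal LD scan
#'
#' Evaluates all marker pairs lying on the same chromosome within
#' `window_cM` of each other.  For inbred panels (`haploidize = TRUE`, the
#' default when the panel-wide heterozygosity is below 5%) each line
#' contributes one haplotype per pair, using lines homozygous at both loci;
#' otherwise haplotype frequencies are estimated by EM over all 2n gametes.
#' `r^2` is computed from the haplotype frequencies and significance by
#' [ld_significance()] on the haplotype count table.
#'
#' Pairs whose r-squared is undefined (a locus monomorphic in the
#' complete-case subset) are dropped from the table and from all summaries.
#'
#' @param gm a [genotype_matrix()] (filtered).
#' @param map a `genetic_map` covering the loci (unmapped loci are skipped).
#' @param window_cM maximum genetic distance between evaluated pairs
#'   (default 50).
#' @param alpha significance level for the "% significant" summary
#'   (default 0.001).
#' @param haploidize `NULL` (auto), `TRUE` or `FALSE`.
#' @param test compute p-values (default `TRUE`); `FALSE` leaves the
#'   `p_value` column `NA` (faster when only the decay is needed).
#' @param method p-value method passed to [ld_significance()].
#' @return An object of class `ld_table`: data.frame with columns `locus_a`,
#'   `locus_b`, `chromosome`, `genome`, `dist_cM`, `r2`, `p_value`, plus a
#'   per-chromosome `summary` attribute (data.frame: chromosome, genome,
#'   n_pairs, mean_r2, pct_significant).
#' @export
ld_scan <- function(gm, map, window_cM = 50, alpha = 0.001,
                    haploidize = NULL, test = TRUE,
                    method = c("auto", "fisher", "chisq")) {
  method <- match.arg(method)
  if (is.null(haploidize)) {
    het <- mean(gm$dose == 1L, na.rm = TRUE)
    haploidize <- is.finite(het) && het < 0.05
  }
  map <- map[map$locus_id %in% locus_ids(gm), , drop = FALSE]
  rows <- list()
  for (ch in unique(map$chromosome)) {
    sub <- map[map$chromosome == ch, , drop = FALSE]
    m <- nrow(sub)
    if (m < 2) next
    dose <- gm$dose[, sub$locus_id, drop = FALSE]
    cc <- if (haploidize) chrom_pair_counts(dose, TRUE) else NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        dist <- abs(sub$cM[j] - sub$cM[i])
        if (dist > window_cM) next
        if (haploidize) {
          cnt <- matrix(c(cc$n00[i, j], cc$n10[i, j],
                          cc$n01[i, j], cc$n11[i, j]), 2, 2)
          n <- sum(cnt)
          if (n < 2) next
          hf <- cnt / n
        } else {
          em <- tryCatch(haplotype_freqs_em(dose[, i], dose[, j]),
                         error = function(e) NULL)
          if (is.null(em)) next
          hf <- em$freq
          cnt <- em$counts
        }
        ld <- ld_r2(hf)
        if (is.na(ld$r2)) next
        p <- if (test) ld_significance(cnt, method = method) else NA_real_
        rows[[length(rows) + 1L]] <-
          data.frame(locus_a = sub$locus_id[i], locus_b = sub$locus_id[j],
                     chromosome = ch, genome = sub$genome[1],
                     dist_cM = dist, r2 = ld$r2, p_value = p,
                     stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_a = character(0), locus_b = character(0),
               chromosome = character(0), genome = character(0),
               dist_cM = numeric(0), r2 = numeric(0), p_value = numeric(0))
  summ <- NULL
  if (nrow(tab)) {
    summ <- do.call(rbind, lapply(split(tab, tab$chromosome), function(s) {
      data.frame(chromosome = s$chromosome[1], genome = s$genome[1],
                 n_pairs = nrow(s), mean_r2 = mean(s$r2),
                 pct_significant =
                   if (all(is.na(s$p_value))) NA_real_ else
                     100 * mean(s$p_value < alpha, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
    rownames(summ) <- NULL
  }
  attr(tab, "summary") <- summ
  attr(tab, "alpha") <- alpha
  attr(tab, "window_cM") <- window_cM
  class(tab) <- c("ld_table", "data.frame")
  tab
}

#' Per-genome critical r-squared
#'
#' The critical value used by the decay fit: the arithmetic mean r-squared
#' over all evaluated pairs on each genome's chromosomes.
#'
#' @param ld_table an `ld_table` from [ld_scan()].
#' @return Named numeric vector, one entry per genome.
#' @export
critical_r2_per_genome <- function(ld_table) {
  if (!nrow(ld_table)) stop("empty LD table")
  vapply(split(ld_table$r2, ld_table$genome), mean, numeric(1))
}

#' LOESS fit of LD decay along a chromosome
#'
#' Fits a degree-1 LOESS of r-squared on genetic distance for one
#' chromosome's pairs and locates the smallest distance (on a 0.1 cM grid)
#' at which the fitted curve falls to the critical r-squared.  The decay
#' distance is reported in whole centimorgans.  If the curve starts at or
#' below the critical value the decay is 0; if it never reaches it within
#' the observed distance range the fit is censored at the maximum distance.
#'
#' @param ld_table an `ld_table` (may contain several chromosomes).
#' @param chromosome chromosome to fit.
#' @param critical_r2 critical value, typically from
#'   [critical_r2_per_genome()].
#' @param span LOESS span (default 0.5).
#' @param min_pairs minimum pair count required (default 20).
#' @return Object of class `ld_decay_fit`: list with `chromosome`,
#'   `critical_r2`, `decay_cM` (whole cM, `NA` if undefined), `censored`,
#'   `n_pairs`, and `curve` (function evaluating the fitted LOESS).
#' @export
fit_ld_decay <- function(ld_table, chromosome, critical_r2, span = 0.5,
                         min_pairs = 20) {
  s <- ld_table[ld_table$chromosome == chromosome, , drop = FALSE]
  out <- list(chromosome = chromosome, critical_r2 = critical_r2,
              decay_cM = NA_real_, censored = FALSE, n_pairs = nrow(s),
              span = span, curve = NULL)
  class(out) <- "ld_decay_fit"
  if (nrow(s) < min_pairs) {
    warning(sprintf("chromosome %s: only %d pairs (< %d), decay undefined",
                    chromosome, nrow(s), min_pairs))
    return(out)
  }
  if (length(unique(s$dist_cM)) < 2)
    stop("degenerate distances: all pairs at the same distance")
  fit <- stats::loess(r2 ~ dist_cM, data = s, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  rng <- range(s$dist_cM)
  grid <- seq(max(0, rng[1]), rng[2], by = 0.1)
  yhat <- stats::predict(fit, newdata = data.frame(dist_cM = grid))
  out$curve <- function(d) stats::predict(fit,
                                          newdata = data.frame(dist_cM = d))
  below <- which(yhat <= critical_r2)
  if (!length(below)) {
    out$censored <- TRUE
    out$decay_cM <- round(rng[2])
  } else if (below[1] == 1L) {
    out$decay_cM <- 0
  } else {
    out$decay_cM <- round(grid[below[1]])
  }
  out
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf("LD decay fit, chromosome %s (%d pairs)\n",
              x$chromosome, x$n_pairs))
  cat(sprintf("  critical r2 = %.4f\n", x$critical_r2))
  if (is.na(x$decay_cM)) {
    cat("  decay: undefined (too few pairs)\n")
  } else if (x$censored) {
    cat(sprintf("  decay: > %d cM (no crossing in observed range)\n",
                x$decay_cM))
  } else {
    cat(sprintf("  decay: %d cM\n", x$decay_cM))
  }
  invisible(x)
}
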