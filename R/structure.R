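#' Fit the Bayesian admixture model by Gibbs sampling
#'
#' A Gibbs-sampler implementation of the admixture model of Pritchard,
#' Stephens and Donnelly with independent allele frequencies (Dirichlet
#' prior with `lambda = 1`): each of a sample's two allele copies at a locus
#' originates from one of `K` latent subpopulations with probabilities given
#' by the sample's admixture vector `q`.  Allele frequencies get Beta
#' posterior updates, admixture vectors Dirichlet updates, and the shared
#' admixture concentration `alpha` a Metropolis random-walk update (uniform
#' prior on `(0, 10)`, proposal sd 0.025).  Missing genotypes are skipped.
#' The model-choice statistic is STRUCTURE's estimator
#' `lnP = mean(L) - var(L)/2` over the post-burn-in trace of the
#' complete-data log-likelihood `L`.
#'
#' @param gm a [genotype_matrix()] (filtered, biallelic).
#' @param K number of latent subpopulations (>= 1).
#' @param burn_in burn-in sweeps (default 10000).
#' @param n_iter post-burn-in sweeps (default 100000).
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @param lambda Dirichlet prior parameter for allele frequencies.
#' @param alpha_init,alpha_prop_sd,alpha_max admixture-concentration prior
#'   and proposal controls.
#' @return Object of class `structure_fit`: `K`, `Q` (posterior-mean
#'   admixture, rows sum to 1), `P` (posterior-mean allele frequencies),
#'   `lnP` (model-choice estimate), `loglik_trace`, `alpha_trace`,
#'   `alpha_accept_rate`, `burn_in`, `n_iter`, `seed`.
#' @export
run_admixture_mcmc <- function(gm, K, burn_in = 10000, n_iter = 100000,
                               seed = NULL, lambda = 1, alpha_init = 1,
                               alpha_prop_sd = 0.025, alpha_max = 10) {
  stopifnot(K >= 1, burn_in >= 0, n_iter >= 1)
  if (K > nrow(gm$dose)) stop("K cannot exceed the number of samples")
  if (!is.null(seed)) set.seed(seed)
  res <- .admixture_gibbs(gm$dose, as.integer(K), as.integer(burn_in),
                          as.integer(n_iter), lambda, alpha_init,
                          alpha_prop_sd, alpha_max)
  ll <- res$loglik_trace
  lnP <- mean(ll) - stats::var(ll) / 2
  if (K > 1 && !is.na(res$alpha_accept_rate) && res$alpha_accept_rate < 0.01)
    warning("alpha Metropolis acceptance below 1%; check mixing")
  rownames(res$Q) <- sample_ids(gm)
  colnames(res$Q) <- paste0("SP", seq_len(K))
  rownames(res$P) <- locus_ids(gm)
  colnames(res$P) <- paste0("SP", seq_len(K))
  out <- list(K = K, Q = res$Q, P = res$P, lnP = lnP,
              loglik_trace = ll, alpha_trace = res$alpha_trace,
              alpha_accept_rate = res$alpha_accept_rate,
              burn_in = burn_in, n_iter = n_iter, seed = seed)
  class(out) <- "structure_fit"
  out
}

#' @export
print.structure_fit <- function(x, ...) {
  cat(sprintf("Admixture model fit: K = %d, %d samples x %d loci\n",
              x$K, nrow(x$Q), nrow(x$P)))
  cat(sprintf("  burn-in %d + %d sweeps, lnP = %.1f\n",
              x$burn_in, x$n_iter, x$lnP))
  cat(sprintf("  mean alpha = %.3f (acceptance %.1f%%)\n",
              mean(x$alpha_trace), 100 * x$alpha_accept_rate))
  invisible(x)
}

#' Run the admixture model over a K range with replicates
#'
#' Mirrors the usual STRUCTURE run design: every `K` in `k_range` is fitted
#' `n_reps` times with deterministic per-run seeds
#' `seed + 1000 * K + rep`, and the log-probability table needed by the
#' Evanno method is collected.
#'
#' @inheritParams run_admixture_mcmc
#' @param k_range integer vector of K values (default `1:10`).
#' @param n_reps replicate runs per K (default 7).
#' @param seed master seed (default 1).
#' @param keep_fits keep every `structure_fit` (default `TRUE`); with
#'   `FALSE` only `Q` for the run with the highest lnP per K is kept.
#' @return Object of class `structure_scan`: `lnP` (K x reps matrix),
#'   `fits` (list of lists of `structure_fit`), `k_range`, `seed`.
#' @export
structure_scan <- function(gm, k_range = 1:10, n_reps = 7,
                           burn_in = 10000, n_iter = 100000, seed = 1,
                           keep_fits = TRUE, ...) {
  stopifnot(length(k_range) >= 1, n_reps >= 1)
  lnP <- matrix(NA_real_, length(k_range), n_reps,
                dimnames = list(paste0("K", k_range), NULL))
  fits <- vector("list", length(k_range))
  names(fits) <- paste0("K", k_range)
  for (ki in seq_along(k_range)) {
    K <- k_range[ki]
    runs <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      fit <- run_admixture_mcmc(gm, K, burn_in = burn_in, n_iter = n_iter,
                                seed = seed + 1000L * K + r, ...)
      lnP[ki, r] <- fit$lnP
      runs[[r]] <- if (keep_fits) fit else fit["Q"]
    }
    fits[[ki]] <- runs
  }
  out <- list(lnP = lnP, fits = fits, k_range = k_range, seed = seed)
  class(out) <- "structure_scan"
  out
}

#' Evanno delta-K statistics from a log-probability table
#'
#' For consecutive K values with replicate runs: `L'(K) = L(K) - L(K-1)`,
#' `L''(K) = L'(K+1) - L'(K)` and `deltaK = mean|L''(K)| / sd(L(K))`, where
#' `L(K)` is the replicate mean.  The most likely number of subpopulations
#' is the interior K maximising deltaK.  `deltaK` is undefined at the K
#' endpoints and wherever the replicate sd is 0.
#'
#' @param lnP K x replicates matrix of log-probability values (rownames
#'   `K<k>` or attribute ordering taken as consecutive), or a
#'   `structure_scan`.
#' @param k_range K values of the rows (default parsed from rownames, else
#'   `1:nrow`).
#' @return Object of class `evanno_result`: data.frame with columns `K`,
#'   `mean_lnP`, `sd_lnP`, `Lp`, `Lpp_abs`, `deltaK`, and attribute
#'   `best_K` (`NA` if no interior peak is defined).
#' @export
evanno_delta_k <- function(lnP, k_range = NULL) {
  if (inherits(lnP, "structure_scan")) {
    k_range <- lnP$k_range
    lnP <- lnP$lnP
  }
  lnP <- as.matrix(lnP)
  if (is.null(k_range)) {
    k_range <- if (!is.null(rownames(lnP)))
      as.integer(sub("^K", "", rownames(lnP))) else seq_len(nrow(lnP))
  }
  if (nrow(lnP) < 3) stop("need at least 3 consecutive K values")
  if (ncol(lnP) < 2) stop("need at least 2 replicate runs per K")
  if (any(diff(k_range) != 1)) stop("K values must be consecutive")
  m <- rowMeans(lnP)
  s <- apply(lnP, 1, stats::sd)
  nk <- length(k_range)
  Lp <- c(NA, diff(m))                       # L'(K) = L(K) - L(K-1)
  Lpp <- c(NA, diff(Lp)[-1], NA)             # L''(K) = L'(K+1) - L'(K)
  deltaK <- abs(Lpp) / s
  deltaK[c(1, nk)] <- NA
  if (any(s[-c(1, nk)] == 0)) {
    warning("replicate sd is 0 at some K; deltaK undefined there")
    deltaK[s == 0] <- NA
  }
  out <- data.frame(K = k_range, mean_lnP = m, sd_lnP = s,
                    Lp = Lp, Lpp_abs = abs(Lpp), deltaK = deltaK,
                    row.names = NULL)
  interior <- !is.na(out$deltaK)
  best <- if (any(interior) && max(out$deltaK[interior]) > 0)
    out$K[interior][which.max(out$deltaK[interior])] else NA_integer_
  if (all(is.na(out$Lpp_abs) | out$Lpp_abs == 0)) best <- NA_integer_
  attr(out, "best_K") <- best
  class(out) <- c("evanno_result", "data.frame")
  out
}

#' Classify samples by their strongest admixture coefficient
#'
#' Using the printed threshold conventions: a sample is a *strong* member of
#' its best subpopulation when `q_best > strong` (default 0.7), a *moderate*
#' member when `moderate < q_best <= strong` (default 0.5), and *admixed*
#' otherwise (strict inequalities).
#'
#' @param Q samples x K admixture matrix (rows sum to 1) or a
#'   `structure_fit`.
#' @param strong,moderate thresholds.
#' @return data.frame with columns `sample_id`, `subpopulation` (`SP<k>` of
#'   the maximal q; admixed samples keep their best SP), `q_best`, `class`
#'   (factor strong/moderate/admixed).
#' @export
assign_membership <- function(Q, strong = 0.7, moderate = 0.5) {
  if (inherits(Q, "structure_fit")) Q <- Q$Q
  Q <- as.matrix(Q)
  best <- max.col(Q, ties.method = "first")
  qb <- Q[cbind(seq_len(nrow(Q)), best)]
  cls <- ifelse(qb > strong, "strong",
                ifelse(qb > moderate, "moderate", "admixed"))
  data.frame(sample_id = rownames(Q) %||% paste0("S", seq_len(nrow(Q))),
             subpopulation = paste0("SP", best), q_best = qb,
             class = factor(cls, levels = c("strong", "moderate", "admixed")),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align and average replicate admixture runs
#'
#' Replicate MCMC runs at the same K are label-switched; columns of each run
#' are greedily matched to the first run by maximal Pearson correlation
#' (ties broken by column index) and the aligned matrices averaged, then
#' row-renormalised.
#'
#' @param runs list of samples x K admixture matrices (or `structure_fit`s)
#'   at the same K, or a single matrix (returned unchanged).
#' @return Samples x K matrix of the aligned mean.
#' @export
aggregate_runs <- function(runs) {
  if (!is.list(runs) || inherits(runs, "structure_fit")) runs <- list(runs)
  qs <- lapply(runs, function(r) {
    if (inherits(r, "structure_fit") || is.list(r)) as.matrix(r$Q)
    else as.matrix(r)
  })
  K <- ncol(qs[[1]])
  if (any(vapply(qs, ncol, 0L) != K)) stop("runs have differing K")
  if (length(qs) == 1L) return(qs[[1]])
  acc <- qs[[1]]
  for (r in 2:length(qs)) {
    acc <- acc + align_columns(qs[[r]], qs[[1]])
  }
  m <- acc / length(qs)
  m / rowSums(m)
}

# greedy correlation matching of columns of x onto columns of ref
align_columns <- function(x, ref) {
  K <- ncol(ref)
  if (K == 1L) return(x)
  cc <- suppressWarnings(stats::cor(ref, x))
  cc[!is.finite(cc)] <- -Inf
  perm <- integer(K)
  usedr <- usedx <- rep(FALSE, K)
  for (step in seq_len(K)) {
    # highest remaining correlation; ties by smallest (ref, x) index
    best <- -Inf; bi <- bj <- 1L
    for (i in seq_len(K)) {
      if (usedr[i]) next
      for (j in seq_len(K)) {
        if (usedx[j]) next
        if (cc[i, j] > best) { best <- cc[i, j]; bi <- i; bj <- j }
      }
    }
    perm[bi] <- bj
    usedr[bi] <- TRUE; usedx[bj] <- TRUE
  }
  x[, perm, drop = FALSE]
}
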