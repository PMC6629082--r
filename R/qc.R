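#' Per-locus missingness and minor allele frequency
#'
#' MAF is allele-count based: with `nAA`, `nAB`, `nBB` non-missing genotype
#' counts, the B-allele frequency is `p = (2 nBB + nAB) / (2 n)` and
#' `maf = min(p, 1 - p)`.  Heterozygotes contribute one copy of each allele.
#' Loci with no non-missing calls get `maf = NA`.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame with columns `locus_id`, `n_called`, `missing_rate`,
#'   `maf`.
#' @export
locus_stats <- function(gm) {
  d <- gm$dose
  n <- nrow(d)
  n_called <- colSums(!is.na(d))
  miss <- 1 - n_called / n
  p <- colSums(d, na.rm = TRUE) / (2 * n_called)  # freq of B allele
  maf <- pmin(p, 1 - p)
  maf[n_called == 0] <- NA_real_
  data.frame(locus_id = locus_ids(gm), n_called = n_called,
             missing_rate = miss, maf = maf, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Filter markers on missingness and MAF
#'
#' Removal precedence is missingness first, then MAF, so the two removal
#' counts and the retained count sum exactly to the input count (a locus
#' failing both thresholds is counted under missingness).  Boundary
#' semantics follow "more than"/"lower than": a locus is removed when
#' `missing_rate > max_missing` or `maf < min_maf`; a locus with
#' `maf == min_maf` exactly is retained.  Loci whose MAF is undefined
#' (all calls missing) are removed under missingness.
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing maximum tolerated per-locus missing fraction
#'   (default 0.25).
#' @param min_maf minimum tolerated minor allele frequency (default 0.05).
#' @return A list of class `filter_report` with elements `genotypes` (the
#'   filtered [genotype_matrix()]), `n_input`, `n_removed_missing`,
#'   `n_removed_maf`, `n_retained` and the per-locus `stats` table with a
#'   `status` column.
#' @export
filter_markers <- function(gm, max_missing = 0.25, min_maf = 0.05) {
  stopifnot(max_missing > 0, max_missing < 1, min_maf > 0, min_maf < 1)
  st <- locus_stats(gm)
  fail_miss <- st$missing_rate > max_missing | is.na(st$maf)
  fail_maf <- !fail_miss & st$maf < min_maf
  keep <- !fail_miss & !fail_maf
  if (!any(keep)) stop("no markers retained by the filters")
  st$status <- ifelse(fail_miss, "removed_missing",
                      ifelse(fail_maf, "removed_maf", "retained"))
  out <- list(genotypes = gm[, keep],
              n_input = ncol(gm$dose),
              n_removed_missing = sum(fail_miss),
              n_removed_maf = sum(fail_maf),
              n_retained = sum(keep),
              max_missing = max_missing, min_maf = min_maf,
              stats = st)
  class(out) <- "filter_report"
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Marker filter report\n")
  cat(sprintf("  input loci:        %6d\n", x$n_input))
  cat(sprintf("  removed, missing > %.0f%%: %6d\n",
              100 * x$max_missing, x$n_removed_missing))
  cat(sprintf("  removed, MAF < %.0f%%:     %6d\n",
              100 * x$min_maf, x$n_removed_maf))
  cat(sprintf("  retained:          %6d\n", x$n_retained))
  invisible(x)
}

# polymorphic within a set of rows: >= 2 distinct alleles observed
# (any heterozygote, or both homozygote classes present)
is_polymorphic <- function(dose) {
  any1 <- colSums(dose == 1L, na.rm = TRUE) > 0
  any0 <- colSums(dose == 0L, na.rm = TRUE) > 0
  any2 <- colSums(dose == 2L, na.rm = TRUE) > 0
  any1 | (any0 & any2)
}

#' Partition marker polymorphism between two sample groups
#'
#' A locus is polymorphic within a group iff at least two distinct alleles
#' are observed among the group's non-missing calls.  The union counts loci
#' polymorphic in at least one group; a locus fixed for different alleles in
#' the two groups is polymorphic in neither and excluded from the union.
#'
#' @param gm a [genotype_matrix()].
#' @param groups a 2-level factor/vector over samples (e.g. era labels);
#'   defaults to `gm$era`.
#' @return A list of class `polymorphism_partition`: `n_total_union`,
#'   `n_common`, `n_only_group1`, `n_only_group2`, the group names, and the
#'   per-locus logical matrix `polymorphic`.
#' @export
partition_polymorphism <- function(gm, groups = gm$era) {
  if (is.null(groups)) stop("no group labels supplied")
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  g1 <- is_polymorphic(gm$dose[groups == levels(groups)[1], , drop = FALSE])
  g2 <- is_polymorphic(gm$dose[groups == levels(groups)[2], , drop = FALSE])
  out <- list(n_total_union = sum(g1 | g2),
              n_common = sum(g1 & g2),
              n_only_group1 = sum(g1 & !g2),
              n_only_group2 = sum(!g1 & g2),
              groups = levels(groups),
              polymorphic = cbind(group1 = g1, group2 = g2))
  class(out) <- "polymorphism_partition"
  out
}

#' @export
print.polymorphism_partition <- function(x, ...) {
  cat("Polymorphism partition\n")
  cat(sprintf("  union:          %6d\n", x$n_total_union))
  cat(sprintf("  common:         %6d\n", x$n_common))
  cat(sprintf("  only %-10s %6d\n", paste0(x$groups[1], ":"), x$n_only_group1))
  cat(sprintf("  only %-10s %6d\n", paste0(x$groups[2], ":"), x$n_only_group2))
  invisible(x)
}

#' Thin mapped markers by LD-decay spacing
#'
#' Greedy left-to-right scan along each chromosome (map order: position,
#' ties by locus id): the first marker is retained, and a subsequent marker
#' is retained only if it lies at least `decay_cM` centimorgans beyond the
#' last retained marker.  With spacing 0 every mapped marker is retained.
#' Markers absent from the map are excluded with a message.
#'
#' @param gm a [genotype_matrix()] (only its locus ids are used).
#' @param map a `genetic_map`.
#' @param decay_cM minimum spacing; a single number or a named vector with
#'   one entry per chromosome present in the map.
#' @return Character vector of retained locus ids.
#' @export
thin_by_decay <- function(gm, map, decay_cM) {
  ids <- locus_ids(gm)
  unmapped <- setdiff(ids, map$locus_id)
  if (length(unmapped))
    message(length(unmapped), " marker(s) without map position excluded")
  map <- map[map$locus_id %in% ids, , drop = FALSE]
  chroms <- unique(map$chromosome)
  if (length(decay_cM) == 1L && is.null(names(decay_cM)))
    decay_cM <- stats::setNames(rep(decay_cM, length(chroms)), chroms)
  if (any(!chroms %in% names(decay_cM)))
    stop("no decay distance for chromosome(s): ",
         paste(setdiff(chroms, names(decay_cM)), collapse = ", "))
  if (any(decay_cM < 0, na.rm = TRUE)) stop("decay distances must be >= 0")
  keep <- character(0)
  for (ch in chroms) {
    sub <- map[map$chromosome == ch, , drop = FALSE]  # already sorted
    d <- decay_cM[[ch]]
    if (is.na(d)) d <- 0
    last <- -Inf
    for (k in seq_len(nrow(sub))) {
      if (sub$cM[k] - last >= d) {
        keep <- c(keep, sub$locus_id[k])
        last <- sub$cM[k]
      }
    }
  }
  keep
}
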