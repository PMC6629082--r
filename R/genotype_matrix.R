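#' Construct a genotype matrix object
#'
#' The central data container of the package: a samples x loci table of
#' biallelic SNP calls stored as allele doses.  A dose counts copies of the
#' locus "B" allele (the second allele of the pair recorded for the locus):
#' 0 = AA, 1 = AB, 2 = BB, `NA` = missing.  Allele identity is kept as
#' encountered in the source file; no minor-allele re-polarisation is applied.
#'
#' @param dose integer matrix (samples in rows, loci in columns) with values
#'   in `{0, 1, 2, NA}`.  Row and column names, if present, seed the sample
#'   and locus ids.
#' @param sample_ids,locus_ids character vectors of unique ids; default to
#'   the dimnames of `dose`.
#' @param alleles optional 2-column character matrix (columns `a`, `b`) of
#'   the allele nucleotides per locus; defaults to generic `"A"`/`"B"`.
#' @param era optional per-sample class label, e.g. `"landrace"`/`"modern"`,
#'   used by group-wise analyses.
#'
#' @return An object of class `geno_matrix`: a list with elements `dose`
#'   (integer matrix with dimnames), `alleles` (character matrix) and `era`
#'   (factor or `NULL`).
#' @export
genotype_matrix <- function(dose, sample_ids = rownames(dose),
                            locus_ids = colnames(dose),
                            alleles = NULL, era = NULL) {
  dose <- as.matrix(dose)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dose)))
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(dose)))
  sample_ids <- as.character(sample_ids)
  locus_ids <- as.character(locus_ids)
  if (nrow(dose) != length(sample_ids) || ncol(dose) != length(locus_ids))
    stop("dimensions of 'dose' do not match id vectors")
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (anyDuplicated(locus_ids)) stop("duplicated locus ids")
  if (nrow(dose) < 2L) stop("a genotype matrix needs at least 2 samples")
  if (ncol(dose) < 1L) stop("a genotype matrix needs at least 1 locus")
  storage.mode(dose) <- "integer"
  bad <- !(dose %in% c(0L, 1L, 2L)) & !is.na(dose)
  if (any(bad)) stop("dose values must be 0, 1, 2 or NA")
  dimnames(dose) <- list(sample_ids, locus_ids)
  if (is.null(alleles)) {
    alleles <- matrix(rep(c("A", "B"), each = ncol(dose)), ncol = 2,
                      dimnames = list(locus_ids, c("a", "b")))
  } else {
    alleles <- as.matrix(alleles)
    if (nrow(alleles) != ncol(dose) || ncol(alleles) != 2)
      stop("'alleles' must be a loci x 2 matrix")
    dimnames(alleles) <- list(locus_ids, c("a", "b"))
  }
  if (!is.null(era)) {
    if (length(era) != nrow(dose)) stop("'era' must have one label per sample")
    era <- factor(era)
  }
  structure(list(dose = dose, alleles = alleles, era = era),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d loci\n",
              nrow(x$dose), ncol(x$dose)))
  miss <- mean(is.na(x$dose))
  het <- mean(x$dose == 1L, na.rm = TRUE)
  cat(sprintf("  missing calls: %.2f%%   heterozygous calls: %.2f%%\n",
              100 * miss, 100 * het))
  if (!is.null(x$era)) {
    tab <- table(x$era)
    cat("  era:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dose)

#' Subset a genotype matrix
#'
#' @param x a `geno_matrix`.
#' @param i sample index (integer, logical or sample ids).
#' @param j locus index (integer, logical or locus ids).
#' @param ... unused.
#' @return A `geno_matrix` restricted to the selected samples and loci.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dose))
  if (missing(j)) j <- seq_len(ncol(x$dose))
  genotype_matrix(x$dose[i, j, drop = FALSE],
                  alleles = x$alleles[j, , drop = FALSE],
                  era = if (!is.null(x$era)) x$era[i])
}

#' Sample and locus identifiers
#'
#' @param gm a `geno_matrix`.
#' @return Character vector of ids.
#' @export
sample_ids <- function(gm) rownames(gm$dose)

#' @rdname sample_ids
#' @export
locus_ids <- function(gm) colnames(gm$dose)

# decode doses to two-letter calls ("AA","AB","BB","NA") using the stored
# allele pair; inverse of the encoding applied on read
decode_calls <- function(gm) {
  n <- nrow(gm$dose); L <- ncol(gm$dose)
  out <- matrix(NA_character_, n, L, dimnames = dimnames(gm$dose))
  a <- gm$alleles[, "a"]; b <- gm$alleles[, "b"]
  for (j in seq_len(L)) {
    cj <- c(paste0(a[j], a[j]), paste0(a[j], b[j]), paste0(b[j], b[j]))
    d <- gm$dose[, j]
    out[, j] <- ifelse(is.na(d), NA_character_, cj[d + 1L])
  }
  out
}
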