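#' Read a genotype matrix from disk
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`matrix`}{the package's native tab-delimited layout, samples in
#'     rows.  Two header lines: line 1 is `id` followed by the locus ids;
#'     line 2 is `alleles` followed by the allele pair of each locus written
#'     `a/b`.  Data rows hold the sample id and two-letter genotype calls
#'     (`AA`, `AB`, `BB`).  Missing calls may be written `NA`, `--` or `./.`.}
#'   \item{`hapmap`}{a HapMap diploid table (11 annotation columns
#'     `rs#` ... `QCcode`, then one column per sample with two-letter calls,
#'     `NN` missing).}
#'   \item{`vcf`}{a VCF with biallelic SNP records; requires the `vcfR`
#'     package.  Genotypes are taken from the GT field.}
#' }
#' Doses count copies of the locus' second (`b`, i.e. alt) allele as
#' encountered in the file; no minor-allele re-polarisation is performed.
#' Multi-allelic records are rejected per locus with a message; if more than
#' half of the records are rejected the read fails.
#'
#' @param path file to read.
#' @param dialect one of `"matrix"`, `"hapmap"`, `"vcf"`.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, dialect = c("matrix", "hapmap", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         matrix = read_geno_native(path),
         hapmap = read_geno_hapmap(path),
         vcf = read_geno_vcf(path))
}

MISSING_TOKENS <- c("NA", "--", "./.", "NN", "")

encode_calls <- function(calls, a, b) {
  # calls: character matrix samples x loci; a, b allele per locus
  n <- nrow(calls); L <- ncol(calls)
  dose <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    cj <- calls[, j]
    lv <- c(paste0(a[j], a[j]), paste0(a[j], b[j]),
            paste0(b[j], a[j]), paste0(b[j], b[j]))
    d <- c(0L, 1L, 1L, 2L)[match(cj, lv)]
    bad <- is.na(d) & !(cj %in% MISSING_TOKENS) & !is.na(cj)
    if (any(bad))
      stop(sprintf("locus %d: unrecognised calls (e.g. '%s') for alleles %s/%s",
                   j, cj[which(bad)[1]], a[j], b[j]))
    dose[, j] <- d
  }
  dose
}

read_geno_native <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4) stop("parse error: fewer than 4 lines (need 2 header lines and >=2 samples)")
  h1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  h2 <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (h1[1] != "id") stop("parse error at line 1: first field must be 'id'")
  if (h2[1] != "alleles") stop("parse error at line 2: first field must be 'alleles'")
  loci <- h1[-1]
  ab <- strsplit(h2[-1], "/", fixed = TRUE)
  if (length(ab) != length(loci) || any(lengths(ab) != 2))
    stop("parse error at line 2: allele pairs must be written a/b, one per locus")
  ab <- do.call(rbind, ab)
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  nf <- lengths(body)
  if (any(nf != length(loci) + 1L))
    stop("parse error at line ", which(nf != length(loci) + 1L)[1] + 2L,
         ": wrong number of fields")
  ids <- vapply(body, `[`, "", 1L)
  calls <- do.call(rbind, lapply(body, `[`, -1L))
  dose <- encode_calls(calls, ab[, 1], ab[, 2])
  genotype_matrix(dose, sample_ids = ids, locus_ids = loci, alleles = ab)
}

read_geno_hapmap <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  fixed <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
             "center", "protLSID", "assayLSID", "panelLSID", "QCcode")
  if (ncol(tab) < 12 || !identical(names(tab)[1:2], fixed[1:2]))
    stop("parse error: not a HapMap diploid table (header mismatch)")
  nfix <- sum(names(tab) %in% fixed)
  loci <- tab[["rs#"]]
  ab <- strsplit(tab[["alleles"]], "/", fixed = TRUE)
  multi <- lengths(ab) != 2
  if (any(multi)) {
    message(sum(multi), " non-biallelic HapMap record(s) rejected")
    if (mean(multi) > 0.5) stop("more than 50% of records are not biallelic")
    tab <- tab[!multi, , drop = FALSE]; loci <- loci[!multi]; ab <- ab[!multi]
  }
  ab <- do.call(rbind, ab)
  calls <- t(as.matrix(tab[, -(seq_len(nfix)), drop = FALSE]))
  dose <- encode_calls(calls, ab[, 1], ab[, 2])
  genotype_matrix(dose, sample_ids = rownames(calls), locus_ids = loci,
                  alleles = ab)
}

read_geno_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]; ref <- fix[, "REF"]
  multi <- grepl(",", alt, fixed = TRUE) | nchar(alt) != 1 | nchar(ref) != 1
  if (any(multi)) {
    message(sum(multi), " multi-allelic/non-SNP VCF record(s) rejected")
    if (mean(multi) > 0.5) stop("more than 50% of VCF records rejected")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  ref <- ref[!multi]; alt <- alt[!multi]
  ids <- fix[!multi, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[!multi, "CHROM"], "_", fix[!multi, "POS"])[is.na(ids) | ids == "."]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dose <- matrix(NA_integer_, ncol(gt), nrow(gt))
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  for (j in seq_len(nrow(gt))) dose[, j] <- lut[gt[j, ]]
  genotype_matrix(dose, sample_ids = colnames(gt), locus_ids = ids,
                  alleles = cbind(ref, alt))
}

#' Write a genotype matrix in the native delimited dialect
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_genotype_matrix <- function(gm, path) {
  calls <- decode_calls(gm)
  calls[is.na(calls)] <- "NA"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", locus_ids(gm)), collapse = "\t"), con)
  writeLines(paste(c("alleles",
                     paste0(gm$alleles[, "a"], "/", gm$alleles[, "b"])),
                   collapse = "\t"), con)
  writeLines(paste(sample_ids(gm),
                   apply(calls, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Wheat chromosome names
#'
#' The 21 chromosomes of hexaploid bread wheat, `1A` ... `7D`, grouped into
#' the A, B and D genomes.
#' @return Character vector of length 21.
#' @export
wheat_chromosomes <- function() {
  paste0(rep(1:7, each = 3), rep(c("A", "B", "D"), 7))
}

#' Read a genetic map
#'
#' Expects a delimited table with columns `locus_id`, `chromosome` and `cM`.
#' The genome (A/B/D) is derived from the last character of the chromosome
#' name.  Markers are sorted within chromosome by position, ties broken by
#' locus id.
#'
#' @param path file to read (tab- or comma-delimited; auto-detected).
#' @param chromosomes valid chromosome names; defaults to the 21 wheat
#'   chromosomes.
#' @return A data.frame of class `genetic_map` with columns `locus_id`,
#'   `chromosome`, `genome`, `cM`.
#' @export
read_genetic_map <- function(path, chromosomes = wheat_chromosomes()) {
  sep <- if (grepl(",", readLines(path, n = 1))) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("locus_id", "chromosome", "cM")
  if (!all(need %in% names(tab)))
    stop("map must have columns: ", paste(need, collapse = ", "))
  genetic_map(tab$locus_id, tab$chromosome, tab$cM, chromosomes = chromosomes)
}

#' Construct a genetic map object
#'
#' @param locus_id character vector of marker ids (unique).
#' @param chromosome chromosome name per marker.
#' @param cM genetic position in centimorgans (finite, non-negative).
#' @param chromosomes the set of valid chromosome names.
#' @return A `genetic_map` data.frame sorted by chromosome then position
#'   (ties broken by locus id), with the genome letter derived from the
#'   chromosome name.
#' @export
genetic_map <- function(locus_id, chromosome, cM,
                        chromosomes = wheat_chromosomes()) {
  locus_id <- as.character(locus_id)
  chromosome <- as.character(chromosome)
  cM <- as.numeric(cM)
  if (anyDuplicated(locus_id)) stop("duplicated locus ids in map")
  bad <- !(chromosome %in% chromosomes)
  if (any(bad))
    stop("unknown chromosome label(s): ",
         paste(unique(chromosome[bad]), collapse = ", "))
  if (any(!is.finite(cM)) || any(cM < 0))
    stop("map positions must be finite and >= 0")
  genome <- substring(chromosome, nchar(chromosome))
  map <- data.frame(locus_id = locus_id, chromosome = chromosome,
                    genome = genome, cM = cM, stringsAsFactors = FALSE)
  map <- map[order(factor(map$chromosome, levels = chromosomes),
                   map$cM, map$locus_id), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Write a genetic map
#'
#' @param map a `genetic_map`.
#' @param path output file (tab-delimited).
#' @return Invisibly, `path`.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(map[, c("locus_id", "chromosome", "cM")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Delimited table with columns `sample_id`, `era` and optionally `country`,
#' `region`.  When a genotype matrix is supplied, metadata ids must be a
#' subset check of its sample ids.
#'
#' @param path file to read.
#' @param gm optional [genotype_matrix()] to validate ids against.
#' @return A data.frame.
#' @export
read_sample_metadata <- function(path, gm = NULL) {
  sep <- if (grepl(",", readLines(path, n = 1))) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "era") %in% names(tab)))
    stop("metadata must have columns sample_id and era")
  if (!is.null(gm)) {
    extra <- setdiff(tab$sample_id, sample_ids(gm))
    if (length(extra))
      stop("metadata ids not in genotype matrix: ",
           paste(utils::head(extra, 5), collapse = ", "))
  }
  tab
}

#' Write a tree in Newick format
#'
#' @param tree an [ape::phylo] tree (as returned by [neighbor_joining()]).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
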