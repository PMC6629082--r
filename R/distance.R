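#' Simple-matching genetic distance
#'
#' Pairwise similarity is the proportion of loci at which two samples carry
#' the same genotype state (doses compared as states 0/1/2), counted over
#' loci non-missing in both samples; the distance is one minus the
#' similarity.  Pairs with fewer than `min_loci` comparable loci are flagged
#' with a warning; a pair with no comparable locus is an error.
#'
#' @param gm a [genotype_matrix()].
#' @param min_loci flag pairs with fewer comparable loci (default 10).
#' @return Symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`, dimnames = sample ids.
#' @export
simple_matching_distance <- function(gm, min_loci = 10) {
  d <- gm$dose
  if (nrow(d) < 2) stop("need at least 2 samples")
  called <- !is.na(d)
  mode(called) <- "numeric"
  comparable <- tcrossprod(called)
  matches <- matrix(0, nrow(d), nrow(d))
  for (v in 0:2) {
    ind <- (d == v)
    ind[is.na(ind)] <- FALSE
    mode(ind) <- "numeric"
    matches <- matches + tcrossprod(ind)
  }
  off <- upper.tri(comparable)
  if (any(comparable[off] == 0)) {
    idx <- which(comparable == 0 & off, arr.ind = TRUE)[1, ]
    stop(sprintf("samples %s and %s share no comparable locus",
                 sample_ids(gm)[idx[1]], sample_ids(gm)[idx[2]]))
  }
  if (any(comparable[off] < min_loci))
    warning(sum(comparable[off] < min_loci),
            " pair(s) with fewer than ", min_loci, " comparable loci")
  dist <- 1 - matches / comparable
  diag(dist) <- 0
  dimnames(dist) <- list(sample_ids(gm), sample_ids(gm))
  dist
}

#' Neighbour-joining tree
#'
#' The Saitou-Nei agglomeration on a distance matrix, with deterministic
#' behaviour fixed: the pair minimising the Q-criterion is joined, ties
#' broken by the smallest row/column index pair; branch lengths use the
#' standard formulas, and a negative branch length is clamped to zero with
#' the deficit transferred to its sister branch.  The final three nodes are
#' joined at a trifurcation, giving an unrooted binary tree with `2n - 3`
#' edges.
#'
#' @param D symmetric distance matrix with sample ids as dimnames
#'   (`n >= 3`).
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("neighbour joining needs at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")
  labels <- rownames(D) %||% paste0("S", seq_len(n))

  # node bookkeeping: tips are 1..n, internal nodes n+1 .. 2n-2 (ape order,
  # root = n+1 assigned last)
  n_internal <- n - 2L
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  next_internal <- n + n_internal  # assign internal ids downwards, root last
  active_id <- seq_len(n)          # current node ids in D's row order
  Dc <- D

  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    lens <<- c(lens, max(len, 0))
  }

  while (length(active_id) > 3) {
    m <- nrow(Dc)
    rs <- rowSums(Dc)
    Qm <- (m - 2) * Dc - outer(rs, rs, "+")
    diag(Qm) <- Inf
    # argmin with smallest (i, j) tie-break, i < j
    best <- Inf; bi <- 1L; bj <- 2L
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (Qm[i, j] < best - 1e-12) { best <- Qm[i, j]; bi <- i; bj <- j }
    }
    dij <- Dc[bi, bj]
    li <- 0.5 * dij + (rs[bi] - rs[bj]) / (2 * (m - 2))
    lj <- dij - li
    # clamp negatives, moving the deficit to the sister branch
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_id <- next_internal
    next_internal <- next_internal - 1L
    add_edge(new_id, active_id[bi], li)
    add_edge(new_id, active_id[bj], lj)
    dnew <- 0.5 * (Dc[bi, ] + Dc[bj, ] - dij)
    keep <- setdiff(seq_len(m), c(bi, bj))
    Dc <- rbind(cbind(Dc[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    active_id <- c(active_id[keep], new_id)
  }

  # join the last three nodes at a trifurcating root
  root <- next_internal
  stopifnot(root == n + 1L)
  d12 <- Dc[1, 2]; d13 <- Dc[1, 3]; d23 <- Dc[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  add_edge(root, active_id[1], l1)
  add_edge(root, active_id[2], l2)
  add_edge(root, active_id[3], l3)

  tree <- list(edge = edges, edge.length = lens, tip.label = labels,
               Nnode = n_internal)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

#' Principal coordinates analysis
#'
#' Classic metric multidimensional scaling: Gower double-centering of
#' `-0.5 * D^2`, eigendecomposition, coordinates scaled by the square roots
#' of the positive eigenvalues.  Variance proportions are computed over the
#' positive eigenvalues only; negative eigenvalues (non-Euclidean
#' distances) are reported separately.
#'
#' @param D symmetric distance matrix.
#' @param n_axes number of axes to return (default 2; truncated with a
#'   warning if fewer positive eigenvalues exist).
#' @return Object of class `pcoa_result`: `coordinates` (samples x axes,
#'   centred), `eigenvalues` (all, descending), `prop_variance` (per
#'   returned axis), `negative_eigenvalues`.
#' @export
pcoa <- function(D, n_axes = 2) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")
  A <- -0.5 * D^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12 & e$values > 0
  npos <- sum(pos)
  if (n_axes > npos) {
    warning("only ", npos, " positive eigenvalue(s); returning that many axes")
    n_axes <- npos
  }
  lam <- e$values[pos][seq_len(n_axes)]
  coords <- e$vectors[, which(pos)[seq_len(n_axes)], drop = FALSE] %*%
    diag(sqrt(lam), n_axes)
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("Axis", seq_len(n_axes))
  out <- list(coordinates = coords,
              eigenvalues = e$values,
              prop_variance = lam / sum(e$values[pos]),
              negative_eigenvalues = e$values[e$values < 0])
  class(out) <- "pcoa_result"
  out
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d axes returned\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("  % variance:",
      paste(sprintf("%.1f", 100 * x$prop_variance), collapse = ", "), "\n")
  if (length(x$negative_eigenvalues))
    cat("  ", length(x$negative_eigenvalues),
        "negative eigenvalue(s) (non-Euclidean input)\n")
  invisible(x)
}
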