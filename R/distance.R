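#' Proportion-of-shared-alleles distance between two frequency profiles
#'
#' For populations i and j, `d = 1 - (1/L') * sum_l sum_a min(p_i(l,a),
#' p_j(l,a))` over the `L'` loci unmasked in both populations (pairwise
#' deletion of missing loci). Identical profiles give 0; fully disjoint
#' allele sets give 1.
#'
#' @param p_i,p_j named lists locus -> named numeric allele frequencies.
#' @param loci character vector of locus names to consider.
#' @return Distance in `[0, 1]`.
#' @export
psa_distance <- function(p_i, p_j, loci = union(names(p_i), names(p_j))) {
  shared <- intersect(intersect(loci, names(p_i)), names(p_j))
  if (length(shared) == 0L) stop("no shared unmasked loci")
  s <- 0
  for (l in shared) {
    a <- p_i[[l]]; b <- p_j[[l]]
    common <- intersect(names(a), names(b))
    if (length(common)) s <- s + sum(pmin(a[common], b[common]))
  }
  1 - s / length(shared)
}

#' All pairwise shared-allele distances
#'
#' @param ft a [freq_table()] with at least two populations.
#' @return Symmetric matrix with population dimnames and zero diagonal;
#'   attributes `max_pair` / `min_pair` name the off-diagonal argmax/argmin
#'   pairs (with ties resolved to the first in row-major order) and
#'   `max_value` / `min_value` their distances.
#' @export
distance_matrix <- function(ft) {
  stopifnot(inherits(ft, "freq_table"), length(ft$pops) >= 2L)
  pops <- ft$pops
  n <- length(pops)
  d <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1L)) {
    pi_ <- ft$freqs[[pops[i]]]
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- psa_distance(pi_, ft$freqs[[pops[j]]], ft$loci)
    }
  }
  off <- d; diag(off) <- NA
  wmax <- which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  wmin <- which(off == min(off, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  attr(d, "max_pair") <- pops[wmax]; attr(d, "max_value") <- max(off, na.rm = TRUE)
  attr(d, "min_pair") <- pops[wmin]; attr(d, "min_value") <- min(off, na.rm = TRUE)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration using the Q-criterion
#' `Q(i,j) = (n-2) d(i,j) - R_i - R_j` with `R_i = sum_k d(i,k)`. Ties in the
#' criterion are broken by the lexicographically smallest index pair in the
#' current matrix order. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling branch of the join, preserving the
#' joined pair's distance.
#'
#' @param d symmetric distance matrix (n >= 3) with labels.
#' @return An unrooted [ape::phylo] tree over the input labels.
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n0 <- nrow(d)
  if (n0 < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n0))
  # node newick fragments, grown as we agglomerate
  frag <- labels
  D <- d
  while (nrow(D) > 3L) {
    n <- nrow(D)
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    # smallest Q; ties -> lexicographically smallest (i, j), i < j
    best <- Inf; bi <- 1L; bj <- 2L
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (Q[i, j] < best - 1e-12) { best <- Q[i, j]; bi <- i; bj <- j }
    }
    li <- 0.5 * D[bi, bj] + (R[bi] - R[bj]) / (2 * (n - 2))
    lj <- D[bi, bj] - li
    # clamp negatives, moving the deficit onto the sibling branch
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%.12g,%s:%.12g)", frag[bi], li, frag[bj], lj)
    dnew <- 0.5 * (D[bi, -c(bi, bj)] + D[bj, -c(bi, bj)] - D[bi, bj])
    keep <- setdiff(seq_len(n), c(bi, bj))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew),
                c(dnew, 0))
    frag <- c(frag[keep], newfrag)
    D <- D2
    rownames(D) <- colnames(D) <- NULL
  }
  # final 3-star: closed-form branch lengths
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ls <- pmax(c(l1, l2, l3), 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[1], ls[1], frag[2], ls[2], frag[3], ls[3])
  tree <- ape::read.tree(text = nwk)
  tree
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric MDS: Gower double-centering `B = -1/2 J D^2 J` (J the
#' centering projector), symmetric eigendecomposition, and coordinates
#' `v_k * sqrt(lambda_k)` for the positive eigenvalues only. Negative
#' eigenvalues (non-Euclidean input) are reported but their axes excluded;
#' variance explained uses the sum of positive eigenvalues as denominator.
#' An optional Lingoes correction (adding a constant to squared off-diagonal
#' dissimilarities) can be applied when negative eigenvalues are large.
#'
#' @param d symmetric distance matrix (n >= 3).
#' @param n_axes number of axes to return (default: all positive).
#' @param lingoes apply the Lingoes additive correction (default `FALSE`).
#' @return List of class `pcoa_ordination`: `coordinates` (centered, columns
#'   ordered by eigenvalue), `eigenvalues` (all, descending),
#'   `variance_explained` (positive axes), `negative_eigenvalues`.
#' @export
pcoa_analysis <- function(d, n_axes = NULL, lingoes = FALSE) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 3L)
  n <- nrow(d)
  d2 <- d^2
  if (lingoes) {
    e0 <- eigen(gower_center(d2), symmetric = TRUE, only.values = TRUE)$values
    c_add <- max(0, -min(e0))
    if (c_add > 0) {
      d2 <- (sqrt(d2) + sqrt(2 * c_add))^2
      diag(d2) <- 0
    }
  }
  B <- gower_center(d2)
  eig <- eigen(B, symmetric = TRUE)
  vals <- eig$values
  pos <- which(vals > max(vals) * 1e-12 & vals > 0)
  if (length(pos) == 0L) stop("degenerate input: no positive eigenvalues")
  if (is.null(n_axes)) n_axes <- length(pos)
  use <- pos[seq_len(min(n_axes, length(pos)))]
  coords <- sweep(eig$vectors[, use, drop = FALSE], 2L, sqrt(vals[use]), `*`)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_along(use))
  structure(list(coordinates = coords,
                 eigenvalues = vals,
                 variance_explained = vals[pos] / sum(vals[pos]),
                 negative_eigenvalues = vals[vals < 0]),
            class = "pcoa_ordination")
}

gower_center <- function(d2) {
  n <- nrow(d2)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% d2 %*% J
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "points,", ncol(x$coordinates),
      "positive axes\n")
  ve <- x$variance_explained
  cat("variance explained (first axes):",
      paste0(sprintf("%.1f%%", 100 * utils::head(ve, 4)), collapse = ", "), "\n")
  if (length(x$negative_eigenvalues))
    cat(length(x$negative_eigenvalues), "negative eigenvalue(s); most negative ",
        signif(min(x$negative_eigenvalues), 3), "\n")
  invisible(x)
}
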