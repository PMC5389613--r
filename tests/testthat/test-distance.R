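test_that("shared-allele distance matches the min-frequency formula", {
  p1 <- list(L1 = c(A = 0.3, B = 0.7))
  p2 <- list(L1 = c(A = 0.6, B = 0.4))
  expect_equal(psa_distance(p1, p2), 1 - (0.3 + 0.4))
  expect_equal(psa_distance(p1, p1), 0)
  disj <- list(L1 = c(C = 1))
  expect_equal(psa_distance(p1, disj), 1)
  expect_error(psa_distance(list(L1 = c(A = 1)), list(L2 = c(A = 1))),
               "no shared")
})

test_that("psa distance averages over shared loci only (pairwise deletion)", {
  p1 <- list(L1 = c(A = 1), L2 = c(A = 0.5, B = 0.5))
  p2 <- list(L1 = c(A = 1))  # L2 missing
  expect_equal(psa_distance(p1, p2), 0)
})

test_that("distance matrix is a symmetric semimetric with consistent extremes", {
  ds <- generate_dataset(generator_config(n_populations = 8, n_loci = 10,
                                          seed = 2))
  d <- distance_matrix(ds$freqs)
  expect_equal(d, t(d), ignore_attr = TRUE)
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  off <- d; diag(off) <- NA
  expect_equal(attr(d, "max_value"), max(off, na.rm = TRUE))
  expect_equal(attr(d, "min_value"), min(off, na.rm = TRUE))
  expect_equal(unname(d[attr(d, "max_pair")[1], attr(d, "max_pair")[2]]),
               attr(d, "max_value"))
  # permuting populations permutes rows/columns consistently
  perm <- rev(ds$freqs$pops)
  ft_perm <- freq_table(ds$freqs$freqs[perm], locus_defs = ds$locus_defs)
  d2 <- distance_matrix(ft_perm)
  expect_equal(unclass(d2), unclass(d)[perm, perm], ignore_attr = TRUE)
})

test_that("three-taxon NJ solves the closed-form star lengths", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  # l_a = (5 + 9 - 10)/2 = 2, l_b = 3, l_c = 7
  m <- ape::cophenetic.phylo(tr)
  expect_equal(m[rownames(d), colnames(d)], d, tolerance = 1e-9,
               ignore_attr = TRUE)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                   tr$tip.label)
  expect_equal(lens[c("a", "b", "c")], c(a = 2, b = 3, c = 7))
})

test_that("NJ recovers additive trees exactly (4 and 5 taxa)", {
  set.seed(77)
  for (n in c(4, 5)) {
    for (rep in 1:10) {
      ref <- ape::rtree(n, rooted = FALSE,
                        br = function(k) runif(k, 0.05, 1))
      dref <- ape::cophenetic.phylo(ref)
      tr <- neighbor_joining(dref)
      # same topology (RF distance 0) and identical path lengths
      expect_equal(ape::dist.topo(ape::unroot(ref), tr), 0, ignore_attr = TRUE)
      expect_equal(ape::cophenetic.phylo(tr)[rownames(dref), colnames(dref)],
                   dref, tolerance = 1e-9)
    }
  }
})

test_that("NJ agrees with an independent implementation on random matrices", {
  set.seed(123)
  for (rep in 1:5) {
    n <- 8
    x <- matrix(runif(n * 2), n)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    ours <- neighbor_joining(d)
    theirs <- ape::nj(d)
    expect_equal(ape::dist.topo(ours, ape::unroot(theirs)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("near-additive 5-taxon NJ is least-squares optimal over topologies", {
  # brute-force oracle: all 15 unrooted 5-leaf topologies, ordinary
  # least-squares branch fit on the 10 pairwise path equations
  ls_fit_sse <- function(d, cherry1, cherry2) {
    taxa <- rownames(d)
    mid <- setdiff(taxa, c(cherry1, cherry2))
    # edges: 5 pendant + 2 internal (cherry1|rest, cherry2|rest)
    pairs <- t(combn(taxa, 2))
    X <- matrix(0, nrow(pairs), 7,
                dimnames = list(NULL, c(taxa, "int1", "int2")))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      X[r, i] <- 1; X[r, j] <- 1
      n1 <- sum(c(i, j) %in% cherry1)
      n2 <- sum(c(i, j) %in% cherry2)
      if (n1 == 1) X[r, "int1"] <- 1
      if (n2 == 1) X[r, "int2"] <- 1
    }
    y <- d[pairs]
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }
  set.seed(55)
  for (rep in 1:5) {
    ref <- ape::rtree(5, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(ref)
    d <- d + matrix(rnorm(25, 0, 0.01), 5); d <- (d + t(d)) / 2; diag(d) <- 0
    d <- pmax(d, 0)
    tr <- neighbor_joining(d)
    taxa <- rownames(d)
    # enumerate all {cherry1, cherry2} splits
    sses <- c()
    topos <- list()
    ch1s <- combn(taxa, 2, simplify = FALSE)
    for (c1 in ch1s) {
      rest <- setdiff(taxa, c1)
      for (c2 in combn(rest, 2, simplify = FALSE)) {
        key <- paste(sort(c(paste(sort(c1), collapse = ","),
                            paste(sort(c2), collapse = ","))), collapse = "|")
        if (key %in% names(sses)) next
        sses[key] <- ls_fit_sse(d, c1, c2)
      }
    }
    expect_equal(length(sses), 15L)
    # our tree's split pair
    splits <- ape::prop.part(tr)
    bip <- lapply(splits[lengths(splits) %in% c(2, 3)], function(s)
      attr(splits, "labels")[s])
    cherries <- lapply(bip, function(s) if (length(s) == 3)
      setdiff(taxa, s) else s)
    cherries <- unique(lapply(cherries, sort))
    cherries <- Filter(function(s) length(s) == 2, cherries)
    key_nj <- paste(sort(vapply(cherries, paste, "", collapse = ",")),
                    collapse = "|")
    expect_equal(unname(sses[key_nj]), min(sses), tolerance = 1e-9)
  }
})

test_that("PCoA reconstructs planted planar configurations", {
  set.seed(8)
  for (rep in 1:5) {
    x <- matrix(runif(8), 4, 2)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(paste0("p", 1:4), paste0("p", 1:4))
    ord <- pcoa_analysis(d)
    y <- ord$coordinates[, 1:2]
    # Procrustes: optimal rotation of centered configs
    xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
    sv <- svd(crossprod(xc, yc))
    rot <- sv$v %*% t(sv$u)
    expect_lt(max(abs(yc %*% rot - xc)), 1e-8)
    # full-space inter-point distances equal the input for Euclidean input
    expect_equal(as.matrix(dist(ord$coordinates)), d, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("PCoA centers coordinates, orders axes, bounds the rank", {
  ds <- generate_dataset(generator_config(n_populations = 7, n_loci = 8,
                                          seed = 3))
  d <- distance_matrix(ds$freqs)
  ord <- pcoa_analysis(unclass(d))
  expect_true(all(abs(colMeans(ord$coordinates)) < 1e-9))
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  expect_lte(ncol(ord$coordinates), nrow(d) - 1)
  expect_equal(sum(ord$variance_explained), 1, tolerance = 1e-12)
})

test_that("equidistant points give a regular simplex with equal eigenvalues", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  dimnames(d) <- list(paste0("p", 1:4), paste0("p", 1:4))
  ord <- pcoa_analysis(d)
  pos <- ord$eigenvalues[ord$eigenvalues > 1e-12]
  expect_equal(length(pos), 3L)
  expect_true(max(pos) - min(pos) < 1e-9)
})

test_that("PCoA agrees with an independent implementation", {
  ds <- generate_dataset(generator_config(n_populations = 6, n_loci = 8,
                                          seed = 14))
  d <- unclass(distance_matrix(ds$freqs))
  attributes(d)[c("max_pair", "min_pair", "max_value", "min_value")] <- NULL
  ours <- pcoa_analysis(d)
  ref <- ape::pcoa(as.dist(d))
  k <- min(ncol(ours$coordinates), ncol(ref$vectors))
  for (ax in seq_len(k)) {
    expect_equal(abs(ours$coordinates[, ax]), abs(ref$vectors[, ax]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})
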