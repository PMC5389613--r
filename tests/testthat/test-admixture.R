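small_geno <- function(seed = 1, n_pops = 5, n_loci = 5) {
  ds <- generate_dataset(generator_config(K_true = 2, n_populations = n_pops,
                                          n_loci = n_loci, seed = seed))
  ds$genotypes
}

test_that("K = 1 forces unit ancestry to exactly one", {
  geno <- small_geno()
  fit <- run_structure(geno, 1, admixture_params(burn_in = 200, reps = 200,
                                                 seed = 3))
  expect_true(all(fit$Q == 1))
  expect_true(all(fit$Qbar == 1))
})

test_that("a single monomorphic locus gives a constant log-likelihood", {
  geno <- data.frame(population = rep(c("a", "b"), each = 10),
                     individual = rep(1:10, 2), locus = "L1",
                     allele1 = 100, allele2 = 100)
  fit <- run_structure(geno, 2, admixture_params(burn_in = 100, reps = 500,
                                                 ll_every = 1, seed = 5))
  expect_lt(max(fit$loglik) - min(fit$loglik), 1e-9)
  expect_lt(max(abs(fit$loglik)), 1e-9)  # single allele: likelihood is 1
})

test_that("identical seeds reproduce Q bit-identically, new seeds do not", {
  geno <- small_geno()
  p <- admixture_params(burn_in = 300, reps = 300)
  f1 <- run_structure(geno, 2, p, seed = 11)
  f2 <- run_structure(geno, 2, p, seed = 11)
  f3 <- run_structure(geno, 2, p, seed = 12)
  expect_identical(f1$Q, f2$Q)
  expect_false(identical(f1$Q, f3$Q))
})

test_that("Q rows and P simplexes stay normalized", {
  geno <- small_geno(seed = 4)
  fit <- run_structure(geno, 3, admixture_params(burn_in = 200, reps = 500,
                                                 seed = 2))
  expect_true(all(abs(rowSums(fit$Q) - 1) < 1e-6))
  for (pl in fit$P) expect_true(all(abs(rowSums(pl) - 1) < 1e-6))
  expect_true(all(is.finite(fit$loglik)))
})

test_that("frozen-state cluster assignment matches the analytic conditional", {
  # the sampler's categorical draw for one allele copy, with P and Q frozen,
  # must follow prob(k) proportional to q_k p_k (chi-squared check at 1e5)
  q <- c(0.2, 0.5, 0.3)
  p <- c(0.9, 0.05, 0.4)
  n <- 1e5
  counts <- bulkpop:::sample_z_conditional_cpp(q, p, n, 991)
  w <- q * p / sum(q * p)
  expect_gt(chisq.test(counts, p = w)$p.value, 0.01)
})

test_that("K = 1 log-evidence matches the closed-form Dirichlet expectation", {
  # with every copy in one cluster, counts are fixed, so post-burn-in
  # log-likelihood draws are iid with analytically known mean and variance:
  # E log p_a = digamma(lambda + c_a) - digamma(sum), and the log-likelihood
  # is sum_l sum_a c_a log p_la under the Dirichlet posterior
  geno <- small_geno(seed = 8, n_pops = 4, n_loci = 4)
  fit <- run_structure(geno, 1, admixture_params(burn_in = 500, reps = 20000,
                                                 ll_every = 10, seed = 21))
  mu <- 0; v <- 0
  for (l in unique(geno$locus)) {
    g <- geno[geno$locus == l, ]
    cnt <- table(c(g$allele1, g$allele2))
    cnt <- as.numeric(cnt)
    a <- 1 + cnt                       # lambda = 1
    a0 <- sum(a)
    mu <- mu + sum(cnt * (digamma(a) - digamma(a0)))
    v <- v + sum(cnt^2 * trigamma(a)) - sum(cnt)^2 * trigamma(a0)
  }
  analytic <- mu - v / 2
  nsamp <- length(fit$loglik)
  tol <- 5 * (sqrt(v / nsamp) + v * sqrt(2 / nsamp) / 2)
  expect_lt(abs(fit$LnPD - analytic), tol)
})

test_that("align_runs inverts known label permutations", {
  set.seed(6)
  mkres <- function(Q, perm = seq_len(ncol(Q))) {
    structure(list(Q = Q[, perm], Qbar = Q[, perm],
                   P = list(L1 = matrix(1 / 3, ncol(Q), 3)[perm, , drop = FALSE]),
                   K = ncol(Q)),
              class = "admixture_result")
  }
  Q <- matrix(rgamma(40 * 3, 0.3), 40)
  Q <- Q / rowSums(Q)
  colnames(Q) <- paste0("K", 1:3)
  rownames(Q) <- paste0("u", 1:40)
  # permuted copy of itself realigns exactly
  out <- align_runs(list(mkres(Q), mkres(Q, c(3, 1, 2)), mkres(Q, c(2, 3, 1))))
  expect_equal(out[[2]]$Q, Q, ignore_attr = TRUE)
  expect_equal(out[[3]]$Q, Q, ignore_attr = TRUE)
  # K = 2 swap
  Q2 <- Q[, 1:2] / rowSums(Q[, 1:2])
  colnames(Q2) <- c("K1", "K2")
  out2 <- align_runs(list(mkres(Q2), mkres(Q2, 2:1)))
  expect_equal(out2[[2]]$Q, Q2, ignore_attr = TRUE)
})

test_that("delta-K reproduces hand-computed second differences", {
  means <- c(-100, -80, -75, -74)
  x <- 1 / sqrt(2)
  lnpd <- rbind(means - x, means + x)       # sd exactly 1 at every K
  colnames(lnpd) <- 1:4
  dk <- evanno_delta_k(lnpd)
  expect_equal(dk$delta_k, c(NA, 15, 4, NA))
  expect_equal(attr(dk, "selected_k"), 2L)
  # linear mean curve: all defined delta-K are zero
  lin <- rbind(c(-90, -80, -70, -60) - x, c(-90, -80, -70, -60) + x)
  colnames(lin) <- 1:4
  expect_equal(evanno_delta_k(lin)$delta_k, c(NA, 0, 0, NA))
  # zero sd leaves delta-K undefined, not infinite
  z <- rbind(means, means)
  colnames(z) <- 1:4
  expect_true(all(is.na(evanno_delta_k(z)$delta_k)))
})

test_that("delta-K is never reported at the scan endpoints", {
  set.seed(9)
  lnpd <- matrix(rnorm(15, -100), 3, 5, dimnames = list(NULL, 2:6))
  dk <- evanno_delta_k(lnpd)
  expect_true(is.na(dk$delta_k[1]))
  expect_true(is.na(dk$delta_k[5]))
})

test_that("ancestry thresholds assign, flag weak, and default to mixed", {
  q <- rbind(c(0.30, 0.70), c(0.50, 0.50), c(0.05, 0.95))
  rownames(q) <- c("a", "b", "c"); colnames(q) <- c("G1", "G2")
  asg <- assign_groups(q)
  expect_equal(asg$group, c("G2", "mixed", "G2"))
  expect_equal(asg$weakly_assigned, c(TRUE, FALSE, FALSE))
  # a population whose largest ancestry is 50.6% falls below the 51% rule
  qvec <- c(S = 0.123, SMO = 0.260, rCH = 0.506, CV = 0.110)
  qvec <- qvec / sum(qvec)  # reported percentages sum to 99.9
  expect_equal(assign_groups(matrix(qvec, 1, dimnames = list("161", names(qvec))),
                             cutoff = 0.51)$group, "mixed")
  expect_error(assign_groups(rbind(c(0.5, 0.6))), "sum to 1")
})

test_that("admixture recovery on a small two-cluster problem", {
  ds <- generate_dataset(generator_config(K_true = 2, n_populations = 16,
                                          n_loci = 12, drift_F = 0.25,
                                          admix_alpha = 0.2, seed = 17))
  fit <- run_structure(ds$genotypes, 2,
                       admixture_params(burn_in = 1500, reps = 1500, seed = 5))
  qhat <- align_to_truth(fit$Qbar, ds$truth$Q)
  expect_lt(mean(abs(qhat - ds$truth$Q)), 0.1)
})

test_that("substructure namespaces sub-groups and partitions populations", {
  ds <- generate_dataset(generator_config(K_true = 2, n_populations = 12,
                                          n_loci = 8, drift_F = 0.3,
                                          admix_alpha = 0.1, seed = 23))
  fit <- run_structure(ds$genotypes, 2,
                       admixture_params(burn_in = 800, reps = 800, seed = 2))
  top <- assign_groups(fit$Qbar, labels = c("G1", "G2"))
  sub <- hierarchical_substructure(ds$genotypes, top, k_max = 3,
                                   admixture_params(burn_in = 400, reps = 400,
                                                    n_runs = 2, seed = 3))
  # every population lands in exactly one sub-level row
  expect_setequal(sub$assignment$population, top$population)
  expect_equal(anyDuplicated(sub$assignment$population), 0L)
  # labels are namespaced under their parent
  for (g in setdiff(unique(top$group), "mixed")) {
    pops_g <- top$population[top$group == g]
    labs <- sub$assignment$group[sub$assignment$population %in% pops_g]
    expect_true(all(startsWith(labs, g)))
  }
})

test_that("clusters with fewer than two populations are skipped with warning", {
  ds <- generate_dataset(generator_config(K_true = 2, n_populations = 6,
                                          n_loci = 6, seed = 31))
  top <- data.frame(population = ds$freqs$pops,
                    group = c("G1", rep("G2", 5)),
                    stringsAsFactors = FALSE)
  expect_warning(
    sub <- hierarchical_substructure(ds$genotypes, top, k_max = 2,
                                     admixture_params(burn_in = 200,
                                                      reps = 200, n_runs = 2,
                                                      seed = 4)),
    "fewer than 2")
  expect_setequal(sub$assignment$population, top$population)
})
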