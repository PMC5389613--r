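#' Simulation parameters for pseudo-individuals
#'
#' @param n_individuals diploid individuals simulated per population
#'   (default 15, the number of plants pooled per bulk).
#' @param seed integer RNG seed.
#' @param het_tolerance maximum allowed gap between realized and expected
#'   heterozygosity per locus before swap repair stops (default 0.05).
#' @param max_repair_iters maximum swap-repair iterations (default 1000).
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_individuals = 15L, seed = 1L, het_tolerance = 0.05,
                       max_repair_iters = 1000L) {
  stopifnot(n_individuals >= 1L)
  structure(list(n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed),
                 het_tolerance = het_tolerance,
                 max_repair_iters = as.integer(max_repair_iters)),
            class = "sim_params")
}

#' Apportion 2n allele copies to match frequencies
#'
#' Largest-remainder (Hamilton) apportionment of the `2n` allele copies of `n`
#' diploid individuals: each allele gets the floor of its quota `2n * p`, and
#' leftover copies go to the largest fractional remainders. Ties are broken by
#' larger quota, then by smaller allele size. Every allele with
#' `p >= 1/(2n)` receives at least one copy, and each count differs from its
#' quota by less than 1.
#'
#' @param freqs named numeric vector of allele frequencies (names: allele
#'   sizes), summing to 1.
#' @param n number of diploid individuals.
#' @return Named integer vector of copy counts summing to `2n`.
#' @export
allocate_allele_copies <- function(freqs, n) {
  stopifnot(abs(sum(freqs) - 1) < 1e-6, all(freqs >= 0))
  m <- 2L * as.integer(n)
  quota <- m * freqs
  cnt <- floor(quota + 1e-9)              # guard exact-integer quotas
  rem <- quota - cnt
  left <- m - sum(cnt)
  if (left > 0) {
    ord <- order(-rem, -quota, as.numeric(names(freqs)))
    cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1
  }
  out <- as.integer(cnt)
  names(out) <- names(freqs)
  out
}

#' Pair allele copies into diploid genotypes matching expected heterozygosity
#'
#' The `2n` copies are randomly shuffled and paired into `n` diploid
#' genotypes. If the realized heterozygosity (fraction of heterozygous pairs)
#' deviates from the Hardy-Weinberg expectation `1 - sum(p_hat^2)` — computed
#' from the realized (apportioned) frequencies `p_hat` — by more than
#' `het_tolerance`, single-allele swaps between a homozygote and a
#' heterozygote are applied until the tolerance is met or
#' `max_repair_iters` is exhausted. Swaps never alter the allele counts.
#'
#' @param copies named integer vector of allele copy counts (sum even).
#' @param params a [sim_params()]; the caller is responsible for seeding the
#'   RNG (this function draws from the current R RNG stream).
#' @return A 2-column matrix (`n` rows) of allele sizes, each row an unordered
#'   genotype (smaller allele first); attribute `het_achieved` records the
#'   realized heterozygosity and `het_warning` is `TRUE` when the tolerance
#'   could not be met.
#' @export
pair_into_genotypes <- function(copies, params = sim_params()) {
  m <- sum(copies)
  stopifnot(m %% 2L == 0L)
  n <- m %/% 2L
  p_hat <- copies / m
  h_exp <- 1 - sum(p_hat^2)
  pool <- rep(as.numeric(names(copies)), copies)
  pool <- sample(pool)
  g <- matrix(pool, ncol = 2L, byrow = TRUE)
  het <- function(g) mean(g[, 1] != g[, 2])
  # candidate count-preserving swaps:
  #   (a,a)+(b,b) -> (a,b)+(a,b)            het +2
  #   (a,a)+(b,c) -> (a,b)+(a,c), b,c != a  het +1
  #   (a,b)+(a,b) -> (a,a)+(b,b)            het -2
  #   (a,b)+(a,c) -> (a,a)+(b,c), b != c    het -1
  # a swap is applied only if it strictly reduces |het - expected|
  it <- 0L
  while (abs(het(g) - h_exp) > params$het_tolerance &&
         it < params$max_repair_iters) {
    it <- it + 1L
    dev <- abs(het(g) - h_exp)
    hom <- which(g[, 1] == g[, 2])
    hetr <- which(g[, 1] != g[, 2])
    moved <- FALSE
    if (het(g) < h_exp) {
      # raise: prefer breaking two unlike homozygotes, else hom x het
      if (length(hom) >= 2L && length(unique(g[hom, 1])) > 1L &&
          abs(het(g) + 2 / n - h_exp) < dev) {
        i <- hom[sample.int(length(hom), 1L)]
        unlike <- hom[g[hom, 1] != g[i, 1]]
        if (length(unlike) > 0) {
          j <- unlike[sample.int(length(unlike), 1L)]
          a <- g[i, 1]; b <- g[j, 1]
          g[i, ] <- sort(c(a, b)); g[j, ] <- sort(c(a, b))
          moved <- TRUE
        }
      }
      if (!moved && length(hom) > 0 && length(hetr) > 0 &&
          abs(het(g) + 1 / n - h_exp) < dev) {
        i <- hom[sample.int(length(hom), 1L)]
        a <- g[i, 1]
        cand <- hetr[g[hetr, 1] != a & g[hetr, 2] != a]
        if (length(cand) > 0) {
          j <- cand[sample.int(length(cand), 1L)]
          b <- g[j, 1]; c_ <- g[j, 2]
          g[i, ] <- sort(c(a, b)); g[j, ] <- sort(c(a, c_))
          moved <- TRUE
        }
      }
    } else if (length(hetr) >= 2L) {
      # lower: merge two heterozygotes sharing an allele
      js <- hetr[sample.int(length(hetr))]
      for (i in js) {
        share <- js[js != i]
        share <- share[vapply(share, function(j)
          any(g[j, ] %in% g[i, ]), logical(1))]
        if (length(share) == 0L) next
        j <- share[1L]
        same <- all(sort(g[i, ]) == sort(g[j, ]))
        step <- if (same) 2L else 1L
        if (abs(het(g) - step / n - h_exp) >= dev) next
        a <- intersect(g[i, ], g[j, ])[1L]
        b <- setdiff(g[i, ], a)[1L]
        c_ <- setdiff(g[j, ], a)[1L]
        if (same) { b <- g[i, ][g[i, ] != a][1L]; c_ <- b }
        g[i, ] <- c(a, a); g[j, ] <- sort(c(b, c_))
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  g <- t(apply(g, 1L, sort))
  attr(g, "het_achieved") <- het(g)
  attr(g, "het_warning") <- abs(het(g) - h_exp) > params$het_tolerance
  if (attr(g, "het_warning"))
    warning("heterozygosity tolerance not reached (achieved ",
            signif(het(g), 4), ", expected ", signif(h_exp, 4), ")")
  g
}

#' Simulate diploid pseudo-individuals from bulk frequencies
#'
#' For every population and locus of a frequency table, apportions allele
#' copies to the bulk frequencies ([allocate_allele_copies()]) and pairs them
#' into diploid genotypes whose heterozygosity matches Hardy-Weinberg
#' expectation ([pair_into_genotypes()]). Loci are simulated independently;
#' missing (population, locus) entries yield missing genotypes.
#'
#' @param freqs a [freq_table()].
#' @param params a [sim_params()]; `params$seed` seeds the whole simulation,
#'   so identical inputs and seed give identical output.
#' @return A `data.frame` of class `genotype_matrix` with columns
#'   `population`, `individual`, `locus`, `allele1`, `allele2`.
#' @export
simulate_individuals <- function(freqs, params = sim_params()) {
  stopifnot(inherits(freqs, "freq_table"))
  n <- params$n_individuals
  rows <- list()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(params$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (p in freqs$pops) {
    for (l in names(freqs$freqs[[p]])) {
      v <- freqs$freqs[[p]][[l]]
      copies <- allocate_allele_copies(v, n)
      g <- suppressWarnings(pair_into_genotypes(copies, params))
      rows[[length(rows) + 1L]] <- data.frame(
        population = p, individual = seq_len(n), locus = l,
        allele1 = g[, 1], allele2 = g[, 2], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("genotype_matrix", "data.frame")
  out
}

#' Recover allele frequencies from a genotype matrix
#'
#' The realized frequency of each allele is its copy count divided by `2n`
#' per (population, locus); used to verify apportionment round-trips and to
#' feed genotype-derived frequencies into diversity statistics.
#'
#' @param geno a `genotype_matrix` (columns `population`, `individual`,
#'   `locus`, `allele1`, `allele2`).
#' @param locus_defs optional [locus_defs()] carried into the result.
#' @return A [freq_table()].
#' @export
frequencies_from_genotypes <- function(geno, locus_defs = NULL) {
  freqs <- list()
  for (p in unique(geno$population)) {
    gp <- geno[geno$population == p, , drop = FALSE]
    freqs[[as.character(p)]] <- list()
    for (l in unique(gp$locus)) {
      gl <- gp[gp$locus == l, , drop = FALSE]
      alleles <- c(gl$allele1, gl$allele2)
      alleles <- alleles[!is.na(alleles)]
      if (length(alleles) == 0L) next
      tab <- table(alleles)
      v <- as.numeric(tab) / length(alleles)
      names(v) <- names(tab)
      freqs[[as.character(p)]][[l]] <- v
    }
  }
  freq_table(freqs, locus_defs = locus_defs)
}
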