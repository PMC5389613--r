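#' Synthetic-data generator configuration
#'
#' Emulates the shape of a bulked-SSR landrace survey: K ancestral clusters
#' differentiated by drift, admixed populations, 15-plant bulks, and
#' electropherogram peak tables contaminated with stutter and noise. Defaults
#' mirror the study design the package targets: 28 SSR loci with 2-21
#' alleles each, 15 individuals per bulk, moderate drift and mostly
#' single-ancestry populations.
#'
#' @param K_true number of ancestral clusters.
#' @param n_populations number of populations (bulks).
#' @param n_loci number of SSR loci (default 28).
#' @param alleles_min,alleles_max per-locus allele count range (default 2-21).
#' @param drift_F drift coefficient of the F-model in (0, 1); cluster
#'   frequencies are Dirichlet(`p_anc * (1 - F) / F`) around the ancestral
#'   frequencies, so larger F means stronger differentiation (default 0.2).
#' @param admix_alpha symmetric Dirichlet concentration of population
#'   ancestry vectors; small values give near-pure populations (default 0.2).
#' @param n_individuals plants per bulk (default 15).
#' @param stutter_rate typical stutter-to-parent height ratio; each rendered
#'   peak spawns a stutter peak one repeat unit below with ratio drawn from
#'   `Uniform(0.05, 1.5 * stutter_rate)` (default 0.12).
#' @param noise_peak_rate probability of adding a spurious noise peak per
#'   (bulk, locus) (default 0.02).
#' @param height_jitter lognormal sd of multiplicative peak-height jitter
#'   (default 0.05); 0 disables jitter.
#' @param seed integer seed; the full dataset is reproducible from
#'   (config, seed).
#' @return List of class `generator_config`.
#' @export
generator_config <- function(K_true = 3L, n_populations = 60L, n_loci = 28L,
                             alleles_min = 2L, alleles_max = 21L,
                             drift_F = 0.2, admix_alpha = 0.2,
                             n_individuals = 15L, stutter_rate = 0.12,
                             noise_peak_rate = 0.02, height_jitter = 0.05,
                             seed = 1L) {
  stopifnot(K_true >= 1L, n_populations >= 1L, n_loci >= 1L,
            alleles_min >= 2L, alleles_max >= alleles_min,
            drift_F > 0, drift_F < 1, admix_alpha > 0,
            n_individuals >= 1L, stutter_rate >= 0, stutter_rate <= 1,
            noise_peak_rate >= 0, noise_peak_rate <= 1)
  structure(list(K_true = as.integer(K_true),
                 n_populations = as.integer(n_populations),
                 n_loci = as.integer(n_loci),
                 alleles_min = as.integer(alleles_min),
                 alleles_max = as.integer(alleles_max),
                 drift_F = drift_F, admix_alpha = admix_alpha,
                 n_individuals = as.integer(n_individuals),
                 stutter_rate = stutter_rate,
                 noise_peak_rate = noise_peak_rate,
                 height_jitter = height_jitter, seed = as.integer(seed)),
            class = "generator_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Draw cluster allele frequencies under the F-model
#'
#' Per locus, ancestral frequencies are a symmetric Dirichlet(1) draw over
#' that locus's alleles; each cluster's frequencies are then
#' `Dirichlet(p_anc * (1 - F) / F)`, the standard drift model of the
#' admixture literature. Locus definitions (repeat units 2/3/4/6 cycling,
#' allele ladders starting at staggered offsets) are generated alongside.
#'
#' @param config a [generator_config()].
#' @return List: `locus_defs` (a [locus_defs()] table), `ancestral` (list
#'   locus -> named frequency vector), `clusters` (list cluster -> list locus
#'   -> named frequency vector).
#' @export
generate_cluster_frequencies <- function(config) {
  set.seed(config$seed)
  units <- rep(c(2L, 3L, 4L, 6L), length.out = config$n_loci)
  a_range <- config$alleles_min:config$alleles_max
  n_all <- a_range[sample.int(length(a_range), config$n_loci, replace = TRUE)]
  size_min <- 80L + (seq_len(config$n_loci) - 1L) * 5L
  size_max <- size_min + units * (n_all - 1L)
  # widen single-step ranges so size_min < size_max always holds
  ld <- locus_defs(sprintf("ssr%02d", seq_len(config$n_loci)),
                   repeat_unit = units, size_min = size_min,
                   size_max = pmax(size_max, size_min + units))
  anc <- clusters <- list()
  for (i in seq_len(config$n_loci)) {
    alleles <- as.character(seq.int(size_min[i], by = units[i],
                                    length.out = n_all[i]))
    p <- rdirichlet1(rep(1, n_all[i]))
    names(p) <- alleles
    anc[[ld$name[i]]] <- p
  }
  conc <- (1 - config$drift_F) / config$drift_F
  for (k in seq_len(config$K_true)) {
    ck <- list()
    for (l in names(anc)) {
      p <- rdirichlet1(anc[[l]] * conc)
      names(p) <- names(anc[[l]])
      ck[[l]] <- p
    }
    clusters[[paste0("C", k)]] <- ck
  }
  list(locus_defs = ld, ancestral = anc, clusters = clusters)
}

#' Simulate admixed population bulks from cluster frequencies
#'
#' Each population draws an ancestry vector `Q ~ Dirichlet(admix_alpha)` over
#' the clusters; each of its individuals draws two allele copies per locus
#' from the Q-mixture of cluster frequencies. Bulk frequencies are the
#' realized copy proportions (what an ideal intensity readout of the pooled
#' sample would measure).
#'
#' @param cluster_freqs output of [generate_cluster_frequencies()].
#' @param config a [generator_config()].
#' @return List: `genotypes` (a `genotype_matrix`), `freqs` (realized bulk
#'   [freq_table()]), `truth` (list with `Q` matrix populations x K and the
#'   generator inputs).
#' @export
generate_population_bulks <- function(cluster_freqs, config) {
  set.seed(config$seed + 1L)
  K <- config$K_true
  ld <- cluster_freqs$locus_defs
  pops <- sprintf("pop%03d", seq_len(config$n_populations))
  Qtrue <- matrix(NA_real_, config$n_populations, K,
                  dimnames = list(pops, names(cluster_freqs$clusters)))
  rows <- list(); freqs <- list()
  n <- config$n_individuals
  for (pi in seq_along(pops)) {
    q <- rdirichlet1(rep(config$admix_alpha, K))
    Qtrue[pi, ] <- q
    freqs[[pops[pi]]] <- list()
    for (l in ld$name) {
      pk <- vapply(cluster_freqs$clusters, function(ck) ck[[l]],
                   numeric(length(cluster_freqs$ancestral[[l]])))
      # per-copy cluster origin, then allele within cluster
      orig <- sample.int(K, 2L * n, replace = TRUE, prob = q)
      alleles <- names(cluster_freqs$ancestral[[l]])
      a_idx <- vapply(orig, function(k)
        sample.int(length(alleles), 1L, prob = pk[, k]), integer(1))
      drawn <- as.numeric(alleles[a_idx])
      g <- matrix(drawn, ncol = 2L, byrow = TRUE)
      g <- t(apply(g, 1L, sort))
      rows[[length(rows) + 1L]] <- data.frame(
        population = pops[pi], individual = seq_len(n), locus = l,
        allele1 = g[, 1], allele2 = g[, 2], stringsAsFactors = FALSE)
      tab <- table(drawn)
      v <- as.numeric(tab) / (2 * n)
      names(v) <- names(tab)
      freqs[[pops[pi]]][[l]] <- v
    }
  }
  geno <- do.call(rbind, rows)
  rownames(geno) <- NULL
  class(geno) <- c("genotype_matrix", "data.frame")
  list(genotypes = geno,
       freqs = freq_table(freqs, locus_defs = ld),
       truth = list(Q = Qtrue, clusters = cluster_freqs$clusters,
                    ancestral = cluster_freqs$ancestral))
}

#' Render a frequency table as a stutter-contaminated peak table
#'
#' The inverse of the allele-calling stage: every allele becomes a peak with
#' height `frequency * 1e4` under multiplicative lognormal jitter; each peak
#' spawns a stutter peak one repeat unit below with height ratio
#' `Uniform(0.05, 1.5 * stutter_rate)`; spurious off-ladder noise peaks are
#' added at rate `noise_peak_rate` per (bulk, locus). A registry records
#' which rows are artifacts so filtering can be scored against ground truth.
#'
#' @param ft a [freq_table()].
#' @param locus_defs the matching [locus_defs()] table.
#' @param config a [generator_config()]; set `stutter_rate = 0`,
#'   `noise_peak_rate = 0`, `height_jitter = 0` for a clean, exactly
#'   invertible rendering.
#' @return List: `peaks` (a `peak_table`), `registry` (`data.frame` flagging
#'   each row as `allele`, `stutter` or `noise`).
#' @export
render_peak_table <- function(ft, locus_defs, config) {
  set.seed(config$seed + 2L)
  rows <- list(); kind <- character(0)
  scale <- 1e4
  for (p in ft$pops) {
    for (l in names(ft$freqs[[p]])) {
      ld <- get_locus(locus_defs, l)
      v <- ft$freqs[[p]][[l]]
      sizes <- as.numeric(names(v))
      jit <- if (config$height_jitter > 0)
        exp(stats::rnorm(length(v), 0, config$height_jitter)) else 1
      h <- as.numeric(v) * scale * jit
      keep <- h > 0
      rows[[length(rows) + 1L]] <- data.frame(
        bulk_id = p, locus = l, size_bp = sizes[keep], height = h[keep],
        quality = 1, stringsAsFactors = FALSE)
      kind <- c(kind, rep("allele", sum(keep)))
      if (config$stutter_rate > 0) {
        ratio <- stats::runif(sum(keep), 0.05,
                              1.5 * config$stutter_rate)
        rows[[length(rows) + 1L]] <- data.frame(
          bulk_id = p, locus = l,
          size_bp = sizes[keep] - ld$repeat_unit,
          height = h[keep] * ratio, quality = 1, stringsAsFactors = FALSE)
        kind <- c(kind, rep("stutter", sum(keep)))
      }
      if (config$noise_peak_rate > 0 &&
          stats::runif(1) < config$noise_peak_rate) {
        # small spurious peak at a random position in the locus range
        pos <- stats::runif(1, ld$size_min, ld$size_max)
        rows[[length(rows) + 1L]] <- data.frame(
          bulk_id = p, locus = l, size_bp = pos,
          height = max(h) * stats::runif(1, 0.005, 0.04), quality = 0.2,
          stringsAsFactors = FALSE)
        kind <- c(kind, "noise")
      }
    }
  }
  pk <- do.call(rbind, rows)
  rownames(pk) <- NULL
  list(peaks = peak_table(pk),
       registry = data.frame(pk[, c("bulk_id", "locus", "size_bp")],
                             kind = kind, stringsAsFactors = FALSE))
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Convenience wrapper chaining [generate_cluster_frequencies()],
#' [generate_population_bulks()] and [render_peak_table()].
#'
#' @param config a [generator_config()].
#' @return List: `locus_defs`, `freqs`, `genotypes`, `peaks`, `registry`,
#'   `truth`.
#' @export
generate_dataset <- function(config = generator_config()) {
  cf <- generate_cluster_frequencies(config)
  bulks <- generate_population_bulks(cf, config)
  rendered <- render_peak_table(bulks$freqs, cf$locus_defs, config)
  list(locus_defs = cf$locus_defs, freqs = bulks$freqs,
       genotypes = bulks$genotypes, peaks = rendered$peaks,
       registry = rendered$registry, truth = bulks$truth)
}
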