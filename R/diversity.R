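#' Nei gene diversity at one locus
#'
#' Expected heterozygosity `H = 1 - sum(p^2)` for allele frequencies `p`.
#'
#' @param freqs named numeric vector of allele frequencies summing to 1.
#' @return A single value in `[0, 1 - 1/A]` for `A` alleles.
#' @export
gene_diversity <- function(freqs) {
  stopifnot(abs(sum(freqs) - 1) < 1e-6)
  1 - sum(freqs^2)
}

# unweighted mean allele frequencies across the populations of a group,
# per locus; populations missing the locus are skipped (pairwise deletion)
pool_group_frequencies <- function(pops, ft, pooled_counts = FALSE) {
  out <- list()
  for (l in ft$loci) {
    acc <- NULL
    npop <- 0L
    for (p in pops) {
      v <- ft$freqs[[p]][[l]]
      if (is.null(v)) next
      npop <- npop + 1L
      if (is.null(acc)) acc <- numeric(0)
      for (a in names(v)) acc[a] <- (if (a %in% names(acc)) acc[a] else 0) + v[[a]]
    }
    if (npop == 0L) next
    acc <- acc / npop
    out[[l]] <- acc[order(as.numeric(names(acc)))]
  }
  out
}

#' Diversity summary for a group of populations
#'
#' For each locus the allele frequencies are averaged across the group's
#' populations (unweighted mean over populations with data at that locus);
#' gene diversity is the mean over loci of `1 - sum(p_bar^2)`, and the allele
#' count is the number of distinct (locus, allele) pairs with pooled
#' frequency > 0. This is the per-cluster summary style of bulked SSR
#' diversity tables.
#'
#' @param pops character vector of population ids (non-empty).
#' @param ft a [freq_table()] containing them.
#' @param label group label carried into the output.
#' @return A one-row `data.frame`: `group`, `n_populations`, `n_alleles`,
#'   `mean_alleles_per_locus`, `gene_diversity`.
#' @export
group_diversity <- function(pops, ft, label = "group") {
  if (length(pops) == 0L) stop("empty group")
  miss <- setdiff(pops, ft$pops)
  if (length(miss)) stop("unknown populations: ", paste(miss, collapse = ", "))
  pooled <- pool_group_frequencies(pops, ft)
  if (length(pooled) == 0L) stop("group has no data at any locus")
  h <- mean(vapply(pooled, function(v) 1 - sum(v^2), numeric(1)))
  n_all <- vapply(pooled, function(v) sum(v > 0), integer(1))
  data.frame(group = label, n_populations = length(pops),
             n_alleles = sum(n_all),
             mean_alleles_per_locus = mean(n_all),
             gene_diversity = h, stringsAsFactors = FALSE)
}

#' Per-locus allele counts over a set of populations
#'
#' Number of distinct alleles with pooled frequency > 0 at each locus.
#'
#' @param ft a [freq_table()].
#' @param pops population ids (default: all).
#' @return Named integer vector, one entry per locus with data.
#' @export
allele_counts <- function(ft, pops = ft$pops) {
  pooled <- pool_group_frequencies(pops, ft)
  vapply(pooled, function(v) sum(v > 0), integer(1))
}

#' Count alleles unique to each group
#'
#' An allele is unique to a group iff its pooled frequency is > 0 in that
#' group and 0 in every other group of the comparison set. With
#' `level = "within-parent"`, groups are compared only against sibling groups
#' sharing the same parent cluster (supply `parent` as a named vector
#' group -> parent label).
#'
#' @param partition named list: group label -> character vector of population
#'   ids; groups must be disjoint.
#' @param ft a [freq_table()].
#' @param level `"between-groups"` (default) or `"within-parent"`.
#' @param parent named character vector mapping group label to parent label
#'   (required for `"within-parent"`).
#' @return Named integer vector of unique-allele counts per group.
#' @export
unique_alleles <- function(partition, ft,
                           level = c("between-groups", "within-parent"),
                           parent = NULL) {
  level <- match.arg(level)
  allpops <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(allpops)) stop("groups overlap")
  present <- lapply(partition, function(pops) {
    pooled <- pool_group_frequencies(pops, ft)
    keys <- character(0)
    for (l in names(pooled)) {
      v <- pooled[[l]]
      keys <- c(keys, paste(l, names(v)[v > 0], sep = "::"))
    }
    keys
  })
  groups <- names(partition)
  out <- integer(length(groups)); names(out) <- groups
  for (g in groups) {
    others <- if (level == "between-groups") setdiff(groups, g)
    else {
      if (is.null(parent)) stop("within-parent comparison needs `parent`")
      setdiff(groups[parent[groups] == parent[[g]]], g)
    }
    other_keys <- unique(unlist(present[others], use.names = FALSE))
    out[g] <- length(setdiff(present[[g]], other_keys))
  }
  out
}

#' Cluster-level diversity table
#'
#' Builds the per-group (and optionally per-sub-group) diversity summary for
#' a partition of populations: population counts, allele counts, unique
#' alleles between groups, and mean gene diversity, plus a `Total` row over
#' all populations. Populations assigned to no group form a `mixed` row when
#' present.
#'
#' @param assignment named character vector population -> group label (the
#'   label `"mixed"` is treated as its own group).
#' @param ft a [freq_table()].
#' @return A `data.frame`, one row per group plus a `Total` row (unique
#'   alleles are not defined for the total and are `NA` there).
#' @export
diversity_table <- function(assignment, ft) {
  groups <- setdiff(unique(assignment), NA)
  partition <- lapply(groups, function(g) names(assignment)[assignment == g])
  names(partition) <- groups
  uniq <- unique_alleles(partition, ft)
  rows <- lapply(groups, function(g) {
    r <- group_diversity(partition[[g]], ft, label = g)
    r$n_unique_alleles <- uniq[[g]]
    r
  })
  total <- group_diversity(names(assignment), ft, label = "Total")
  total$n_unique_alleles <- NA_integer_
  out <- do.call(rbind, c(rows, list(total)))
  out[, c("group", "n_populations", "n_alleles", "n_unique_alleles",
          "mean_alleles_per_locus", "gene_diversity")]
}
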