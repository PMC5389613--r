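#' Admixture model parameters
#'
#' Desk-scale defaults (20,000 burn-in, 20,000 recorded sweeps, 3 replicate
#' runs) suit synthetic verification; production analyses of real bulk data
#' use longer chains (hundreds of thousands to millions of sweeps and 5 runs)
#' by raising `burn_in`, `reps` and `n_runs`.
#'
#' @param burn_in discarded Gibbs sweeps (default 20000).
#' @param reps recorded sweeps after burn-in (default 20000).
#' @param n_runs replicate runs per K (default 3).
#' @param seed integer base seed; run r at value K uses a seed derived
#'   deterministically from (seed, K, r).
#' @param lambda Dirichlet prior parameter for cluster allele frequencies
#'   (default 1, uninformative).
#' @param alpha_init initial value of the ancestry concentration alpha.
#' @param alpha_proposal_sd random-walk Metropolis proposal sd for alpha.
#' @param alpha_max upper bound of alpha's uniform prior.
#' @param update_alpha set `FALSE` to keep alpha fixed at `alpha_init`.
#' @param ll_every record the log-likelihood every this many post-burn-in
#'   sweeps (default 10).
#' @param unit `"individual"` treats every pseudo-individual as a sampling
#'   unit and averages its Q vectors per population; `"population"` treats
#'   each population's pooled allele copies as one unit.
#' @return List of class `admixture_params`.
#' @export
admixture_params <- function(burn_in = 20000L, reps = 20000L, n_runs = 3L,
                             seed = 1L, lambda = 1, alpha_init = 1,
                             alpha_proposal_sd = 0.025, alpha_max = 10,
                             update_alpha = TRUE, ll_every = 10L,
                             unit = c("individual", "population")) {
  stopifnot(burn_in >= 0L, reps > 0L, n_runs >= 1L)
  structure(list(burn_in = as.integer(burn_in), reps = as.integer(reps),
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 lambda = lambda, alpha_init = alpha_init,
                 alpha_proposal_sd = alpha_proposal_sd, alpha_max = alpha_max,
                 update_alpha = update_alpha, ll_every = as.integer(ll_every),
                 unit = match.arg(unit)),
            class = "admixture_params")
}

# flatten a genotype_matrix into the copy-level arrays the sampler consumes
flatten_genotypes <- function(geno, unit = "individual") {
  loci <- sort(unique(geno$locus))
  allele_sets <- lapply(loci, function(l) {
    g <- geno[geno$locus == l, ]
    sort(unique(c(g$allele1, g$allele2)))
  })
  names(allele_sets) <- loci
  if (unit == "individual") {
    ukey <- paste(geno$population, geno$individual, sep = "\r")
  } else {
    ukey <- as.character(geno$population)
  }
  units <- unique(ukey)
  upop <- vapply(strsplit(units, "\r", fixed = TRUE), `[`, "", 1L)
  uidx <- match(ukey, units) - 1L
  lidx <- match(geno$locus, loci) - 1L
  a1 <- mapply(function(a, l) match(a, allele_sets[[l + 1L]]) - 1L,
               geno$allele1, lidx)
  a2 <- mapply(function(a, l) match(a, allele_sets[[l + 1L]]) - 1L,
               geno$allele2, lidx)
  keep1 <- !is.na(a1); keep2 <- !is.na(a2)
  list(unit = c(uidx[keep1], uidx[keep2]),
       locus = c(lidx[keep1], lidx[keep2]),
       allele = as.integer(c(a1[keep1], a2[keep2])),
       n_units = length(units), units = units, unit_pop = upop,
       loci = loci, allele_sets = allele_sets)
}

#' Fit the admixture model for one K by Gibbs sampling
#'
#' Each allele copy is assigned to one of K clusters; cluster allele
#' frequencies and unit ancestry vectors are Gibbs-updated in blocked sweeps
#' and the concentration parameter alpha by random-walk Metropolis. The model
#' log-evidence estimate is `LnPD = mean(loglik) - var(loglik) / 2` over the
#' recorded post-burn-in log-likelihoods.
#'
#' @param geno a `genotype_matrix` (see [simulate_individuals()]).
#' @param K number of clusters (>= 1).
#' @param params an [admixture_params()].
#' @param seed seed for this run (default `params$seed`).
#' @return List of class `admixture_result`: `Q` (unit-level ancestry
#'   posterior means), `Qbar` (population-level means), `P` (per-locus K x
#'   allele frequency posterior means), `loglik` (recorded trace), `LnPD`,
#'   `alpha` (posterior mean), `K`.
#' @export
run_structure <- function(geno, K, params = admixture_params(),
                          seed = params$seed) {
  fl <- flatten_genotypes(geno, params$unit)
  fit <- gibbs_admixture_cpp(fl$n_units, fl$unit, fl$locus, fl$allele,
                             lengths(fl$allele_sets), as.integer(K),
                             params$burn_in, params$reps, params$ll_every,
                             params$lambda, params$alpha_init,
                             params$alpha_proposal_sd, params$alpha_max,
                             params$update_alpha && K > 1, as.double(seed))
  if (!fit$loglik_finite) stop("non-finite log-likelihood during sampling")
  Q <- fit$Q
  rownames(Q) <- fl$units
  colnames(Q) <- paste0("K", seq_len(K))
  pops <- unique(fl$unit_pop)
  Qbar <- do.call(rbind, lapply(pops, function(p)
    colMeans(Q[fl$unit_pop == p, , drop = FALSE])))
  rownames(Qbar) <- pops
  P <- fit$P
  names(P) <- fl$loci
  for (l in fl$loci) colnames(P[[l]]) <- as.character(fl$allele_sets[[l]])
  ll <- fit$loglik
  structure(list(Q = Q, Qbar = Qbar, P = P, loglik = ll,
                 LnPD = mean(ll) - stats::var(ll) / 2,
                 alpha = mean(fit$alpha_trace),
                 alpha_accept_rate = fit$alpha_accept_rate,
                 K = as.integer(K), unit_pop = fl$unit_pop),
            class = "admixture_result")
}

#' @export
print.admixture_result <- function(x, ...) {
  cat("admixture fit: K =", x$K, ",", nrow(x$Q), "units,",
      length(x$P), "loci; LnPD =", signif(x$LnPD, 8),
      ", alpha =", signif(x$alpha, 4), "\n")
  invisible(x)
}

#' Align cluster labels across replicate runs
#'
#' MCMC cluster labels are arbitrary ("label switching"); the cluster columns
#' of runs 2..n are greedily matched to run 1 by maximal Q-column dot product
#' without replacement, and the permutation is applied to both Q and P.
#'
#' @param results list of `admixture_result` objects with identical K.
#' @return The list with columns of runs 2..n permuted to match run 1; the
#'   permutation used is attached to each result as attribute `perm`.
#' @export
align_runs <- function(results) {
  stopifnot(length(results) >= 1L)
  K <- results[[1L]]$K
  if (any(vapply(results, `[[`, 0L, "K") != K)) stop("runs must share K")
  ref <- results[[1L]]$Q
  attr(results[[1L]], "perm") <- seq_len(K)
  if (length(results) == 1L || K == 1L) return(results)
  for (r in 2:length(results)) {
    qr_ <- results[[r]]$Q
    score <- crossprod(ref, qr_)          # K x K dot products
    perm <- integer(K)
    for (step in seq_len(K)) {
      w <- arrayInd(which.max(score), dim(score))
      perm[w[1L]] <- w[2L]
      score[w[1L], ] <- -Inf; score[, w[2L]] <- -Inf
    }
    res <- results[[r]]
    res$Q <- res$Q[, perm, drop = FALSE]; colnames(res$Q) <- colnames(ref)
    res$Qbar <- res$Qbar[, perm, drop = FALSE]
    colnames(res$Qbar) <- colnames(results[[1L]]$Qbar)
    res$P <- lapply(res$P, function(pm) pm[perm, , drop = FALSE])
    attr(res, "perm") <- perm
    results[[r]] <- res
  }
  results
}

#' Scan K values with replicate runs
#'
#' Runs [run_structure()] `n_runs` times at every K in `k_range`, aligns
#' replicate runs, and collects the LnPD grid for Evanno delta-K model
#' selection.
#'
#' @param geno a `genotype_matrix`.
#' @param k_range integer vector of K values (e.g. `1:8`).
#' @param params an [admixture_params()].
#' @return List of class `structure_scan`: `runs` (nested list K -> aligned
#'   runs), `lnpd` (matrix runs x K), `delta_k` (from [evanno_delta_k()]),
#'   `selected_k`.
#' @export
k_scan <- function(geno, k_range, params = admixture_params()) {
  k_range <- sort(unique(as.integer(k_range)))
  runs <- list()
  lnpd <- matrix(NA_real_, params$n_runs, length(k_range),
                 dimnames = list(NULL, as.character(k_range)))
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    res <- lapply(seq_len(params$n_runs), function(r)
      run_structure(geno, K, params,
                    seed = (params$seed * 1000L + K * 100L + r) %% .Machine$integer.max))
    res <- align_runs(res)
    runs[[as.character(K)]] <- res
    lnpd[, i] <- vapply(res, `[[`, 0, "LnPD")
  }
  dk <- if (length(k_range) >= 3L) evanno_delta_k(lnpd) else NULL
  structure(list(runs = runs, lnpd = lnpd, delta_k = dk,
                 selected_k = if (!is.null(dk)) attr(dk, "selected_k") else NA_integer_,
                 k_range = k_range),
            class = "structure_scan")
}

#' Evanno delta-K table from an LnPD grid
#'
#' With mean log-evidence `L(K)` over replicate runs: `L'(K) = L(K) - L(K-1)`,
#' `|L''(K)| = |L'(K+1) - L'(K)|`, and `deltaK = |L''(K)| / sd(LnPD at K)`
#' where the sd is across replicate runs. Delta-K is defined only for
#' interior K values; a zero between-run sd leaves delta-K undefined (`NA`)
#' at that K rather than infinite. The argmax over defined values is the
#' suggested K; all local maxima are reported since real scans can show
#' several competing peaks.
#'
#' @param lnpd numeric matrix, runs x K, with K values as column names
#'   (consecutive).
#' @return A `data.frame` with columns `K`, `mean_lnpd`, `sd_lnpd`, `lprime`,
#'   `lsecond_abs`, `delta_k`; attributes `selected_k` (argmax) and
#'   `local_maxima`.
#' @export
evanno_delta_k <- function(lnpd) {
  stopifnot(is.matrix(lnpd), ncol(lnpd) >= 3L, nrow(lnpd) >= 1L)
  ks <- as.integer(colnames(lnpd))
  if (any(diff(ks) != 1L)) stop("K values must be consecutive")
  m <- colMeans(lnpd)
  s <- apply(lnpd, 2L, stats::sd)
  nk <- length(ks)
  lp <- c(NA, diff(m))                       # L'(K), defined for K >= min+1
  l2 <- rep(NA_real_, nk)
  l2[2:(nk - 1)] <- abs(lp[3:nk] - lp[2:(nk - 1)])
  dk <- rep(NA_real_, nk)
  interior <- 2:(nk - 1)
  ok <- interior[!is.na(s[interior]) & s[interior] > 0]
  dk[ok] <- l2[ok] / s[ok]
  out <- data.frame(K = ks, mean_lnpd = m, sd_lnpd = s, lprime = lp,
                    lsecond_abs = l2, delta_k = dk, row.names = NULL)
  sel <- if (all(is.na(dk))) NA_integer_ else ks[which.max(dk)]
  dkx <- ifelse(is.na(dk), -Inf, dk)
  lm_ <- ks[is.finite(dkx) & dkx >= c(-Inf, dkx[-nk]) & dkx >= c(dkx[-1], -Inf)]
  attr(out, "selected_k") <- sel
  attr(out, "local_maxima") <- lm_
  out
}

#' Assign populations to groups by ancestry threshold
#'
#' A population is assigned to its majority cluster when the maximum ancestry
#' proportion exceeds `cutoff` (default 51%), and to `"mixed"` otherwise.
#' Assigned populations whose maximum ancestry does not exceed
#' `strong_cutoff` (default 80%) are flagged as weakly assigned — present in
#' a group but not among its most representative members.
#'
#' @param qbar numeric matrix populations x K, rows summing to 1 (within
#'   1e-6), with population rownames.
#' @param cutoff assignment threshold (strictly greater-than; default 0.51).
#' @param strong_cutoff representativeness threshold (default 0.80).
#' @param labels optional cluster labels (default the Q column names).
#' @return A `data.frame` of class `group_assignment`: `population`, `group`
#'   (cluster label or `"mixed"`), `max_q`, `weakly_assigned`; the full
#'   ancestry matrix is attached as attribute `ancestry`.
#' @export
assign_groups <- function(qbar, cutoff = 0.51, strong_cutoff = 0.80,
                          labels = colnames(qbar)) {
  if (is.null(dim(qbar))) qbar <- matrix(qbar, nrow = 1,
                                         dimnames = list("pop1", names(qbar)))
  if (any(abs(rowSums(qbar) - 1) > 1e-6)) stop("ancestry rows must sum to 1")
  if (is.null(labels)) labels <- paste0("K", seq_len(ncol(qbar)))
  if (is.null(rownames(qbar))) rownames(qbar) <- paste0("pop", seq_len(nrow(qbar)))
  imax <- max.col(qbar, ties.method = "first")
  qmax <- qbar[cbind(seq_len(nrow(qbar)), imax)]
  grp <- ifelse(qmax > cutoff, labels[imax], "mixed")
  out <- data.frame(population = rownames(qbar), group = grp, max_q = qmax,
                    weakly_assigned = grp != "mixed" & qmax <= strong_cutoff,
                    stringsAsFactors = FALSE)
  attr(out, "ancestry") <- qbar
  class(out) <- c("group_assignment", "data.frame")
  out
}

#' Hierarchical sub-structure analysis
#'
#' For every non-mixed top-level cluster with at least two member
#' populations, the full K-scan, delta-K selection and threshold assignment
#' are rerun on that cluster's populations alone; sub-group labels are
#' namespaced under the parent (`"G1.g1"` style). Clusters with fewer than
#' two populations are skipped with a warning.
#'
#' @param geno a `genotype_matrix` covering all populations.
#' @param top_assignment a `group_assignment` from the top-level analysis.
#' @param k_max largest K scanned within each cluster (capped at the cluster's
#'   population count).
#' @param params an [admixture_params()].
#' @return List of class `substructure_result`: per-cluster entries each
#'   holding `scan` (the `structure_scan`), `selected_k` and `assignment`
#'   (with namespaced labels), plus `assignment` combining all sub-level
#'   assignments (populations of skipped or mixed clusters keep their parent
#'   label).
#' @export
hierarchical_substructure <- function(geno, top_assignment, k_max = 5L,
                                      params = admixture_params()) {
  clusters <- setdiff(unique(top_assignment$group), "mixed")
  out <- list()
  combined <- list()
  for (g in clusters) {
    pops <- top_assignment$population[top_assignment$group == g]
    if (length(pops) < 2L) {
      warning("cluster ", g, " has fewer than 2 populations; skipped")
      combined[[g]] <- data.frame(population = pops, group = g,
                                  stringsAsFactors = FALSE)
      next
    }
    sub <- geno[geno$population %in% pops, , drop = FALSE]
    kr <- 1:min(k_max, length(pops))
    scan <- k_scan(sub, kr, params)
    sel <- scan$selected_k
    if (is.na(sel)) sel <- 1L
    if (sel >= 2L) {
      best_run <- which.max(scan$lnpd[, as.character(sel)])
      qbar <- scan$runs[[as.character(sel)]][[best_run]]$Qbar
      asg <- assign_groups(qbar, labels = paste0(g, ".g", seq_len(sel)))
      asg$group[asg$group == "mixed"] <- paste0(g, ".mixed")
    } else {
      asg <- data.frame(population = pops, group = paste0(g, ".g1"),
                        max_q = 1, weakly_assigned = FALSE,
                        stringsAsFactors = FALSE)
    }
    out[[g]] <- list(scan = scan, selected_k = sel, assignment = asg)
    combined[[g]] <- asg[, c("population", "group")]
  }
  mixed_pops <- top_assignment$population[top_assignment$group == "mixed"]
  if (length(mixed_pops))
    combined[["mixed"]] <- data.frame(population = mixed_pops, group = "mixed",
                                      stringsAsFactors = FALSE)
  structure(list(clusters = out,
                 assignment = do.call(rbind, c(combined, list(make.row.names = FALSE)))),
            class = "substructure_result")
}
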