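# shared in-code fixtures: a two-locus panel and a tiny frequency table

panel2 <- function() {
  locus_defs(c("ssrA", "ssrB"), repeat_unit = c(2L, 3L),
             size_min = c(100L, 150L), size_max = c(160L, 189L))
}

tiny_ft <- function() {
  freq_table(list(
    p1 = list(ssrA = c(`100` = 0.3, `104` = 0.7),
              ssrB = c(`150` = 1.0)),
    p2 = list(ssrA = c(`100` = 0.6, `104` = 0.4),
              ssrB = c(`153` = 0.5, `156` = 0.5))
  ), locus_defs = panel2())
}

# greedy column alignment of an estimated Q matrix to a reference, returning
# the permuted estimate (independent of align_runs, for truth comparisons)
align_to_truth <- function(qhat, qtrue) {
  K <- ncol(qtrue)
  sc <- crossprod(qtrue, qhat[rownames(qtrue), , drop = FALSE])
  perm <- integer(K)
  for (s in seq_len(K)) {
    w <- arrayInd(which.max(sc), dim(sc))
    perm[w[1]] <- w[2]
    sc[w[1], ] <- -Inf; sc[, w[2]] <- -Inf
  }
  qhat[rownames(qtrue), perm, drop = FALSE]
}
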