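ldA <- function() locus_defs("ssrA", 2L, 100L, 120L)

pk <- function(sizes, heights, locus = "ssrA", bulk = "b1") {
  peak_table(data.frame(bulk_id = rep(bulk, length(sizes)),
                        locus = rep(locus, length(sizes)),
                        size_bp = sizes, height = heights))
}

test_that("binning snaps to the nearest rung, summing heights", {
  out <- bin_peaks(pk(c(100.1, 99.8), c(300, 200)), ldA())
  expect_equal(out$size_bp, 100)
  expect_equal(out$height, 500)
})

test_that("exact midpoints go to the lower rung (exhaustive grid check)", {
  # oracle: for every size on a 0.1-bp grid, the nearest rung, lower on ties
  ld <- ldA()
  rungs <- seq(100, 120, by = 2)
  for (s in seq(99.5, 120.5, by = 0.1)) {
    out <- bin_peaks(pk(s, 100), ld)
    dist <- abs(rungs - s)
    nearest <- rungs[dist == min(dist)]
    expect_equal(out$size_bp, min(nearest), info = paste("size", s))
  }
  expect_equal(bin_peaks(pk(101.0, 100), ld)$size_bp, 100)  # tie case
  expect_equal(bin_peaks(pk(103.7, 100), ld)$size_bp, 104)
})

test_that("off-ladder peaks beyond the tolerance are dropped and counted", {
  ld <- locus_defs("ssrC", 4L, 100L, 120L)
  p <- peak_table(data.frame(bulk_id = "b", locus = "ssrC",
                             size_bp = c(100.2, 102.0, 97.0),
                             height = c(100, 50, 60)))
  out <- bin_peaks(p, ld)  # tolerance = 2; 102.0 is 2 from both 100 and 104
  expect_equal(attr(out, "n_offladder"), 1L)  # 97.0 is 3 bp from rung 100
  expect_equal(out$size_bp, c(100))
  expect_equal(out$height, 150)  # 102 ties to lower rung 100 and merges
})

test_that("empty input passes through binning without error", {
  empty <- pk(numeric(0), numeric(0))
  expect_equal(nrow(bin_peaks(empty, ldA())), 0L)
  expect_equal(nrow(remove_stutter(empty, ldA())), 0L)
})

test_that("stutter one repeat below a parent is removed iff below the ratio", {
  # direct arithmetic: 150 < 0.2 * 1000 -> removed
  out <- remove_stutter(pk(c(104, 102), c(1000, 150)), ldA())
  expect_equal(out$size_bp, 104)
  # 450 >= 0.2 * 1000 -> both kept
  out2 <- remove_stutter(pk(c(104, 102), c(1000, 450)), ldA())
  expect_equal(out2$size_bp, c(102, 104))
  # single peak unchanged
  out3 <- remove_stutter(pk(110, 5), ldA())
  expect_equal(out3$size_bp, 110)
})

test_that("noise floor removes peaks below 5% of the tallest retained", {
  out <- remove_stutter(pk(c(100, 110, 116), c(30, 1000, 900)), ldA())
  expect_equal(out$size_bp, c(110, 116))  # 30 < 0.05 * 1000
})

test_that("stutter removal is idempotent and monotone in the ratio", {
  set.seed(31)
  ld <- ldA()
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    sizes <- sample(seq(100, 120, 2), n)
    p <- pk(sizes, runif(n, 10, 1000))
    once <- remove_stutter(p, ld)
    twice <- remove_stutter(once, ld)
    expect_equal(as.data.frame(twice), as.data.frame(once))
    # monotonicity: larger ratio never retains more peaks
    kept <- vapply(c(0, 0.1, 0.2, 0.5, 1),
                   function(r) nrow(remove_stutter(
                     p, ld, peak_filter_params(stutter_ratio = r))),
                   integer(1))
    expect_true(all(diff(kept) <= 0))
  }
})

test_that("frequencies are peak heights normalized to 1", {
  v <- estimate_bulk_frequencies(pk(c(100, 104), c(300, 700)))
  expect_equal(v, c(`100` = 0.3, `104` = 0.7))
  expect_equal(estimate_bulk_frequencies(pk(110, 12)), c(`110` = 1))
  v3 <- estimate_bulk_frequencies(pk(c(100, 102, 104), c(1, 1, 2)))
  expect_equal(unname(v3), c(0.25, 0.25, 0.5))
  expect_null(estimate_bulk_frequencies(pk(numeric(0), numeric(0))))
})

test_that("clean rendered peaks invert exactly back to the bulk frequencies", {
  cfg <- generator_config(K_true = 2, n_populations = 3, n_loci = 4,
                          stutter_rate = 0, noise_peak_rate = 0,
                          height_jitter = 0, seed = 5)
  ds <- generate_dataset(cfg)
  # with artifacts off, filtering is disabled too: the stutter heuristic
  # would otherwise delete genuine low-frequency alleles one repeat below a
  # tall neighbour, which is the designed behaviour on real data
  called <- call_allele_frequencies(ds$peaks, ds$locus_defs,
                                    peak_filter_params(stutter_ratio = 0,
                                                       noise_floor = 0))
  for (p in ds$freqs$pops) for (l in names(ds$freqs$freqs[[p]])) {
    expect_equal(called$freqs[[p]][[l]], ds$freqs$freqs[[p]][[l]],
                 tolerance = 1e-12)
  }
})

test_that("with stutter and noise on, recovered frequencies have MAE < 0.02", {
  cfg <- generator_config(K_true = 3, n_populations = 10, n_loci = 28,
                          seed = 7)  # defaults: stutter 0.12, noise 0.02
  ds <- generate_dataset(cfg)
  called <- call_allele_frequencies(ds$peaks, ds$locus_defs)
  errs <- c()
  for (p in ds$freqs$pops) for (l in names(ds$freqs$freqs[[p]])) {
    truth <- ds$freqs$freqs[[p]][[l]]
    est <- called$freqs[[p]][[l]]
    alle <- union(names(truth), names(est))
    tv <- ifelse(alle %in% names(truth), truth[alle], 0)
    ev <- ifelse(alle %in% names(est), est[alle], 0)
    errs <- c(errs, abs(tv - ev))
  }
  expect_lt(mean(errs), 0.02)
})

test_that("all frequencies from peak calling sum to one per (bulk, locus)", {
  ds <- generate_dataset(generator_config(n_populations = 5, n_loci = 6,
                                          seed = 9))
  called <- call_allele_frequencies(ds$peaks, ds$locus_defs)
  for (p in called$pops) for (l in names(called$freqs[[p]]))
    expect_equal(sum(called$freqs[[p]][[l]]), 1, tolerance = 1e-12)
})
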