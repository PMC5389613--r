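#' Peak filtering parameters
#'
#' Controls the conversion of raw bulk electropherogram peaks into allele
#' calls. `stutter_ratio` is the height ratio below which a peak one repeat
#' unit short of a taller neighbour is treated as PCR stutter; `noise_floor`
#' removes peaks below a fraction of the tallest retained peak at the locus;
#' `bin_tolerance` is the maximum distance (bp) from a ladder rung for a peak
#' to be binned (default half the repeat unit). Defaults follow common
#' fragment-analysis practice for di- to hexa-nucleotide SSRs.
#'
#' @param stutter_ratio real in \[0, 1\], default 0.2.
#' @param noise_floor real in \[0, 1\], default 0.05 (relative to the tallest
#'   retained peak at the locus).
#' @param bin_tolerance bp, or `NA` to use `repeat_unit / 2` per locus.
#' @param stutter_minus2 also remove second-order stutter two repeat units
#'   below a parent (off by default; minus-one stutter dominates for short
#'   repeat motifs).
#' @param size_reweight optional linear re-weighting of peak heights by
#'   fragment size to counter preferential amplification of shorter
#'   fragments; `0` (default) disables it. A value `b` multiplies each height
#'   by `1 + b * (size - size_min) / (size_max - size_min)`.
#' @return A list of class `peak_filter_params`.
#' @export
peak_filter_params <- function(stutter_ratio = 0.2, noise_floor = 0.05,
                               bin_tolerance = NA_real_,
                               stutter_minus2 = FALSE, size_reweight = 0) {
  stopifnot(stutter_ratio >= 0, stutter_ratio <= 1,
            noise_floor >= 0, noise_floor <= 1,
            is.na(bin_tolerance) || bin_tolerance > 0)
  structure(list(stutter_ratio = stutter_ratio, noise_floor = noise_floor,
                 bin_tolerance = bin_tolerance,
                 stutter_minus2 = stutter_minus2,
                 size_reweight = size_reweight),
            class = "peak_filter_params")
}

#' Snap peaks of one (bulk, locus) to the allele-size ladder
#'
#' Fragment sizes are snapped to the nearest rung of the integer ladder
#' `size_min + k * repeat_unit` (k >= 0, up to `size_max`); peaks snapping to
#' the same rung have their heights summed. A peak farther than
#' `bin_tolerance` from every rung is dropped (off-ladder artifact). A peak
#' exactly equidistant between two rungs is assigned to the lower rung.
#'
#' @param peaks a `peak_table` restricted to one (bulk, locus).
#' @param locus one row of a [locus_defs()] table.
#' @param params a [peak_filter_params()].
#' @return A `peak_table` with one row per occupied rung; empty input gives an
#'   empty table. The number of off-ladder peaks dropped is attached as
#'   attribute `n_offladder`.
#' @export
bin_peaks <- function(peaks, locus, params = peak_filter_params()) {
  stopifnot(nrow(locus) == 1L)
  tol <- if (is.na(params$bin_tolerance)) locus$repeat_unit / 2 else params$bin_tolerance
  if (nrow(peaks) == 0L) {
    out <- peaks
    attr(out, "n_offladder") <- 0L
    return(out)
  }
  rungs <- locus_ladder(locus)
  # nearest rung; exact midpoints go to the lower rung
  k <- (peaks$size_bp - locus$size_min) / locus$repeat_unit
  k_lo <- floor(k)
  frac <- k - k_lo
  k_near <- ifelse(frac > 0.5, k_lo + 1, k_lo)     # ties (frac == 0.5) -> lower
  k_near <- pmin(pmax(k_near, 0), length(rungs) - 1L)
  rung <- locus$size_min + k_near * locus$repeat_unit
  off <- abs(peaks$size_bp - rung) > tol + 1e-12
  n_off <- sum(off)
  kept <- peaks[!off, , drop = FALSE]
  rung <- rung[!off]
  if (nrow(kept) == 0L) {
    out <- kept
  } else {
    h <- tapply(kept$height, rung, sum)
    q <- tapply(kept$quality, rung, function(x) mean(x, na.rm = TRUE))
    out <- data.frame(bulk_id = kept$bulk_id[1], locus = kept$locus[1],
                      size_bp = as.numeric(names(h)), height = as.numeric(h),
                      quality = as.numeric(q), stringsAsFactors = FALSE)
    out <- out[order(out$size_bp), , drop = FALSE]
    out <- peak_table(out)
  }
  attr(out, "n_offladder") <- n_off
  out
}

#' Remove stutter and noise peaks at one (bulk, locus)
#'
#' Rungs are scanned from largest to smallest allele size; a peak one repeat
#' unit below a retained peak at size `a` is removed iff its height is below
#' `stutter_ratio * height(a)`. Optionally the same rule is applied two repeat
#' units below (`stutter_minus2`). Afterwards, peaks below `noise_floor`
#' times the tallest retained height are removed. The operation is
#' idempotent.
#'
#' @inheritParams bin_peaks
#' @param peaks binned peaks for one (bulk, locus), as from [bin_peaks()].
#' @return Filtered `peak_table`; if every peak is removed the result has zero
#'   rows and attribute `all_removed = TRUE` (the entry is to be treated as
#'   missing).
#' @export
remove_stutter <- function(peaks, locus, params = peak_filter_params()) {
  if (nrow(peaks) == 0L) return(peaks)
  o <- order(peaks$size_bp, decreasing = TRUE)
  sz <- peaks$size_bp[o]; h <- peaks$height[o]
  keep <- rep(TRUE, length(sz))
  for (i in seq_along(sz)) {
    if (!keep[i]) next
    for (step in c(1L, if (params$stutter_minus2) 2L)) {
      j <- which(keep & abs(sz - (sz[i] - step * locus$repeat_unit)) < 1e-9)
      if (length(j) == 1L && h[j] < params$stutter_ratio * h[i])
        keep[j] <- FALSE
    }
  }
  if (any(keep)) {
    floor_h <- params$noise_floor * max(h[keep])
    keep <- keep & h >= floor_h
  }
  out <- peaks[o[keep], , drop = FALSE]
  out <- out[order(out$size_bp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  attr(out, "all_removed") <- nrow(out) == 0L
  out
}

#' Allele frequencies from filtered peaks of one (bulk, locus)
#'
#' The frequency of each allele is its peak height divided by the summed
#' heights, so the result sums to exactly 1. With `size_reweight` non-zero,
#' heights are first multiplied by a linear ramp in fragment size to
#' compensate preferential amplification of short fragments.
#'
#' @inheritParams bin_peaks
#' @return Named numeric vector (allele size -> frequency), or `NULL` when no
#'   peaks remain.
#' @export
estimate_bulk_frequencies <- function(peaks, locus = NULL,
                                      params = peak_filter_params()) {
  if (nrow(peaks) == 0L) return(NULL)
  h <- peaks$height
  if (params$size_reweight != 0) {
    stopifnot(!is.null(locus))
    ramp <- 1 + params$size_reweight *
      (peaks$size_bp - locus$size_min) / (locus$size_max - locus$size_min)
    h <- h * ramp
  }
  v <- h / sum(h)
  names(v) <- as.character(peaks$size_bp)
  v
}

#' Bulk allele-frequency profiles from a raw peak table
#'
#' Runs the full pooled-sample allele-calling stage for every (bulk, locus):
#' ladder binning, stutter and noise removal, and height-proportional
#' frequency estimation. This reproduces the frequency-from-intensity step of
#' bulked SSR genotyping.
#'
#' @param peaks a `peak_table` (any number of bulks and loci).
#' @param locus_defs a [locus_defs()] table covering all loci present.
#' @param params a [peak_filter_params()].
#' @return A [freq_table()]; (bulk, locus) entries whose peaks were all
#'   filtered out are masked missing.
#' @export
call_allele_frequencies <- function(peaks, locus_defs,
                                    params = peak_filter_params()) {
  bulks <- unique(peaks$bulk_id)
  freqs <- list()
  for (b in bulks) {
    freqs[[as.character(b)]] <- list()
    pb <- peaks[peaks$bulk_id == b, , drop = FALSE]
    for (l in unique(pb$locus)) {
      ld <- get_locus(locus_defs, l)
      pl <- pb[pb$locus == l, , drop = FALSE]
      binned <- bin_peaks(pl, ld, params)
      filt <- remove_stutter(binned, ld, params)
      v <- estimate_bulk_frequencies(filt, ld, params)
      if (!is.null(v)) freqs[[as.character(b)]][[l]] <- v
    }
  }
  freq_table(freqs, locus_defs = locus_defs)
}
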