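#' Define a set of SSR loci
#'
#' Builds the locus metadata table used throughout the package: one row per
#' microsatellite locus with its genome location (informational), repeat unit
#' and expected allele size range in base pairs. Fragment sizes are binned to
#' the integer ladder `size_min + k * repeat_unit` within `[size_min,
#' size_max]`.
#'
#' @param name character vector of locus names (unique).
#' @param repeat_unit integer repeat unit length in bp (> 0); typically 2, 3,
#'   4 or 6 for SSRs but any positive integer is accepted.
#' @param size_min,size_max integer bounds of the allele size range in bp,
#'   with `size_min < size_max`.
#' @param genome_bin optional character vector giving chromosome.bin location;
#'   purely informational.
#'
#' @return A `data.frame` of class `locus_defs` with columns `name`,
#'   `genome_bin`, `repeat_unit`, `size_min`, `size_max`.
#' @examples
#' locus_defs(c("phi001", "umc1"), repeat_unit = c(2L, 3L),
#'            size_min = c(100L, 150L), size_max = c(140L, 180L))
#' @export
locus_defs <- function(name, repeat_unit, size_min, size_max,
                       genome_bin = NA_character_) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("duplicated locus names")
  n <- length(name)
  repeat_unit <- as.integer(rep_len(repeat_unit, n))
  size_min <- as.integer(rep_len(size_min, n))
  size_max <- as.integer(rep_len(size_max, n))
  genome_bin <- as.character(rep_len(genome_bin, n))
  if (any(repeat_unit <= 0L)) stop("repeat_unit must be a positive integer")
  if (any(size_min >= size_max)) stop("size_min must be < size_max")
  out <- data.frame(name = name, genome_bin = genome_bin,
                    repeat_unit = repeat_unit,
                    size_min = size_min, size_max = size_max,
                    stringsAsFactors = FALSE)
  class(out) <- c("locus_defs", "data.frame")
  out
}

#' Read locus definitions from a CSV file
#'
#' Expects columns `name`, `repeat_unit`, `size_min`, `size_max` and
#' optionally `genome_bin`.
#'
#' @param path path to a CSV file.
#' @return A `locus_defs` table.
#' @export
read_locus_defs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "repeat_unit", "size_min", "size_max")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("locus file missing columns: ", paste(miss, collapse = ", "))
  locus_defs(df$name, df$repeat_unit, df$size_min, df$size_max,
             genome_bin = if ("genome_bin" %in% names(df)) df$genome_bin else NA_character_)
}

# rungs of the allele-size ladder for one locus row
locus_ladder <- function(ld) {
  seq.int(ld$size_min, ld$size_max, by = ld$repeat_unit)
}

get_locus <- function(locus_defs, name) {
  i <- match(name, locus_defs$name)
  if (is.na(i)) stop("unknown locus: ", name)
  locus_defs[i, , drop = FALSE]
}
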