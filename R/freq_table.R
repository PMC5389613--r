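#' Population x locus allele-frequency tables
#'
#' The central exchange object of the pipeline: for each population and locus,
#' a named numeric vector mapping allele size (bp, as the vector names) to its
#' relative frequency. A (population, locus) combination that is absent is
#' treated as missing data — never as a row of zero frequencies.
#'
#' @param freqs nested named list: `freqs[[pop]][[locus]]` is a named numeric
#'   vector of allele frequencies (names are allele sizes in bp). Missing
#'   (pop, locus) entries are simply absent.
#' @param locus_defs optional [locus_defs()] table; when supplied, loci must be
#'   known and allele sizes must lie within each locus size range.
#' @param renormalize if `TRUE`, per-entry frequency sums in
#'   `1 +/- sum_tol` are rescaled to sum exactly to 1 (tables exported from
#'   fragment-analysis software carry rounding); sums outside that band are a
#'   hard error either way. If `FALSE` sums must equal 1 to within `1e-9`.
#' @param sum_tol half-width of the acceptable sum band when
#'   `renormalize = TRUE` (default 0.02).
#'
#' @return An object of class `freq_table` with elements `freqs`, `pops`,
#'   `loci`, `locus_defs`.
#' @export
freq_table <- function(freqs, locus_defs = NULL, renormalize = FALSE,
                       sum_tol = 0.02) {
  if (!is.list(freqs)) stop("freqs must be a nested list")
  pops <- names(freqs)
  if (is.null(pops) || anyDuplicated(pops)) stop("populations must be uniquely named")
  loci <- unique(unlist(lapply(freqs, names), use.names = FALSE))
  if (!is.null(locus_defs)) {
    unknown <- setdiff(loci, locus_defs$name)
    if (length(unknown)) stop("unknown locus: ", paste(unknown, collapse = ", "))
    loci <- intersect(locus_defs$name, loci)
  }
  for (p in pops) {
    for (l in names(freqs[[p]])) {
      v <- freqs[[p]][[l]]
      if (is.null(v)) { freqs[[p]][[l]] <- NULL; next }
      if (is.null(names(v)) || anyNA(suppressWarnings(as.numeric(names(v)))))
        stop("alleles must be named by size in bp: (", p, ", ", l, ")")
      if (any(v < 0)) stop("negative frequency in (", p, ", ", l, ")")
      s <- sum(v)
      if (renormalize) {
        if (abs(s - 1) > sum_tol)
          stop("frequencies for (", p, ", ", l, ") sum to ", signif(s, 6),
               ", outside 1 +/- ", sum_tol)
        v <- v / s
      } else if (abs(s - 1) > 1e-9) {
        stop("frequencies for (", p, ", ", l, ") sum to ", signif(s, 6),
             " (must be 1 +/- 1e-9)")
      }
      v <- v[order(as.numeric(names(v)))]
      if (!is.null(locus_defs)) {
        ld <- get_locus(locus_defs, l)
        sz <- as.numeric(names(v))
        if (any(sz < ld$size_min | sz > ld$size_max))
          stop("allele size outside locus range in (", p, ", ", l, ")")
      }
      freqs[[p]][[l]] <- v
    }
  }
  structure(list(freqs = freqs, pops = pops, loci = loci,
                 locus_defs = locus_defs),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("freq_table:", length(x$pops), "populations x", length(x$loci), "loci\n")
  n_missing <- sum(vapply(x$pops, function(p)
    sum(!x$loci %in% names(x$freqs[[p]])), integer(1)))
  if (n_missing > 0) cat("  missing (pop, locus) entries:", n_missing, "\n")
  invisible(x)
}

#' Frequencies for one population at one locus
#'
#' @param x a `freq_table`.
#' @param pop,locus population id and locus name.
#' @return Named numeric vector of allele frequencies, or `NULL` when the
#'   entry is masked missing.
#' @export
get_freqs <- function(x, pop, locus) {
  stopifnot(inherits(x, "freq_table"))
  x$freqs[[pop]][[locus]]
}

#' @export
as.data.frame.freq_table <- function(x, ...) {
  rows <- list()
  for (p in x$pops) for (l in names(x$freqs[[p]])) {
    v <- x$freqs[[p]][[l]]
    rows[[length(rows) + 1L]] <- data.frame(
      population = p, locus = l, allele = as.numeric(names(v)),
      frequency = as.numeric(v), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Read an allele-frequency table from CSV or XLSX
#'
#' Two layouts are auto-detected from the header. Long: columns `population`,
#' `locus`, `allele`, `frequency`. Wide: a `population` column plus one column
#' per allele named `locus.allele` (dotted), the layout used by
#' spreadsheet-style exports; zero/empty wide cells mean "allele absent", and
#' a population whose columns for a locus are all empty is masked missing at
#' that locus.
#'
#' Frequency sums per (population, locus) within `1 +/- 0.02` are
#' renormalized to 1; sums outside that band raise an error naming the entry.
#'
#' @param path CSV or XLSX file path.
#' @param locus_defs optional [locus_defs()] for validation.
#' @param sheet XLSX sheet name or index (ignored for CSV).
#' @return A [freq_table()].
#' @export
read_frequency_table <- function(path, locus_defs = NULL, sheet = 1) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the readxl package")
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  lower <- tolower(names(df))
  if (all(c("population", "locus", "allele", "frequency") %in% lower)) {
    names(df) <- lower
    freqs <- freqs_from_long(df)
  } else if ("population" %in% lower) {
    names(df)[lower == "population"] <- "population"
    freqs <- freqs_from_wide(df)
  } else {
    stop("unrecognized frequency-table layout: need a 'population' column")
  }
  freq_table(freqs, locus_defs = locus_defs, renormalize = TRUE)
}

freqs_from_long <- function(df) {
  freqs <- list()
  for (i in seq_len(nrow(df))) {
    p <- as.character(df$population[i]); l <- as.character(df$locus[i])
    a <- as.character(as.numeric(df$allele[i]))
    freqs[[p]][[l]][a] <- as.numeric(df$frequency[i])
  }
  freqs
}

freqs_from_wide <- function(df) {
  acols <- setdiff(names(df), "population")
  parts <- regmatches(acols, regexpr("\\.", acols), invert = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("wide columns must be named locus.allele: ",
                     paste(acols[bad], collapse = ", "))
  locus_of <- vapply(parts, `[`, "", 1L)
  allele_of <- vapply(parts, `[`, "", 2L)
  freqs <- list()
  for (i in seq_len(nrow(df))) {
    p <- as.character(df$population[i])
    freqs[[p]] <- list()
    for (l in unique(locus_of)) {
      sel <- locus_of == l
      v <- suppressWarnings(as.numeric(df[i, acols[sel]]))
      v[is.na(v)] <- 0
      if (all(v == 0)) next  # fully empty locus -> masked missing
      names(v) <- as.character(as.numeric(allele_of[sel]))
      freqs[[p]][[l]] <- v[v > 0]
    }
  }
  freqs
}

#' Write an allele-frequency table as long CSV
#'
#' @param x a `freq_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(x, path) {
  stopifnot(inherits(x, "freq_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
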