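#' Read a fragment-analysis peak table
#'
#' Consumes the per-bulk, per-locus peak export of Genotyper-style fragment
#' analysis software: one row per detected peak with fragment size (bp), peak
#' height (amplification intensity) and an optional quality score. Rows with
#' non-positive height are dropped (count reported via a message); peaks whose
#' size falls outside `[size_min - repeat_unit, size_max + repeat_unit]` for
#' their locus are dropped with a warning.
#'
#' @param path CSV with columns `bulk_id`, `locus`, `size_bp`, `height` and
#'   optionally `quality`.
#' @param locus_defs a [locus_defs()] table; all loci in the file must be
#'   listed.
#' @return A `data.frame` of class `peak_table` with columns `bulk_id`,
#'   `locus`, `size_bp`, `height`, `quality`.
#' @export
read_peak_table <- function(path, locus_defs) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bulk_id", "locus", "size_bp", "height")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("peak table missing columns: ", paste(miss, collapse = ", "))
  if (!"quality" %in% names(df)) df$quality <- NA_real_
  df$size_bp <- suppressWarnings(as.numeric(df$size_bp))
  df$height <- suppressWarnings(as.numeric(df$height))
  bad <- which(is.na(df$size_bp) | is.na(df$height))
  if (length(bad)) stop("malformed peak row at line ", bad[1] + 1L)
  unknown <- setdiff(unique(df$locus), locus_defs$name)
  if (length(unknown)) stop("unknown locus: ", paste(unknown, collapse = ", "))
  drop0 <- df$height <= 0
  if (any(drop0)) {
    message(sum(drop0), " peak(s) with non-positive height dropped")
    df <- df[!drop0, , drop = FALSE]
  }
  i <- match(df$locus, locus_defs$name)
  out_of_range <- df$size_bp < (locus_defs$size_min[i] - locus_defs$repeat_unit[i]) |
    df$size_bp > (locus_defs$size_max[i] + locus_defs$repeat_unit[i])
  if (any(out_of_range)) {
    warning(sum(out_of_range), " peak(s) outside locus size range dropped")
    df <- df[!out_of_range, , drop = FALSE]
  }
  peak_table(df)
}

#' Construct a peak table from a data frame
#'
#' @param df data frame with columns `bulk_id`, `locus`, `size_bp`, `height`
#'   and optionally `quality`.
#' @return The same data, classed as `peak_table`, heights validated
#'   non-negative.
#' @export
peak_table <- function(df) {
  need <- c("bulk_id", "locus", "size_bp", "height")
  stopifnot(all(need %in% names(df)))
  if (!"quality" %in% names(df)) df$quality <- rep(NA_real_, nrow(df))
  if (any(df$height < 0)) stop("negative peak height")
  df <- df[, c(need, "quality")]
  rownames(df) <- NULL
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Write and read square labeled distance matrices
#'
#' CSV round-trip is stable to at least 1e-9 per cell (values are written with
#' full precision).
#'
#' @param d symmetric numeric matrix with matching dimnames and zero diagonal.
#' @param path output CSV path.
#' @return `path` invisibly for the writer; the matrix for the reader.
#' @export
write_distance_matrix <- function(d, path) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d),
            identical(rownames(d), colnames(d)))
  df <- data.frame(id = rownames(d), format(d, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (!identical(rownames(m), colnames(m))) stop("row/column labels disagree")
  if (max(abs(m - t(m))) > 1e-9) stop("matrix is not symmetric")
  m
}

#' Write and read admixture Q matrices
#'
#' One row per population with its ancestry proportions across the K clusters;
#' rows must sum to 1 within 1e-6.
#'
#' @param q numeric matrix (populations x K) with rownames.
#' @param path CSV path.
#' @return `path` invisibly for the writer; the Q matrix for the reader.
#' @export
write_q_matrix <- function(q, path) {
  stopifnot(is.matrix(q), !is.null(rownames(q)))
  if (any(abs(rowSums(q) - 1) > 1e-6)) stop("Q rows must sum to 1")
  if (is.null(colnames(q))) colnames(q) <- paste0("K", seq_len(ncol(q)))
  df <- data.frame(population = rownames(q),
                   format(q, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_q_matrix
#' @export
read_q_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  q <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(q) <- "double"
  rownames(q) <- df[[1]]
  if (any(abs(rowSums(q) - 1) > 1e-6)) stop("Q rows must sum to 1")
  q
}

#' Write a tree in newick format
#'
#' @param tree an [ape::phylo] tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
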