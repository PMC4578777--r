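#' Expression time-series segments
#'
#' Container for one or more equidistant expression time series ("segments")
#' over a shared gene set. Each segment is a numeric matrix with rows as time
#' points and columns as genes; all segments must have identical gene columns
#' (same names, same order) and at least two time points. Missing values are
#' not allowed: non-equidistant series must be interpolated upstream.
#'
#' @param segments a list of numeric matrices (or a single matrix), rows =
#'   time points, columns = genes.
#' @param genes optional character vector of gene names; defaults to the
#'   column names of the first segment, or \code{g1, g2, ...}.
#' @return an object of class \code{expression_segments}: a list of matrices
#'   with a \code{genes} attribute.
#' @export
expression_segments <- function(segments, genes = NULL) {
  if (is.matrix(segments)) segments <- list(segments)
  if (!is.list(segments) || length(segments) == 0L)
    stop("'segments' must be a non-empty list of matrices")
  segments <- lapply(segments, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    s
  })
  n <- ncol(segments[[1L]])
  if (is.null(genes)) genes <- colnames(segments[[1L]])
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  for (k in seq_along(segments)) {
    s <- segments[[k]]
    if (ncol(s) != n)
      stop("segment ", k, " has ", ncol(s), " genes; expected ", n)
    if (!is.null(colnames(s)) && !identical(colnames(s), genes))
      stop("segment ", k, " gene names differ from the first segment")
    if (nrow(s) < 2L)
      stop("segment ", k, " has fewer than 2 time points")
    if (anyNA(s))
      stop("segment ", k, " contains missing values; interpolate upstream")
    colnames(segments[[k]]) <- genes
  }
  structure(segments, genes = genes, class = "expression_segments")
}

#' @export
print.expression_segments <- function(x, ...) {
  m <- vapply(x, nrow, 0L)
  cat("Expression segments:", length(x), "segment(s),",
      length(attr(x, "genes")), "genes,",
      sum(m), "total time points\n")
  cat("  segment lengths:", paste(m, collapse = ", "), "\n")
  invisible(x)
}

n_genes <- function(data) length(attr(data, "genes"))

#' Read expression segments from TSV files
#'
#' Each file holds one segment: a tab-separated table with a header row of
#' gene names, one row per (equidistant) time point. All files must have
#' identical gene columns.
#'
#' @param paths character vector of file paths, one per segment, in order.
#' @return an [expression_segments] object with one segment per file.
#' @export
read_segments <- function(paths) {
  segs <- lapply(paths, function(p) {
    tab <- utils::read.delim(p, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "numeric")
    as.matrix(tab)
  })
  genes <- colnames(segs[[1L]])
  for (k in seq_along(segs))
    if (!identical(colnames(segs[[k]]), genes))
      stop("gene columns of '", paths[k], "' differ from '", paths[1L], "'")
  expression_segments(segs, genes)
}

#' Write expression segments to TSV files
#'
#' @param data an [expression_segments] object.
#' @param paths one output path per segment.
#' @return `paths`, invisibly.
#' @export
write_segments <- function(data, paths) {
  stopifnot(length(paths) == length(data))
  for (k in seq_along(data))
    utils::write.table(data[[k]], paths[k], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(paths)
}

#' Lag and align genes across segments
#'
#' Builds the design sample used by every (partial) correlation and
#' regression in the package: each requested gene is shifted by its own lag,
#' every segment contributes the rows where all shifted series are in range,
#' and the per-segment overlaps are stacked. With lags all >= 0 and
#' maxLag = max(lags), a segment of length m contributes max(0, m - maxLag)
#' rows. Negative lags (leads) are supported for internal conditioning use.
#'
#' @param data an [expression_segments] object.
#' @param genes integer vector of gene (column) indices.
#' @param lags integer vector of lags, one per entry of `genes`; entry `i` of
#'   a returned row at time t is `x[t - lags[i], genes[i]]`.
#' @return numeric matrix with `length(genes)` columns; zero rows when no
#'   segment is long enough.
#' @export
shift_and_concat <- function(data, genes, lags) {
  stopifnot(length(genes) == length(lags))
  lags <- as.integer(lags)
  lmax <- max(lags); lmin <- min(lags)
  parts <- lapply(unclass(data), function(s) {
    m <- nrow(s)
    t0 <- 1L + max(lmax, 0L); t1 <- m + min(lmin, 0L)
    if (t1 < t0) return(NULL)
    tt <- t0:t1
    out <- matrix(0, length(tt), length(genes))
    for (i in seq_along(genes)) out[, i] <- s[tt - lags[i], genes[i]]
    out
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (length(parts) == 0L)
    return(matrix(0, 0L, length(genes)))
  do.call(rbind, parts)
}
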