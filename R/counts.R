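#' Peak x sample count matrix
#'
#' The basic count container: a non-negative integer matrix with peak ids as
#' row names and sample ids as column names, plus per-sample effective
#' library sizes (total reads falling in consensus peaks, i.e. column sums).
#'
#' @param counts numeric matrix of non-negative integers with complete
#'   dimnames.
#' @return an object of class `peak_counts`: list with `counts` and
#'   `lib_sizes` (named numeric vector of column sums).
#' @export
peak_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L) {
    stop("count matrix must have at least one peak and one sample",
         call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix needs peak ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate peak ids in count matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids in count matrix", call. = FALSE)
  }
  if (!is.numeric(counts) || any(!is.finite(counts))) {
    stop("counts must be finite numbers", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts != round(counts))) {
    stop("counts must be integers", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  structure(list(counts = counts, lib_sizes = colSums(counts)),
            class = "peak_counts")
}

#' @export
print.peak_counts <- function(x, ...) {
  cat(sprintf("Peak count matrix: %d peaks x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  effective library sizes:",
      paste(sprintf("%s=%s", names(x$lib_sizes),
                    format(x$lib_sizes, big.mark = ",", trim = TRUE)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.peak_counts <- function(x) dim(x$counts)

#' Per-sample effective library sizes
#'
#' Total reads in consensus peaks per sample — the column sums of the count
#' matrix, used as the normalization denominator.
#'
#' @param counts a [peak_counts()] object or bare count matrix.
#' @return named numeric vector, one entry per sample.
#' @export
effective_library_sizes <- function(counts) {
  mat <- if (inherits(counts, "peak_counts")) counts$counts else as.matrix(counts)
  if (length(mat) == 0L) stop("empty count matrix", call. = FALSE)
  colSums(mat)
}

#' Combine count matrices by column
#'
#' @param ... `peak_counts` objects over the same peaks (same order).
#' @return a single [peak_counts()] object.
#' @export
cbind_counts <- function(...) {
  objs <- list(...)
  stopifnot(all(vapply(objs, inherits, logical(1), "peak_counts")))
  ids <- rownames(objs[[1L]]$counts)
  for (o in objs[-1L]) {
    if (!identical(rownames(o$counts), ids)) {
      stop("count matrices must share an identical peak id order", call. = FALSE)
    }
  }
  peak_counts(do.call(cbind, lapply(objs, `[[`, "counts")))
}

#' Read a peak count matrix from TSV
#'
#' Expects a header row of sample ids, a first column of peak ids, and
#' non-negative integer cells.
#'
#' @param path file path.
#' @return a [peak_counts()] object (library sizes recomputed).
#' @export
read_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = NA)
  if (ncol(df) < 2L) stop("count table needs a peak_id column and at least one sample",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate peak_id in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    loc <- if (length(bad)) {
      sprintf(" (first at row %d, sample '%s')", bad[1, 1],
              colnames(df)[-1L][bad[1, 2]])
    } else ""
    stop("non-numeric count cell in ", path, loc, call. = FALSE)
  }
  nonint <- which(mat != round(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(nonint)) {
    stop(sprintf(
      "invalid count at peak '%s', sample '%s' in %s: %s (must be a non-negative integer)",
      ids[nonint[1, 1]], colnames(mat)[nonint[1, 2]], path,
      format(mat[nonint[1, 1], nonint[1, 2]])), call. = FALSE)
  }
  rownames(mat) <- ids
  peak_counts(mat)
}

#' Write a peak count matrix to TSV
#'
#' @param counts a [peak_counts()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "peak_counts"))
  df <- data.frame(peak_id = rownames(counts$counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (s in colnames(counts$counts)) {
    df[[s]] <- formatC(counts$counts[, s], format = "d")  # no scientific notation
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
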