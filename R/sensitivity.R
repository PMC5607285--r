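#' Count-level peak detection against a uniform Poisson background
#'
#' A proxy for per-sample peak calling: under a uniform background, the
#' expected reads in a peak of length L from a library of N reads over an
#' effective genome of G bp is lambda = N * L / G. A peak is detected when
#' its upper-tail Poisson p-value P(X >= count | lambda), BH-adjusted across
#' the evaluated peak set of the sample, falls below `q_threshold`.
#'
#' @param counts a [peak_counts()] object, count matrix, or single-sample
#'   count vector.
#' @param peak_lengths per-peak lengths in bp (recycled if scalar).
#' @param library_size per-sample total reads; defaults to column sums.
#' @param effective_genome background genome size in bp (> 0).
#' @param q_threshold BH-adjusted significance threshold (default 0.01).
#' @return logical matrix (peaks x samples) of detection flags.
#' @export
detect_peaks <- function(counts, peak_lengths, library_size = NULL,
                         effective_genome, q_threshold = 0.01) {
  mat <- if (inherits(counts, "peak_counts")) counts$counts else as.matrix(counts)
  if (!is.numeric(effective_genome) || effective_genome <= 0) {
    stop("effective genome size must be positive", call. = FALSE)
  }
  peak_lengths <- rep_len(peak_lengths, nrow(mat))
  if (any(peak_lengths <= 0)) stop("peak lengths must be positive", call. = FALSE)
  if (is.null(library_size)) library_size <- colSums(mat)
  library_size <- rep_len(library_size, ncol(mat))
  if (any(library_size < 0)) stop("library sizes must be non-negative", call. = FALSE)

  flags <- matrix(FALSE, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (j in seq_len(ncol(mat))) {
    lambda <- library_size[j] * peak_lengths / effective_genome
    p <- ppois(mat[, j] - 1, lambda = lambda, lower.tail = FALSE)
    q <- bh_fdr(p)
    flags[, j] <- q < q_threshold & mat[, j] > 0
  }
  flags
}

#' Detection rates of cell-type peak sets across samples
#'
#' Applies [detect_peaks()] over all peaks of the matrix (the BH adjustment
#' spans the full evaluated set per sample) and summarizes, per sample and
#' cell type, the fraction of that type's peaks (signature or differential)
#' that are detected.
#'
#' In synthetic mode the effective genome defaults to the total peak length
#' divided by `in_peak_fraction`, i.e. peaks occupy 10% of the background by
#' default.
#'
#' @param counts a [peak_counts()] object.
#' @param peak_sets named list of peak id vectors, one per cell type.
#' @param peak_lengths per-peak lengths in bp, named by peak id or in matrix
#'   row order (default 500 bp).
#' @param effective_genome background size in bp; default
#'   `sum(peak_lengths) / in_peak_fraction`.
#' @param in_peak_fraction fraction of the background occupied by peaks when
#'   `effective_genome` is not given.
#' @param q_threshold BH-adjusted detection threshold.
#' @return class `detection_report`: list with `rates` (data frame: sample,
#'   cell_type, n_peaks, detection_rate, library_size), `detected` (flag
#'   matrix), `effective_genome`, `q_threshold`.
#' @export
detection_rates <- function(counts, peak_sets, peak_lengths = 500,
                            effective_genome = NULL, in_peak_fraction = 0.1,
                            q_threshold = 0.01) {
  stopifnot(inherits(counts, "peak_counts"))
  mat <- counts$counts
  if (!is.list(peak_sets) || is.null(names(peak_sets))) {
    stop("peak_sets must be a named list of peak id vectors", call. = FALSE)
  }
  if (any(lengths(peak_sets) == 0L)) {
    stop("empty peak set for: ",
         paste(names(peak_sets)[lengths(peak_sets) == 0L], collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(unlist(peak_sets)), rownames(mat))
  if (length(unknown)) {
    stop("peak id(s) not in the count matrix: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  peak_lengths <- rep_len(peak_lengths, nrow(mat))
  if (is.null(effective_genome)) {
    if (in_peak_fraction <= 0 || in_peak_fraction > 1) {
      stop("in_peak_fraction must lie in (0, 1]", call. = FALSE)
    }
    effective_genome <- sum(peak_lengths) / in_peak_fraction
  }
  flags <- detect_peaks(counts, peak_lengths,
                        effective_genome = effective_genome,
                        q_threshold = q_threshold)
  rates <- do.call(rbind, lapply(names(peak_sets), function(ty) {
    ids <- peak_sets[[ty]]
    data.frame(sample = colnames(mat), cell_type = ty, n_peaks = length(ids),
               detection_rate = colMeans(flags[ids, , drop = FALSE]),
               library_size = counts$lib_sizes, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  structure(list(rates = rates, detected = flags,
                 effective_genome = effective_genome,
                 q_threshold = q_threshold),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, digits = 3, ...) {
  cat(sprintf("Peak detection report (Poisson background over %.3g bp, q < %g)\n",
              x$effective_genome, x$q_threshold))
  df <- x$rates
  df$detection_rate <- round(df$detection_rate, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Re-run detection and deconvolution across sequencing depths
#'
#' Binomially thins every sample to each fraction of its original effective
#' library size, re-normalizes, re-deconvolves against a fixed signature
#' matrix, and recomputes detection rates — the depth-robustness analysis of
#' the mixing benchmark (e.g. fractions mirroring a 25/15/5/1 million-read
#' down-sampling design).
#'
#' @param counts a [peak_counts()] object (the mixture samples).
#' @param depth_fractions fractions of the original depth, each in (0, 1].
#' @param signature a [select_signature_matrix()] object.
#' @param peak_sets named list of per-cell-type peak id vectors for
#'   detection.
#' @param truth optional [mixture_design()] matrix for recovery statistics.
#' @param ... further arguments passed to [detection_rates()].
#' @return class `depth_titration`: list with `table` (one row per fraction:
#'   mean depth, per-type mean detection rates, R/RMSE vs truth, mean
#'   absolute shift of the estimates from the full-depth fit), `fits` and
#'   `reports` keyed by fraction.
#' @export
depth_titration <- function(counts, depth_fractions, signature, peak_sets,
                            truth = NULL, ...) {
  stopifnot(inherits(counts, "peak_counts"))
  if (any(depth_fractions <= 0) || any(depth_fractions > 1)) {
    stop("depth fractions must lie in (0, 1]", call. = FALSE)
  }
  depth_fractions <- sort(depth_fractions, decreasing = TRUE)

  full_fit <- deconvolve(signature, normalize_cpm(counts), truth = truth)
  fits <- list(); reports <- list(); rows <- list()
  for (fr in depth_fractions) {
    thinned <- if (fr == 1) counts else
      downsample_counts(counts, round(fr * counts$lib_sizes))
    fit <- deconvolve(signature, normalize_cpm(thinned), truth = truth)
    rep <- detection_rates(thinned, peak_sets, ...)
    key <- format(fr)
    fits[[key]] <- fit; reports[[key]] <- rep
    by_type <- tapply(rep$rates$detection_rate, rep$rates$cell_type, mean)
    row <- data.frame(fraction = fr,
                      mean_depth = mean(thinned$lib_sizes),
                      mean_detection_rate = mean(rep$rates$detection_rate),
                      shift_from_full = mean(abs(coef(fit) - coef(full_fit))),
                      row.names = NULL)
    for (ty in names(by_type)) row[[paste0("detection_", ty)]] <- by_type[[ty]]
    if (!is.null(truth)) {
      row$R <- fit$recovery$R
      row$RMSE <- fit$recovery$RMSE
    }
    rows[[key]] <- row
  }
  structure(list(table = do.call(rbind, rows), fits = fits,
                 reports = reports, full_fit = full_fit),
            class = "depth_titration")
}

#' @export
print.depth_titration <- function(x, digits = 4, ...) {
  cat("Depth titration (binomial thinning):\n")
  df <- x$table
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
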