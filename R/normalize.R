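#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' Composition-robust scaling factors relative to effective library size.
#' The reference sample is the one whose 75th-percentile count fraction is
#' closest to the mean across samples; per sample, log ratios (M) and average
#' log intensities (A) are computed over peaks nonzero in both the sample and
#' the reference, doubly trimmed (30% on M, 5% on A by default), and the
#' factor is 2 to the precision-weighted mean of the surviving M values.
#' Factors are re-centered so their geometric mean is 1. Computation is
#' delegated to `edgeR::calcNormFactors(method = "TMM")`.
#'
#' @param counts a [peak_counts()] object or count matrix.
#' @param logratio_trim fraction of M values trimmed from each tail.
#' @param sum_trim fraction of A values trimmed from each tail.
#' @param a_cutoff minimum A value retained.
#' @return named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, sum_trim = 0.05,
                        a_cutoff = -1e10) {
  mat <- if (inherits(counts, "peak_counts")) counts$counts else as.matrix(counts)
  lib <- colSums(mat)
  if (all(lib == 0)) {
    stop("TMM factors need at least one sample with nonzero library size",
         call. = FALSE)
  }
  f <- suppressWarnings(edgeR::calcNormFactors(
    mat, lib.size = lib, method = "TMM",
    logratio.trim = logratio_trim, sum.trim = sum_trim, Acutoff = a_cutoff))
  if (any(!is.finite(f))) {
    warning("TMM factor undefined for sample(s) ",
            paste(colnames(mat)[!is.finite(f)], collapse = ", "),
            "; set to 1")
    f[!is.finite(f)] <- 1
    f <- f / exp(mean(log(f)))
  }
  setNames(as.numeric(f), colnames(mat))
}

#' Normalize counts to TMM-adjusted counts per million
#'
#' value = 1e6 * count / (effective library size * TMM factor), linear scale.
#' Zero counts map to 0; no pseudocount is added here (log transforms
#' downstream use pseudocount 0.5 where stated).
#'
#' @param counts a [peak_counts()] object or count matrix.
#' @param factors optional per-sample scaling factors; estimated with
#'   [tmm_factors()] when missing.
#' @return an object of class `atac_cpm`: list with `values` (peaks x samples
#'   matrix), `lib_sizes`, and `tmm_factors`.
#' @export
normalize_cpm <- function(counts, factors = NULL) {
  mat <- if (inherits(counts, "peak_counts")) counts$counts else as.matrix(counts)
  lib <- colSums(mat)
  if (any(lib == 0)) {
    stop("zero effective library size for sample(s) ",
         paste(colnames(mat)[lib == 0], collapse = ", "), call. = FALSE)
  }
  if (is.null(factors)) factors <- tmm_factors(counts)
  if (length(factors) != ncol(mat)) {
    stop("need one scaling factor per sample", call. = FALSE)
  }
  if (any(factors <= 0)) stop("scaling factors must be positive", call. = FALSE)
  values <- sweep(mat, 2, lib * factors, "/") * 1e6
  structure(list(values = values, lib_sizes = lib,
                 tmm_factors = setNames(as.numeric(factors), colnames(mat))),
            class = "atac_cpm")
}

#' @export
print.atac_cpm <- function(x, ...) {
  cat(sprintf("TMM-normalized accessibility (CPM): %d peaks x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  TMM factors:",
      paste(sprintf("%s=%.4f", names(x$tmm_factors), x$tmm_factors),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.atac_cpm <- function(x) dim(x$values)

cpm_values <- function(x) {
  if (inherits(x, "atac_cpm")) x$values else as.matrix(x)
}
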