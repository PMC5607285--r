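#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided test with the Satterthwaite degrees-of-freedom approximation.
#' Group variances below 1e-12 are floored at 1e-12 (with a warning) so that
#' exactly replicated values yield a defined statistic rather than 0/0.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df` and two-sided `p`.
#' @export
#' @examples
#' welch_t_test(c(10, 12, 11), c(2, 3, 2))
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  res <- row_welch(matrix(group_a, nrow = 1), matrix(group_b, nrow = 1))
  list(t = res$t[1L], df = res$df[1L], p = res$p[1L])
}

# Vectorized Welch test over matrix rows (peaks). Variance floor keeps
# zero-variance rows (e.g. noiseless simulations) finite.
row_welch <- function(a, b, var_floor = 1e-12) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  floored <- va < var_floor | vb < var_floor
  if (any(floored)) {
    warning(sum(floored), " group variance(s) below ", var_floor,
            " floored for the Welch test", call. = FALSE)
    va <- pmax(va, var_floor)
    vb <- pmax(vb, var_floor)
  }
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(t), df = df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up q-values: monotone over the p-value ranking and capped at 1.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

# log2 fold change of group means on the linear CPM scale, pseudocount 0.5.
log2fc_means <- function(a, b, pseudocount = 0.5) {
  log2(rowMeans(a) + pseudocount) - log2(rowMeans(b) + pseudocount)
}

# Resolve group labels against the columns of a normalized matrix.
resolve_groups <- function(values, groups) {
  if (is.null(names(groups))) {
    if (length(groups) != ncol(values)) {
      stop("groups must be named by sample or match the sample count",
           call. = FALSE)
    }
    names(groups) <- colnames(values)
  }
  missing <- setdiff(names(groups), colnames(values))
  if (length(missing)) {
    stop("samples not present in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  split(names(groups), as.character(groups))
}

#' Call differentially accessible peaks between two pure populations
#'
#' Per peak, a two-sided Welch test on log2(CPM + 0.5) across replicates of
#' the two groups, BH adjustment, and a log2 fold change of the linear group
#' means (pseudocount 0.5). A peak is labeled specific to the group it favors
#' when q < `q_max` and |log2 FC| > `min_abs_log2fc`; otherwise `shared/ns`.
#'
#' @param norm an `atac_cpm` object (or matrix of normalized values).
#' @param groups sample -> group labels (exactly two groups, >= 2 replicates
#'   each).
#' @param q_max FDR threshold (default 5%).
#' @param min_abs_log2fc fold-change threshold in log2 units (default 2).
#' @return data frame with peak_id, t, df, p, q, log2fc (first group over
#'   second), and label in `{"<groupA>-specific", "<groupB>-specific",
#'   "shared/ns"}`.
#' @export
call_differential_peaks <- function(norm, groups, q_max = 0.05,
                                    min_abs_log2fc = 2) {
  values <- cpm_values(norm)
  by_group <- resolve_groups(values, groups)
  if (length(by_group) != 2L) {
    stop("differential calling needs exactly two groups", call. = FALSE)
  }
  sizes <- lengths(by_group)
  if (any(sizes < 2L)) {
    stop("group(s) with fewer than 2 replicates: ",
         paste(names(by_group)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  ga <- names(by_group)[1L]; gb <- names(by_group)[2L]
  a <- values[, by_group[[ga]], drop = FALSE]
  b <- values[, by_group[[gb]], drop = FALSE]
  test <- row_welch(log2(a + 0.5), log2(b + 0.5))
  q <- bh_fdr(test$p)
  lfc <- log2fc_means(a, b)
  label <- rep("shared/ns", nrow(values))
  sig <- q < q_max & abs(lfc) > min_abs_log2fc
  label[sig & lfc > 0] <- paste0(ga, "-specific")
  label[sig & lfc < 0] <- paste0(gb, "-specific")
  data.frame(peak_id = rownames(values), t = test$t, df = test$df,
             p = test$p, q = q, log2fc = lfc, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' 2-norm condition number of a matrix
#'
#' Ratio of largest to smallest singular value; `Inf` for rank-deficient
#' matrices. Used to pick the signature size whose basis is most stable for
#' deconvolution.
#'
#' @param m numeric matrix with at least as many rows as columns.
#' @return the condition number (possibly `Inf`).
#' @export
condition_number <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < ncol(m)) {
    stop("condition number needs at least as many peaks (rows) as cell types (columns)",
         call. = FALSE)
  }
  d <- svd(m, nu = 0, nv = 0)$d
  tol <- max(dim(m)) * .Machine$double.eps * d[1L]
  if (d[length(d)] <= tol) return(Inf)
  d[1L] / d[length(d)]
}

#' Select signature peaks and build the signature matrix
#'
#' CIBERSORT-style signature construction from pure replicate profiles. For
#' each cell type a one-vs-rest Welch test (on log2 CPM, pseudocount 0.5)
#' ranks candidate peaks with q < `q_sig` and positive fold change toward the
#' type by descending fold change. For every candidate size g in `g_grid`,
#' the top g peaks per type are pooled and the signature matrix of per-type
#' replicate medians (linear CPM) is formed; the g minimizing the 2-norm
#' condition number is returned (ties -> smallest g).
#'
#' @param norm an `atac_cpm` object (pure replicate samples only).
#' @param groups sample -> cell type labels (K >= 2 types, >= 2 replicates
#'   each).
#' @param q_sig candidacy FDR threshold (default 0.30).
#' @param g_grid candidate per-type signature sizes (default 50:200).
#' @return class `signature_matrix`: list with `values` (signature peaks x K
#'   median CPM matrix), `g`, `kappa`, `cell_types`, `peaks_by_type`, and
#'   `tests` (per-type one-vs-rest test tables).
#' @export
select_signature_matrix <- function(norm, groups, q_sig = 0.30,
                                    g_grid = 50:200) {
  values <- cpm_values(norm)
  by_group <- resolve_groups(values, groups)
  types <- names(by_group)
  if (length(types) < 2L) stop("need at least two cell types", call. = FALSE)
  sizes <- lengths(by_group)
  if (any(sizes < 2L)) {
    stop("cell type(s) with fewer than 2 replicates: ",
         paste(types[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  g_grid <- sort(unique(as.integer(g_grid)))

  tests <- list()
  ranked <- list()
  for (ty in types) {
    own <- values[, by_group[[ty]], drop = FALSE]
    rest <- values[, unlist(by_group[types != ty]), drop = FALSE]
    test <- row_welch(log2(own + 0.5), log2(rest + 0.5))
    q <- bh_fdr(test$p)
    lfc <- log2fc_means(own, rest)
    tests[[ty]] <- data.frame(peak_id = rownames(values), t = test$t,
                              df = test$df, p = test$p, q = q, log2fc = lfc,
                              row.names = NULL, stringsAsFactors = FALSE)
    cand <- which(q < q_sig & lfc > 0)
    ranked[[ty]] <- rownames(values)[cand[order(-lfc[cand])]]
  }

  avail <- vapply(ranked, length, integer(1))
  usable <- g_grid[g_grid <= min(avail)]
  if (!length(usable)) {
    stop("too few qualifying signature candidates (q < ", q_sig, "): ",
         paste(sprintf("%s=%d", types, avail), collapse = ", "),
         "; smallest requested size is ", min(g_grid), call. = FALSE)
  }

  medians <- do.call(cbind, lapply(types, function(ty) {
    apply(values[, by_group[[ty]], drop = FALSE], 1, median)
  }))
  colnames(medians) <- types

  kappas <- vapply(usable, function(g) {
    peaks <- unique(unlist(lapply(ranked, head, g)))
    condition_number(medians[peaks, , drop = FALSE])
  }, numeric(1))
  best <- usable[which.min(kappas)]   # which.min takes the first (smallest g) tie
  peaks_by_type <- lapply(ranked, head, best)
  sel <- unique(unlist(peaks_by_type))

  structure(list(values = medians[sel, , drop = FALSE], g = best,
                 kappa = min(kappas), cell_types = types,
                 peaks_by_type = peaks_by_type, tests = tests,
                 q_sig = q_sig, g_grid = usable, kappa_grid = kappas),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("Signature matrix: %d peaks x %d cell types (g = %d per type, condition number %.3g)\n",
              nrow(x$values), ncol(x$values), x$g, x$kappa))
  cat("  per-type signature peaks:",
      paste(sprintf("%s=%d", names(x$peaks_by_type),
                    lengths(x$peaks_by_type)), collapse = ", "), "\n")
  invisible(x)
}
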