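# Independent oracles used across the suite. These deliberately re-derive
# results from first principles (published formulas, exhaustive search) and
# never call the package code paths they check.

# Scripted evaluation of the published TMM recipe: upper-quartile reference
# selection, M/A values over peaks nonzero in both sample and reference,
# double rank-trim (30% on M, 5% on A), precision-weighted mean of the
# surviving M values, geometric-mean-1 re-centering.
tmm_oracle <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  counts <- counts[rowSums(counts > 0) > 0, , drop = FALSE]
  lib <- colSums(counts)
  f75 <- apply(counts, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))

  one_factor <- function(j) {
    obs <- counts[, j]; re <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    M <- log2((obs / nO) / (re / nR))
    A <- (log2(obs / nO) + log2(re / nR)) / 2
    w <- (nO - obs) / (nO * obs) + (nR - re) / (nR * re)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

# Exhaustive search over K=2 simplex directions at `step` resolution, with
# the closed-form optimal non-negative scale per direction; returns the
# direction minimizing the residual of s * S f - m (the same objective whose
# optimum the non-negative least-squares direction attains).
grid_oracle <- function(S, m, step = 1e-4) {
  a <- seq(0, 1, by = step)
  best <- c(NA, Inf)
  for (ai in a) {
    w <- S[, 1] * ai + S[, 2] * (1 - ai)
    s <- max(0, sum(w * m) / sum(w * w))
    r2 <- sum((s * w - m)^2)
    if (r2 < best[2]) best <- c(ai, r2)
  }
  c(best[1], 1 - best[1])
}

# Small, fast simulation settings for unit tests (scaled-down study design;
# the full-scale conditions live in test-acceptance.R).
tiny_params <- function(...) {
  args <- utils::modifyList(list(n_peaks = 800, depth = 1e5,
                                 n_replicates = 3, seed = 11L), list(...))
  do.call(sim_params, args)
}
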