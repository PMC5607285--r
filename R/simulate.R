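#' Simulation parameters for a cell-mixture ATAC-seq experiment
#'
#' Bundles and validates the knobs of the bundled simulator. Defaults describe
#' the two-cell-type titration design the package is benchmarked on: 20,000
#' consensus peaks of which 10% per type are cell-specific, a 16-fold
#' accessibility boost of a specific peak in its own cell type against a 0.5x
#' background elsewhere (expected log2 fold change log2(16/0.5) = 5), negative
#' binomial counts with dispersion 0.05, three pure replicates per type at
#' 5e6 in-peak reads, and mixtures titrated in 10% steps.
#'
#' @param n_peaks number of consensus peaks.
#' @param n_cell_types number of cell types K (>= 2).
#' @param frac_specific fraction of peaks specific to each cell type; scalar
#'   (recycled) or length-K vector, each in \[0,1) and summing to < 1.
#' @param base_mean_log_mu,base_mean_log_sigma meanlog and sdlog of the
#'   log-normal distribution of per-peak baseline relative accessibility.
#' @param fold_factor accessibility multiplier of a specific peak in its own
#'   cell type (> 4 so the expected log2 fold change against background
#'   exceeds 2).
#' @param background_factor accessibility of a specific peak in the other
#'   cell types, relative to baseline; in (0,1).
#' @param nb_dispersion negative binomial dispersion phi
#'   (variance = mu + phi * mu^2); 0 gives Poisson counts.
#' @param n_replicates pure replicates per cell type.
#' @param depth total in-peak reads per sample; scalar or per-sample later.
#' @param titration_step spacing of the two-type mixture grid, in (0, 0.5].
#' @param cell_types cell type labels; default LETTERS\[1:K\].
#' @param seed integer RNG seed used by [simulate_mixture_experiment()].
#' @return an object of class `sim_params` (a validated list).
#' @export
#' @examples
#' sim_params(n_peaks = 1000, depth = 1e5)
sim_params <- function(n_peaks = 20000, n_cell_types = 2, frac_specific = 0.10,
                       base_mean_log_mu = 0, base_mean_log_sigma = 1,
                       fold_factor = 16, background_factor = 0.5,
                       nb_dispersion = 0.05, n_replicates = 3, depth = 5e6,
                       titration_step = 0.10, cell_types = NULL, seed = 42L) {
  fail <- function(field, msg) {
    stop("invalid simulation parameter '", field, "': ", msg, call. = FALSE)
  }
  if (!is.numeric(n_peaks) || length(n_peaks) != 1L || n_peaks < 1 ||
      n_peaks != round(n_peaks)) {
    fail("n_peaks", "must be a positive integer")
  }
  if (!is.numeric(n_cell_types) || length(n_cell_types) != 1L ||
      n_cell_types < 2 || n_cell_types != round(n_cell_types)) {
    fail("n_cell_types", "must be an integer >= 2")
  }
  K <- as.integer(n_cell_types)
  if (length(frac_specific) == 1L) frac_specific <- rep(frac_specific, K)
  if (length(frac_specific) != K) {
    fail("frac_specific", "must be scalar or one value per cell type")
  }
  if (any(frac_specific < 0) || any(frac_specific >= 1)) {
    fail("frac_specific", "each fraction must lie in [0, 1)")
  }
  if (sum(frac_specific) >= 1) {
    fail("frac_specific", sprintf("fractions sum to %.3g; must sum to < 1",
                                  sum(frac_specific)))
  }
  if (!is.numeric(base_mean_log_sigma) || base_mean_log_sigma <= 0) {
    fail("base_mean_log_sigma", "must be > 0")
  }
  if (!is.numeric(fold_factor) || fold_factor <= 0) {
    fail("fold_factor", "must be > 0")
  }
  if (!is.numeric(background_factor) || background_factor <= 0 ||
      background_factor >= 1) {
    fail("background_factor", "must lie in (0, 1)")
  }
  if (log2(fold_factor / background_factor) <= 2) {
    fail("fold_factor", sprintf(
      "expected log2 fold change log2(fold/background) = %.3g must exceed 2",
      log2(fold_factor / background_factor)))
  }
  if (!is.numeric(nb_dispersion) || nb_dispersion < 0) {
    fail("nb_dispersion", "must be >= 0")
  }
  if (!is.numeric(n_replicates) || n_replicates < 1 ||
      n_replicates != round(n_replicates)) {
    fail("n_replicates", "must be a positive integer")
  }
  if (!is.numeric(depth) || any(depth <= 0) || any(depth != round(depth))) {
    fail("depth", "must be strictly positive integer read counts")
  }
  if (!is.numeric(titration_step) || titration_step <= 0 ||
      titration_step > 0.5) {
    fail("titration_step", "must lie in (0, 0.5]")
  }
  if (is.null(cell_types)) cell_types <- LETTERS[seq_len(K)]
  if (length(cell_types) != K || anyDuplicated(cell_types)) {
    fail("cell_types", "must be K unique labels")
  }
  structure(list(
    n_peaks = as.integer(n_peaks), n_cell_types = K,
    frac_specific = frac_specific, base_mean_log_mu = base_mean_log_mu,
    base_mean_log_sigma = base_mean_log_sigma, fold_factor = fold_factor,
    background_factor = background_factor, nb_dispersion = nb_dispersion,
    n_replicates = as.integer(n_replicates), depth = depth,
    titration_step = titration_step, cell_types = as.character(cell_types),
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("Simulation parameters: %d peaks, %d cell types (%s)\n",
              x$n_peaks, x$n_cell_types, paste(x$cell_types, collapse = ", ")))
  cat(sprintf("  specific fraction per type: %s; fold %.3g vs background %.3g (E[log2FC] = %.2f)\n",
              paste(format(x$frac_specific), collapse = ", "),
              x$fold_factor, x$background_factor,
              log2(x$fold_factor / x$background_factor)))
  cat(sprintf("  NB dispersion %.3g; %d replicates/type at depth %s; titration step %.2f; seed %d\n",
              x$nb_dispersion, x$n_replicates,
              format(x$depth, big.mark = ","), x$titration_step, x$seed))
  invisible(x)
}

#' Generate the synthetic peak universe and per-type accessibility profile
#'
#' Lays out `n_peaks` non-overlapping 500 bp peaks on a synthetic chromosome
#' "chrS" (1 kb spacing, 0-based half-open coordinates), assigns each peak a
#' class (shared, or specific to one cell type, with per-type counts
#' `round(frac_specific * n_peaks)`), and draws per-peak baseline relative
#' accessibility from the configured log-normal. A peak specific to type c has
#' intensity `fold_factor * base` in c and `background_factor * base`
#' elsewhere; shared peaks have the baseline everywhere.
#'
#' Uses the current RNG state; seed it (or use
#' [simulate_mixture_experiment()]) for reproducibility.
#'
#' @param params a [sim_params()] object.
#' @return an object of class `peak_universe`: list with `peaks` (a
#'   [peak_set()] data frame), `classes` (per-peak labels, `"shared"` or
#'   `"specific:<type>"`), and `intensity` (peaks x K matrix of relative
#'   accessibility).
#' @export
generate_peak_universe <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_peaks
  K <- params$n_cell_types
  ids <- sprintf("peak_%06d", seq_len(n))
  peaks <- peak_set(data.frame(
    chrom = "chrS",
    start = (seq_len(n) - 1L) * 1000L,
    end = (seq_len(n) - 1L) * 1000L + 500L,
    peak_id = ids,
    stringsAsFactors = FALSE
  ))

  n_spec <- round(params$frac_specific * n)
  classes <- rep("shared", n)
  pool <- sample.int(n)   # random placement of specific peaks along the chromosome
  offset <- 0L
  for (k in seq_len(K)) {
    if (n_spec[k] > 0) {
      idx <- pool[(offset + 1L):(offset + n_spec[k])]
      classes[idx] <- paste0("specific:", params$cell_types[k])
      offset <- offset + n_spec[k]
    }
  }

  base <- rlnorm(n, meanlog = params$base_mean_log_mu,
                 sdlog = params$base_mean_log_sigma)
  intensity <- matrix(base, nrow = n, ncol = K,
                      dimnames = list(ids, params$cell_types))
  for (k in seq_len(K)) {
    own <- classes == paste0("specific:", params$cell_types[k])
    other <- classes != "shared" & !own
    intensity[own, k] <- params$fold_factor * base[own]
    intensity[other, k] <- params$background_factor * base[other]
  }

  structure(list(peaks = peaks, classes = setNames(classes, ids),
                 intensity = intensity, params = params),
            class = "peak_universe")
}

#' @export
print.peak_universe <- function(x, ...) {
  tab <- table(x$classes)
  cat(sprintf("Synthetic peak universe: %d peaks on chrS, %d cell types\n",
              nrow(x$intensity), ncol(x$intensity)))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Exact expected in-peak counts for a set of composition vectors
#'
#' The mixing model: each cell type contributes reads in proportion to its
#' mixture fraction, distributed over peaks according to its normalized
#' accessibility shares `mu_c / sum(mu_c)`. The expected count of peak p in a
#' sample with composition f and depth D is therefore
#' `D * sum_c f_c * mu_pc / sum_p' mu_p'c` — exactly the f-weighted
#' combination of the pure-population expectations.
#'
#' @param universe a `peak_universe`.
#' @param design a [mixture_design()] matrix (samples x K, rows sum to 1).
#' @param depth per-sample depth (scalar or one per design row).
#' @return peaks x samples matrix of (non-integer) expected counts.
#' @export
expected_counts <- function(universe, design, depth) {
  stopifnot(inherits(universe, "peak_universe"))
  design <- mixture_design(design, universe$params$cell_types)
  depth <- rep_len(depth, nrow(design))
  shares <- sweep(universe$intensity, 2, colSums(universe$intensity), "/")
  mu <- shares %*% t(design)           # peaks x samples, columns sum to 1
  sweep(mu, 2, depth, "*")
}

nb_draw <- function(mu, dispersion) {
  n <- length(mu)
  if (dispersion <= 0) {
    counts <- rpois(n, lambda = mu)
  } else {
    counts <- rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  counts
}

#' Simulate pure-population replicate count profiles
#'
#' Draws `n_replicates` negative binomial count columns per cell type, with
#' per-peak means `depth * mu_c / sum(mu_c)` and dispersion `nb_dispersion`.
#'
#' @inheritParams expected_counts
#' @param params a [sim_params()] object (replicates, depth, dispersion).
#' @return list with `counts` (a [peak_counts()] object) and `groups`
#'   (named character vector mapping sample id to cell type).
#' @export
generate_pure_counts <- function(params, universe) {
  stopifnot(inherits(params, "sim_params"), inherits(universe, "peak_universe"))
  K <- params$n_cell_types
  design <- diag(K)[rep(seq_len(K), each = params$n_replicates), , drop = FALSE]
  rownames(design) <- paste0(rep(params$cell_types, each = params$n_replicates),
                             "_rep", rep(seq_len(params$n_replicates), K))
  colnames(design) <- params$cell_types
  counts <- generate_mixture_counts(params, universe, design)
  groups <- setNames(rep(params$cell_types, each = params$n_replicates),
                     rownames(design))
  list(counts = counts, groups = groups)
}

#' Simulate mixture count profiles for a composition design
#'
#' Expected counts follow the f-weighted mixing model of [expected_counts()];
#' observed counts are negative binomial around them.
#'
#' @inheritParams expected_counts
#' @param params a [sim_params()] object.
#' @return a [peak_counts()] object with one column per design row.
#' @export
generate_mixture_counts <- function(params, universe, design) {
  stopifnot(inherits(params, "sim_params"), inherits(universe, "peak_universe"))
  design <- mixture_design(design, params$cell_types)
  mu <- expected_counts(universe, design, params$depth)
  counts <- matrix(nb_draw(mu, params$nb_dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  peak_counts(counts)
}

#' Validate (or build) a mixture composition design
#'
#' @param design samples x K numeric matrix of cell-type proportions; rows
#'   must be non-negative and sum to 1 within 1e-12.
#' @param cell_types optional expected column labels.
#' @return the validated matrix with dimnames, class `mixture_design`.
#' @export
mixture_design <- function(design, cell_types = NULL) {
  design <- as.matrix(design)
  if (!is.numeric(design)) stop("mixture design must be numeric", call. = FALSE)
  if (any(design < 0)) {
    stop("mixture proportions must be non-negative", call. = FALSE)
  }
  bad <- abs(rowSums(design) - 1) > 1e-12
  if (any(bad)) {
    stop("mixture proportions must sum to 1 (rows: ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  if (!is.null(cell_types)) {
    if (is.null(colnames(design))) {
      colnames(design) <- cell_types
    } else if (!identical(colnames(design), cell_types)) {
      design <- design[, cell_types, drop = FALSE]
    }
  }
  if (is.null(rownames(design))) {
    rownames(design) <- sprintf("mix_%02d", seq_len(nrow(design)))
  }
  class(design) <- c("mixture_design", class(design))
  design
}

#' Two-cell-type titration design
#'
#' The benchmark grid: mixtures spanning 0-100% of the first cell type in
#' `step` increments (11 samples at the default 10% step, pure endpoints
#' included).
#'
#' @param step grid spacing in (0, 0.5].
#' @param cell_types two labels.
#' @return a [mixture_design()] matrix with rows named `mix_000` ... `mix_100`
#'   by percentage of the first type.
#' @export
titration_design <- function(step = 0.10, cell_types = c("A", "B")) {
  stopifnot(length(cell_types) == 2L, step > 0, step <= 0.5)
  f <- seq(0, 1, by = step)
  if (abs(f[length(f)] - 1) > 1e-9) f <- c(f, 1)
  design <- cbind(f, 1 - f)
  colnames(design) <- cell_types
  rownames(design) <- sprintf("mix_%03.0f", 100 * f)
  mixture_design(design, cell_types)
}

#' Binomially thin a count matrix to a lower sequencing depth
#'
#' Each count in a thinned sample is replaced by a Binomial(count, p) draw
#' with p = target_depth / current effective library size, so the expected
#' column sum equals the target. Zeros stay zero and no count ever increases.
#'
#' @param counts a [peak_counts()] object.
#' @param target_depth desired in-peak reads; scalar or one per thinned sample.
#' @param samples samples to thin (default all).
#' @return a new [peak_counts()] object.
#' @export
downsample_counts <- function(counts, target_depth, samples = NULL) {
  stopifnot(inherits(counts, "peak_counts"))
  mat <- counts$counts
  if (is.null(samples)) samples <- colnames(mat)
  if (!all(samples %in% colnames(mat))) {
    stop("unknown sample(s): ",
         paste(setdiff(samples, colnames(mat)), collapse = ", "), call. = FALSE)
  }
  target_depth <- rep_len(target_depth, length(samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    lib <- counts$lib_sizes[[s]]
    if (target_depth[i] > lib) {
      stop(sprintf("target depth %g exceeds current depth %g for sample '%s'",
                   target_depth[i], lib, s), call. = FALSE)
    }
    p <- if (lib > 0) target_depth[i] / lib else 0
    mat[, s] <- rbinom(nrow(mat), size = mat[, s], prob = p)
  }
  peak_counts(mat)
}

#' Simulate a complete titrated mixture experiment
#'
#' Seeds the RNG from `params$seed`, generates the peak universe, the pure
#' replicate profiles of every cell type, and (for two cell types) the
#' titration mixtures.
#'
#' @param params a [sim_params()] object.
#' @param design optional mixture design; defaults to [titration_design()]
#'   when K = 2, otherwise no mixtures unless supplied.
#' @return class `mixture_experiment`: list with `universe`, `pure`
#'   ([peak_counts()]), `groups`, `mixtures` ([peak_counts()] or NULL),
#'   `design`, `params`.
#' @export
#' @examples
#' exp <- simulate_mixture_experiment(sim_params(n_peaks = 500, depth = 5e4))
#' exp
simulate_mixture_experiment <- function(params = sim_params(), design = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  universe <- generate_peak_universe(params)
  pure <- generate_pure_counts(params, universe)
  if (is.null(design) && params$n_cell_types == 2L) {
    design <- titration_design(params$titration_step, params$cell_types)
  }
  mixtures <- NULL
  if (!is.null(design)) {
    design <- mixture_design(design, params$cell_types)
    mixtures <- generate_mixture_counts(params, universe, design)
  }
  structure(list(universe = universe, pure = pure$counts,
                 groups = pure$groups, mixtures = mixtures, design = design,
                 params = params),
            class = "mixture_experiment")
}

#' @export
print.mixture_experiment <- function(x, ...) {
  cat(sprintf("Simulated mixture experiment (seed %d)\n", x$params$seed))
  cat(sprintf("  %d peaks; pure samples: %s\n", x$params$n_peaks,
              paste(colnames(x$pure$counts), collapse = ", ")))
  if (!is.null(x$mixtures)) {
    cat(sprintf("  %d mixture samples over %s\n", nrow(x$design),
                paste(colnames(x$design), collapse = "/")))
  }
  invisible(x)
}
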