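#' Run the full mixture analysis on a simulated (or assembled) experiment
#'
#' Chains the pipeline stages on a `mixture_experiment`: joint TMM
#' normalization of pure and mixture samples, signature selection from the
#' pure replicates, deconvolution of the mixtures against the known design,
#' and signature-peak detection rates across the titration.
#'
#' @param experiment a [simulate_mixture_experiment()] result, or a list with
#'   the same fields built from real data (`design` may then be `NULL`).
#' @param q_sig,g_grid passed to [select_signature_matrix()].
#' @param q_detect,in_peak_fraction passed to [detection_rates()].
#' @param method solver passed to [deconvolve()].
#' @return list with `norm`, `signature`, `fit` (a `deconv_fit`),
#'   `detection` (a `detection_report` over the mixtures, `NULL` without
#'   mixtures) and `recovery`.
#' @export
analyze_mixture_experiment <- function(experiment, q_sig = 0.30,
                                       g_grid = 50:200, q_detect = 0.01,
                                       in_peak_fraction = 0.1,
                                       method = "nnls") {
  counts <- if (!is.null(experiment$mixtures)) {
    cbind_counts(experiment$pure, experiment$mixtures)
  } else {
    experiment$pure
  }
  norm <- normalize_cpm(counts)
  signature <- select_signature_matrix(norm, experiment$groups,
                                       q_sig = q_sig, g_grid = g_grid)
  fit <- NULL; detection <- NULL
  if (!is.null(experiment$mixtures)) {
    fit <- deconvolve(signature, norm, samples = rownames(experiment$design),
                      truth = experiment$design, method = method)
    detection <- detection_rates(experiment$mixtures,
                                 signature$peaks_by_type,
                                 in_peak_fraction = in_peak_fraction,
                                 q_threshold = q_detect)
  }
  list(norm = norm, signature = signature, fit = fit, detection = detection,
       recovery = if (!is.null(fit)) fit$recovery else NULL)
}

default_pipeline_config <- function() {
  list(
    n_peaks = 20000, n_cell_types = 2, frac_specific = 0.10,
    base_mean_log_mu = 0, base_mean_log_sigma = 1, fold_factor = 16,
    background_factor = 0.5, nb_dispersion = 0.05, n_replicates = 3,
    depth = 5e6, titration_step = 0.10,
    q_sig = 0.30, g_min = 50, g_max = 200,
    q_detect = 0.01, in_peak_fraction = 0.1,
    depth_fractions = c(1, 0.2, 0.04),
    method = "nnls"
  )
}

write_provenance <- function(outdir, config, seed) {
  prov <- list(
    package = "atacmix",
    version = as.character(utils::packageVersion("atacmix")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = config
  )
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the end-to-end simulate / normalize / deconvolve / sensitivity pipeline
#'
#' Simulates a titrated mixture experiment, runs
#' [analyze_mixture_experiment()] and [depth_titration()], and writes all
#' result tables (BED peak set, count matrices, truth design, TMM-CPM
#' matrix, signature matrix, estimated proportions, detection rates, depth
#' table) plus a provenance JSON into `outdir`. This is the engine behind
#' the command-line interface.
#'
#' @param config named list overriding entries of the default configuration
#'   (simulation parameters plus analysis thresholds; see
#'   `atacmix:::default_pipeline_config()`).
#' @param outdir output directory (created if needed).
#' @param seed integer RNG seed.
#' @param verbose print progress messages.
#' @return invisibly, a list with `experiment`, `analysis` and `depth`.
#' @export
run_pipeline <- function(config = list(), outdir, seed = 42L,
                         verbose = TRUE) {
  cfg <- default_pipeline_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(config)] <- config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)

  params <- sim_params(
    n_peaks = cfg$n_peaks, n_cell_types = cfg$n_cell_types,
    frac_specific = cfg$frac_specific,
    base_mean_log_mu = cfg$base_mean_log_mu,
    base_mean_log_sigma = cfg$base_mean_log_sigma,
    fold_factor = cfg$fold_factor, background_factor = cfg$background_factor,
    nb_dispersion = cfg$nb_dispersion, n_replicates = cfg$n_replicates,
    depth = cfg$depth, titration_step = cfg$titration_step, seed = seed)

  say("simulating mixture experiment (", params$n_peaks, " peaks)")
  experiment <- simulate_mixture_experiment(params)
  write_bed(experiment$universe$peaks, file.path(outdir, "peaks.bed"))
  write_counts(experiment$pure, file.path(outdir, "pure_counts.tsv"))
  write_counts(experiment$mixtures, file.path(outdir, "mixture_counts.tsv"))
  write.table(data.frame(sample_id = names(experiment$groups),
                         group = experiment$groups, row.names = NULL),
              file.path(outdir, "groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample_id = rownames(experiment$design),
                         experiment$design, check.names = FALSE),
              file.path(outdir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  say("normalizing, selecting signatures, deconvolving")
  analysis <- analyze_mixture_experiment(
    experiment, q_sig = cfg$q_sig, g_grid = cfg$g_min:cfg$g_max,
    q_detect = cfg$q_detect, in_peak_fraction = cfg$in_peak_fraction,
    method = cfg$method)

  write.table(data.frame(peak_id = rownames(analysis$norm$values),
                         analysis$norm$values, check.names = FALSE),
              file.path(outdir, "normalized_cpm.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(peak_id = rownames(analysis$signature$values),
                         analysis$signature$values, check.names = FALSE),
              file.path(outdir, "signature_matrix.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = rownames(coef(analysis$fit)),
                         coef(analysis$fit), check.names = FALSE),
              file.path(outdir, "proportions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(analysis$detection$rates,
              file.path(outdir, "detection_rates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  say("depth titration at fractions ",
      paste(cfg$depth_fractions, collapse = ", "))
  depth <- depth_titration(experiment$mixtures, cfg$depth_fractions,
                           analysis$signature, analysis$signature$peaks_by_type,
                           truth = experiment$design,
                           in_peak_fraction = cfg$in_peak_fraction,
                           q_threshold = cfg$q_detect)
  write.table(depth$table, file.path(outdir, "depth_titration.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  write_provenance(outdir, cfg, seed)
  say(sprintf("done: recovery R = %.4f, RMSE = %.4f",
              analysis$recovery$R, analysis$recovery$RMSE))
  invisible(list(experiment = experiment, analysis = analysis, depth = depth))
}
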