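# Non-negative least squares. When the unconstrained least-squares solution
# is already non-negative it is the NNLS optimum (KKT), which also covers
# exactly-degenerate fits (e.g. m equal to one signature column) that trip
# active-set iterations; otherwise defer to the Lawson-Hanson implementation.
nnls_coefs <- function(S, m) {
  beta <- tryCatch(qr.solve(S, m), error = function(e) NULL)
  if (!is.null(beta) && all(beta >= -1e-9 * max(abs(beta), 1e-300))) {
    return(pmax(beta, 0))
  }
  pracma::lsqnonneg(S, m)$x
}

#' Estimate cell-type proportions for a single mixture profile
#'
#' Solves the linear mixing model m ~ S f: the mixture's normalized
#' accessibility over signature peaks is modeled as the proportion-weighted
#' sum of the pure-population signature columns. The non-negative
#' least-squares solution is renormalized to sum to 1; the residual norm is
#' reported before renormalization.
#'
#' @param signature a [select_signature_matrix()] object or a signature
#'   peaks x K numeric matrix.
#' @param mixture_vector normalized values over the signature peaks; if
#'   named, it is aligned to the signature's peak order.
#' @param method `"nnls"` (default) or `"svr"` (linear-kernel nu-support
#'   vector regression via e1071, provided for comparison).
#' @return list with `proportions` (named, non-negative, sum 1), `residual`
#'   (euclidean norm of S b - m at the unnormalized optimum b) and `raw`
#'   (the unnormalized coefficients).
#' @export
estimate_proportions <- function(signature, mixture_vector,
                                 method = c("nnls", "svr")) {
  method <- match.arg(method)
  S <- if (inherits(signature, "signature_matrix")) signature$values else as.matrix(signature)
  if (!is.null(names(mixture_vector))) {
    missing <- setdiff(rownames(S), names(mixture_vector))
    if (length(missing)) {
      stop("mixture vector lacks signature peak(s): ",
           paste(head(missing, 5), collapse = ", "),
           if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5),
           call. = FALSE)
    }
    mixture_vector <- mixture_vector[rownames(S)]
  } else if (length(mixture_vector) != nrow(S)) {
    stop("mixture vector length does not match the signature peak count",
         call. = FALSE)
  }
  m <- as.numeric(mixture_vector)
  if (all(m == 0)) stop("all-zero mixture profile", call. = FALSE)

  if (method == "nnls") {
    beta <- nnls_coefs(S, m)
  } else {
    if (!requireNamespace("e1071", quietly = TRUE)) {
      stop("the 'svr' backend requires the e1071 package", call. = FALSE)
    }
    fit <- e1071::svm(x = S, y = m, type = "nu-regression", kernel = "linear",
                      nu = 0.5, scale = FALSE)
    beta <- pmax(as.numeric(t(fit$coefs) %*% fit$SV), 0)
  }
  residual <- sqrt(sum((S %*% beta - m)^2))
  if (sum(beta) <= 0) {
    warning("degenerate fit (all coefficients zero); returning uniform proportions")
    beta <- rep(1, ncol(S))
  }
  list(proportions = setNames(beta / sum(beta), colnames(S)),
       residual = residual, raw = setNames(beta, colnames(S)))
}

#' Deconvolve mixture samples into cell-type proportions
#'
#' The model-fitting entry point: applies [estimate_proportions()] to each
#' selected sample of a normalized matrix and, when the true composition is
#' known (simulations), scores recovery with [evaluate_recovery()].
#'
#' @param signature a [select_signature_matrix()] object (or signature
#'   matrix with peak rownames).
#' @param norm an `atac_cpm` object or normalized matrix containing the
#'   signature peaks.
#' @param samples samples to deconvolve (default: all columns of `norm`).
#' @param truth optional [mixture_design()] matrix of true proportions.
#' @param method solver passed to [estimate_proportions()].
#' @return an object of class `deconv_fit` with methods `print`, `summary`,
#'   `coef` (samples x K proportion matrix), `fitted`, `residuals`,
#'   `predict` and `plot`.
#' @export
#' @examples
#' exp <- simulate_mixture_experiment(sim_params(n_peaks = 2000, depth = 2e5,
#'                                               frac_specific = 0.1))
#' norm <- normalize_cpm(cbind_counts(exp$pure, exp$mixtures))
#' sig <- select_signature_matrix(norm, exp$groups, g_grid = 10:50)
#' fit <- deconvolve(sig, norm, samples = rownames(exp$design),
#'                   truth = exp$design)
#' coef(fit)
deconvolve <- function(signature, norm, samples = NULL, truth = NULL,
                       method = c("nnls", "svr")) {
  method <- match.arg(method)
  S <- if (inherits(signature, "signature_matrix")) signature$values else as.matrix(signature)
  values <- cpm_values(norm)
  missing <- setdiff(rownames(S), rownames(values))
  if (length(missing)) {
    stop("signature peak(s) absent from the matrix: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5),
         call. = FALSE)
  }
  if (is.null(samples)) samples <- colnames(values)
  absent <- setdiff(samples, colnames(values))
  if (length(absent)) {
    stop("sample(s) absent from the matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  M <- values[rownames(S), samples, drop = FALSE]

  ests <- lapply(samples, function(s) estimate_proportions(S, M[, s], method))
  proportions <- do.call(rbind, lapply(ests, `[[`, "proportions"))
  raw <- do.call(rbind, lapply(ests, `[[`, "raw"))
  rownames(proportions) <- rownames(raw) <- samples
  res_norm <- setNames(vapply(ests, `[[`, numeric(1), "residual"), samples)

  recovery <- NULL
  if (!is.null(truth)) {
    truth <- as.matrix(truth)
    if (!all(samples %in% rownames(truth))) {
      stop("truth is missing sample(s): ",
           paste(setdiff(samples, rownames(truth)), collapse = ", "),
           call. = FALSE)
    }
    truth <- truth[samples, colnames(proportions), drop = FALSE]
    recovery <- evaluate_recovery(proportions, truth)
  }

  structure(list(proportions = proportions, raw = raw,
                 residual_norms = res_norm, signature = S, mixture = M,
                 truth = truth, recovery = recovery, method = method,
                 call = match.call()),
            class = "deconv_fit")
}

#' @export
print.deconv_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cell-type deconvolution (%s): %d samples, %d cell types, %d signature peaks\n",
              x$method, nrow(x$proportions), ncol(x$proportions),
              nrow(x$signature)))
  print(round(x$proportions, digits))
  if (!is.null(x$recovery)) {
    cat(sprintf("Recovery vs truth: R = %.4f, RMSE = %.4f\n",
                x$recovery$R, x$recovery$RMSE))
  }
  invisible(x)
}

#' @export
summary.deconv_fit <- function(object, ...) {
  out <- list(
    n_samples = nrow(object$proportions),
    cell_types = colnames(object$proportions),
    n_signature_peaks = nrow(object$signature),
    method = object$method,
    proportions = object$proportions,
    residual_norms = object$residual_norms,
    recovery = object$recovery
  )
  class(out) <- "summary.deconv_fit"
  out
}

#' @export
print.summary.deconv_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Deconvolution of %d samples over %d signature peaks (%s solver)\n",
              x$n_samples, x$n_signature_peaks, x$method))
  cat("\nEstimated proportions:\n")
  print(round(x$proportions, digits))
  cat("\nResidual norms:\n")
  print(signif(x$residual_norms, digits))
  if (!is.null(x$recovery)) {
    cat("\n")
    print(x$recovery)
  }
  invisible(x)
}

#' @export
coef.deconv_fit <- function(object, ...) object$proportions

#' @export
fitted.deconv_fit <- function(object, ...) {
  object$signature %*% t(object$raw)
}

#' @export
residuals.deconv_fit <- function(object, ...) {
  object$mixture - fitted(object)
}

#' @param newdata normalized values for new samples: a matrix with signature
#'   peaks as rows (or a named vector for one sample).
#' @rdname deconvolve
#' @param object,... a fitted `deconv_fit` and further arguments (ignored).
#' @export
predict.deconv_fit <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    return(estimate_proportions(object$signature, newdata,
                                object$method)$proportions)
  }
  newdata <- as.matrix(newdata)
  out <- t(apply(newdata[rownames(object$signature), , drop = FALSE], 2,
                 function(m) estimate_proportions(object$signature, m,
                                                  object$method)$proportions))
  colnames(out) <- colnames(object$signature)
  out
}

#' @export
plot.deconv_fit <- function(x, ...) {
  if (!is.null(x$truth)) {
    plot(as.numeric(x$truth), as.numeric(x$proportions),
         xlab = "true proportion", ylab = "estimated proportion",
         xlim = c(0, 1), ylim = c(0, 1),
         main = sprintf("Proportion recovery (R = %.3f)", x$recovery$R), ...)
    abline(0, 1, lty = 2)
  } else {
    barplot(t(x$proportions), legend.text = colnames(x$proportions),
            ylab = "estimated proportion", las = 2, ...)
  }
  invisible(x)
}

#' Score estimated against true cell-type proportions
#'
#' Pools all (sample, cell type) pairs and reports the Pearson correlation R,
#' the root-mean-square error, and the per-sample maximum absolute error.
#' When either side has zero variance, R is reported as 0 with a warning and
#' a `degenerate` flag.
#'
#' @param estimated a `deconv_fit` or samples x K proportion matrix.
#' @param truth samples x K matrix of true proportions covering the same
#'   samples.
#' @return class `recovery_stats`: list with `R`, `RMSE`,
#'   `max_abs_error_per_sample`, `n` (pooled pairs) and `degenerate`.
#' @export
evaluate_recovery <- function(estimated, truth) {
  if (inherits(estimated, "deconv_fit")) estimated <- coef(estimated)
  estimated <- as.matrix(estimated)
  truth <- as.matrix(truth)
  if (!all(rownames(estimated) %in% rownames(truth))) {
    stop("truth is missing sample(s): ",
         paste(setdiff(rownames(estimated), rownames(truth)), collapse = ", "),
         call. = FALSE)
  }
  truth <- truth[rownames(estimated), colnames(estimated), drop = FALSE]
  e <- as.numeric(estimated); f <- as.numeric(truth)
  degenerate <- sd(e) == 0 || sd(f) == 0
  if (degenerate) {
    warning("zero variance in proportions; correlation undefined, reported as 0")
    R <- 0
  } else {
    R <- cor(e, f)
  }
  err <- estimated - truth
  structure(list(R = R, RMSE = sqrt(mean(err^2)),
                 max_abs_error_per_sample = apply(abs(err), 1, max),
                 n = length(e), degenerate = degenerate),
            class = "recovery_stats")
}

#' @export
print.recovery_stats <- function(x, ...) {
  cat(sprintf("Recovery over %d (sample x cell type) pairs: R = %.4f, RMSE = %.4f, max per-sample |error| = %.4f%s\n",
              x$n, x$R, x$RMSE, max(x$max_abs_error_per_sample),
              if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}
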