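test_that("Welch test matches direct evaluation of the formula", {
  out <- welch_t_test(c(10, 12, 11), c(2, 3, 2))
  # hand evaluation: means 11 and 7/3, variances 1 and 1/3
  se2 <- 1 / 3 + (1 / 3) / 3
  t_hand <- (11 - 7 / 3) / sqrt(se2)
  df_hand <- se2^2 / ((1 / 3)^2 / 2 + (1 / 9)^2 / 2)
  expect_equal(out$t, t_hand)
  expect_equal(out$df, df_hand)
  expect_equal(out$p, 2 * pt(t_hand, df_hand, lower.tail = FALSE))

  # cross-check against the base implementation on random data
  set.seed(31)
  for (i in 1:5) {
    a <- rnorm(4 + i); b <- rnorm(3, mean = 1, sd = 2)
    ref <- t.test(a, b, var.equal = FALSE)
    out <- welch_t_test(a, b)
    expect_equal(out$t, unname(ref$statistic))
    expect_equal(out$df, unname(ref$parameter))
    expect_equal(out$p, ref$p.value)
  }
})

test_that("identical groups give t = 0, p = 1 and tiny groups error", {
  out <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("null Welch p-values are uniform", {
  set.seed(41)
  a <- matrix(rnorm(5000 * 10), 5000)
  b <- matrix(rnorm(5000 * 10), 5000)
  p <- atacmix:::row_welch(a, b)$p
  ks <- ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone over the p-value ranking and q >= p
  set.seed(42)
  p <- runif(50)
  q <- bh_fdr(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= 0))
  expect_true(all(q >= p))
})

test_that("differential calling recovers the simulated classes when noise is low", {
  p <- tiny_params(nb_dispersion = 1e-4, depth = 5e5, n_replicates = 4)
  e <- simulate_mixture_experiment(p)
  norm <- normalize_cpm(e$pure)
  da <- call_differential_peaks(norm, e$groups)
  got <- setNames(da$label, da$peak_id)
  want <- ifelse(e$universe$classes == "specific:A", "A-specific",
                 ifelse(e$universe$classes == "specific:B", "B-specific",
                        "shared/ns"))
  expect_equal(unname(got[names(want)]), unname(want))
})

test_that("both thresholds must hold for a differential call", {
  set.seed(51)
  n <- 200
  vals <- matrix(rlnorm(n * 6, 4, 0.1), n,
                 dimnames = list(sprintf("p%d", 1:n),
                                 c(paste0("A", 1:3), paste0("B", 1:3))))
  # strong but sub-threshold fold change (2^1.5 < 4): must stay shared/ns
  vals[1, 1:3] <- vals[1, 1:3] * 2^1.5
  groups <- setNames(rep(c("A", "B"), each = 3), colnames(vals))
  da <- call_differential_peaks(vals, groups)
  expect_equal(da$label[1], "shared/ns")
  expect_error(call_differential_peaks(vals[, c(1, 2, 4, 5)],
                                       groups[c(1, 2, 4, 5)]), NA)
  expect_error(call_differential_peaks(vals[, c(1, 4, 5)], groups[c(1, 4, 5)]),
               "fewer than 2")
})

test_that("under a global null the q < 0.05 discovery fraction stays at the FDR", {
  set.seed(61)
  n <- 4000
  a <- matrix(rnorm(n * 3, 5), n)
  b <- matrix(rnorm(n * 3, 5), n)
  q <- bh_fdr(atacmix:::row_welch(a, b)$p)
  frac <- mean(q < 0.05)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lte(frac, 0.05 + 3 * se)
})

test_that("condition number equals the singular value ratio", {
  expect_equal(condition_number(diag(2)), 1)
  expect_equal(condition_number(diag(c(10, 1))), 10)
  expect_equal(condition_number(matrix(c(1, 1, 1, 1), 2)), Inf)
  set.seed(71)
  m <- matrix(rlnorm(100), 50, 2)
  # independent route: eigenvalues of the cross-product matrix
  ev <- eigen(crossprod(m), only.values = TRUE)$values
  expect_equal(condition_number(m), sqrt(ev[1] / ev[2]))
  expect_error(condition_number(matrix(1, 1, 2)), "at least as many")
})

test_that("signature size minimizes the condition number over the grid", {
  p <- tiny_params(frac_specific = 0.15)
  e <- simulate_mixture_experiment(p)
  norm <- normalize_cpm(cbind_counts(e$pure, e$mixtures))
  sig <- select_signature_matrix(norm, e$groups, g_grid = 5:20)
  expect_s3_class(sig, "signature_matrix")

  # brute-force recomputation of kappa across the whole grid
  by_group <- split(names(e$groups), e$groups)
  med <- sapply(by_group, function(ss) apply(norm$values[, ss], 1, median))
  kappas <- sapply(5:20, function(g) {
    peaks <- unique(unlist(lapply(sig$tests, function(te) {
      cand <- te[te$q < 0.30 & te$log2fc > 0, ]
      head(cand$peak_id[order(-cand$log2fc)], g)
    })))
    condition_number(med[peaks, names(by_group)])
  })
  expect_equal(sig$kappa, min(kappas))
  expect_equal(sig$g, (5:20)[which.min(kappas)])

  # every signature peak is significant with fold change toward its type
  for (ty in names(sig$peaks_by_type)) {
    te <- sig$tests[[ty]]
    rows <- te[match(sig$peaks_by_type[[ty]], te$peak_id), ]
    expect_true(all(rows$q < 0.30))
    expect_true(all(rows$log2fc > 0))
  }
})

test_that("signature medians are invariant to replicate order", {
  p <- tiny_params()
  e <- simulate_mixture_experiment(p)
  norm <- normalize_cpm(e$pure)
  sig1 <- select_signature_matrix(norm, e$groups, g_grid = 5:15)
  perm <- c("A_rep3", "A_rep1", "A_rep2", "B_rep2", "B_rep3", "B_rep1")
  norm2 <- norm
  norm2$values <- norm$values[, perm]
  sig2 <- select_signature_matrix(norm2, e$groups[perm], g_grid = 5:15)
  expect_equal(sig1$values, sig2$values)
})

test_that("identical cell types yield no signature", {
  set.seed(81)
  base <- matrix(rpois(300 * 6, 50), 300,
                 dimnames = list(sprintf("p%d", 1:300),
                                 c(paste0("A", 1:3), paste0("B", 1:3))))
  groups <- setNames(rep(c("A", "B"), each = 3), colnames(base))
  norm <- normalize_cpm(peak_counts(base))
  expect_error(select_signature_matrix(norm, groups, g_grid = 5:10),
               "too few qualifying")
})
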