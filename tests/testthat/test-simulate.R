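test_that("parameter validation names the offending field", {
  expect_error(sim_params(frac_specific = c(0.7, 0.5)), "frac_specific")
  expect_error(sim_params(frac_specific = -0.1), "frac_specific")
  expect_error(sim_params(n_peaks = 0), "n_peaks")
  expect_error(sim_params(depth = 1.5e6 + 0.3), "depth")
  expect_error(sim_params(background_factor = 1.2), "background_factor")
  # log2(5 / 0.5) = 3.32 > 2 is fine; log2(3/0.9) = 1.74 is not
  expect_silent(sim_params(fold_factor = 5))
  expect_error(sim_params(fold_factor = 3, background_factor = 0.9),
               "exceed 2")
})

test_that("peak class counts follow the rounding rule exactly", {
  set.seed(1)
  p <- sim_params(n_peaks = 10, frac_specific = 0.2, depth = 1000)
  u <- generate_peak_universe(p)
  expect_equal(sum(u$classes == "specific:A"), 2)
  expect_equal(sum(u$classes == "specific:B"), 2)
  expect_equal(sum(u$classes == "shared"), 6)

  # specific peaks carry the fold/background structure relative to baseline
  a_spec <- names(u$classes)[u$classes == "specific:A"]
  expect_equal(u$intensity[a_spec, "A"] / u$intensity[a_spec, "B"],
               rep(p$fold_factor / p$background_factor, 2),
               ignore_attr = TRUE)
})

test_that("synthetic coordinates are non-overlapping 500 bp peaks on chrS", {
  set.seed(1)
  u <- generate_peak_universe(sim_params(n_peaks = 50, depth = 1000))
  pk <- u$peaks
  expect_s3_class(pk, "peak_set")
  expect_true(all(pk$end - pk$start == 500))
  expect_true(all(pk$start[-1] >= pk$end[-nrow(pk)]))
  expect_true(all(pk$chrom == "chrS"))
})

test_that("baseline intensities follow the configured log-normal", {
  set.seed(7)
  p <- sim_params(n_peaks = 20000, frac_specific = 0, depth = 1000)
  u <- generate_peak_universe(p)
  logs <- log(u$intensity[, "A"])
  se <- sd(logs) / sqrt(length(logs))
  expect_lt(abs(mean(logs) - p$base_mean_log_mu), 3 * se)
  expect_lt(abs(sd(logs) - p$base_mean_log_sigma), 0.03)
})

test_that("simulation is bit-identical under a fixed seed", {
  e1 <- simulate_mixture_experiment(tiny_params())
  e2 <- simulate_mixture_experiment(tiny_params())
  expect_identical(e1$pure$counts, e2$pure$counts)
  expect_identical(e1$mixtures$counts, e2$mixtures$counts)
  expect_identical(e1$universe$intensity, e2$universe$intensity)
})

test_that("negative binomial counts have the configured mean structure", {
  # one peak with accessibility share 1e-4 at depth 5e6 -> mean 500; the
  # sample mean over 2000 replicate draws must sit within 3 standard errors
  p <- sim_params(n_peaks = 2, depth = 5e6, n_replicates = 2000,
                  frac_specific = 0, nb_dispersion = 0.05)
  set.seed(99)
  u <- generate_peak_universe(p)
  u$intensity[, ] <- c(1e-4, 1 - 1e-4) # exact shares by construction
  pure <- generate_pure_counts(p, u)
  draws <- pure$counts$counts[1, 1:2000]
  mu <- 5e6 * 1e-4
  se <- sqrt(mu + p$nb_dispersion * mu^2) / sqrt(2000)
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("zero dispersion gives Poisson-like counts and column sums near depth", {
  p <- tiny_params(nb_dispersion = 0)
  e <- simulate_mixture_experiment(p)
  cnt <- e$pure$counts
  # variance/mean over replicates, averaged across peaks, is ~1 for Poisson
  shares <- sweep(e$universe$intensity, 2, colSums(e$universe$intensity), "/")
  mu <- p$depth * shares[, "A"]
  z <- (cnt[, "A_rep1"] - mu) / sqrt(mu)
  expect_lt(abs(mean(z^2) - 1), 0.15)
  expect_lt(abs(sum(cnt[, "A_rep1"]) / p$depth - 1), 0.01)
})

test_that("mixture expectations are the f-weighted combination of pure expectations", {
  set.seed(3)
  p <- sim_params(n_peaks = 60, frac_specific = 0.2, depth = 1e4)
  u <- generate_peak_universe(p)
  design <- mixture_design(rbind(c(0.2, 0.8), c(1, 0), c(0.5, 0.5)),
                           p$cell_types)
  E <- expected_counts(u, design, p$depth)
  shares <- sweep(u$intensity, 2, colSums(u$intensity), "/")
  pureE <- p$depth * shares
  # checked analytically from stored intensities, not by sampling
  expect_equal(E[, 1], 0.2 * pureE[, "A"] + 0.8 * pureE[, "B"])
  expect_equal(E[, 2], pureE[, "A"])

  # hand evaluation of the weighted-sum formula for one specific:A peak
  pk <- names(u$classes)[u$classes == "specific:A"][1]
  base <- u$intensity[pk, "B"] / p$background_factor
  byhand <- p$depth * (0.2 * p$fold_factor * base / sum(u$intensity[, "A"]) +
                       0.8 * p$background_factor * base / sum(u$intensity[, "B"]))
  expect_equal(E[pk, 1], byhand, ignore_attr = TRUE)
})

test_that("degenerate mixtures reproduce pure generation exactly under one seed", {
  p <- tiny_params()
  set.seed(5)
  u <- generate_peak_universe(p)
  set.seed(17)
  pureA <- generate_mixture_counts(p, u, mixture_design(matrix(c(1, 0), 1),
                                                        p$cell_types))
  set.seed(17)
  d <- diag(2); rownames(d) <- c("a", "b")
  both <- generate_mixture_counts(p, u, mixture_design(d, p$cell_types))
  expect_identical(unname(pureA$counts[, 1]), unname(both$counts[, "a"]))
})

test_that("invalid mixture designs are rejected", {
  expect_error(mixture_design(matrix(c(0.5, 0.7), 1)), "sum to 1")
  expect_error(mixture_design(matrix(c(-0.2, 1.2), 1)), "non-negative")
})

test_that("binomial thinning behaves like a depth fraction", {
  p <- tiny_params()
  e <- simulate_mixture_experiment(p)
  counts <- e$pure

  set.seed(2)
  same <- downsample_counts(counts, counts$lib_sizes)
  expect_identical(same$counts, counts$counts)

  set.seed(2)
  zero <- downsample_counts(counts, 0, samples = "A_rep1")
  expect_true(all(zero$counts[, "A_rep1"] == 0))

  set.seed(2)
  thin <- downsample_counts(counts, round(0.3 * counts$lib_sizes))
  expect_true(all(thin$counts <= counts$counts))
  expect_true(all(thin$counts[counts$counts == 0] == 0))

  expect_error(downsample_counts(counts, counts$lib_sizes + 1), "exceeds")

  # binomial expectation: count 1000 thinned at p = 0.2 over 1000 replicates
  big <- peak_counts(matrix(1000, 1000, 1,
                            dimnames = list(sprintf("p%d", 1:1000), "s")))
  set.seed(4)
  th <- downsample_counts(big, round(0.2 * big$lib_sizes))
  se <- sqrt(1000 * 0.2 * 0.8) / sqrt(1000)
  expect_lt(abs(mean(th$counts) - 200), 3 * se)
})
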