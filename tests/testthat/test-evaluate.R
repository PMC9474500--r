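test_that("MLE uncertainty bound matches the inverse-Gamma closed form", {
  set.seed(71)
  for (n in c(10, 100, 1000)) {
    b <- mle_uncertainty_lower_bound(0.5, n, n_replicates = 1e5)
    expect_equal(b$sd_absolute, mle_sd_closed_form(0.5, n), tolerance = 0.01)
  }
  expect_error(mle_uncertainty_lower_bound(0.5, 2), ">= 3")
  expect_error(mle_uncertainty_lower_bound(-1, 10), "> 0")

  # large-n limit: relative SD tends to 1/sqrt(n)
  expect_equal(mle_sd_closed_form(1, 1e6), 1 / sqrt(1e6), tolerance = 0.05)

  # scale equivariance: doubling k doubles the absolute SD only
  set.seed(72)
  b1 <- mle_uncertainty_lower_bound(0.1, 50, 2e4)
  set.seed(72)
  b2 <- mle_uncertainty_lower_bound(0.2, 50, 2e4)
  expect_equal(b2$sd_absolute / b1$sd_absolute, 2, tolerance = 1e-10)
  expect_equal(b2$sd_relative, b1$sd_relative, tolerance = 1e-10)
})

test_that("dwell CDF of a two-state model matches the analytic exponential", {
  m <- kinetic_model(rbind(c(0, 0.2), c(0.5, 0)), fret = c(0.3, 0.7))
  set.seed(73)
  cd <- cumulative_dwell_cdf(m, oversample_factor = 60,
                             reference_points = 5000, frame_period = 0.2)
  # expected dwells per class: total time x entry flux pi_2 * k21
  p <- stationary_distribution(m)
  expected <- 60 * 5000 * 0.2 * p[[2]] * m$rates[2, 1]
  expect_gte(min(cd$n_dwells), 0.8 * expected)
  for (cl in 1:2) {
    k_exit <- sum(m$rates[cl, ])
    analytic <- 1 - exp(-k_exit * cd$times)
    # KS 1% critical band for the simulated sample size
    band <- 1.63 / sqrt(cd$n_dwells[cl])
    expect_lt(max(abs(cd$cdf[, cl] - analytic)), band)
    expect_true(all(diff(cd$cdf[, cl]) >= 0))
  }
})

test_that("dwell CDF merges degenerate FRET states into one class", {
  het <- heterogeneous_four_state()
  set.seed(74)
  cd <- cumulative_dwell_cdf(het$model, fret_tolerance = 0.05,
                             oversample_factor = 10,
                             reference_points = 2000, frame_period = 0.2)
  expect_equal(ncol(cd$cdf), 2L)
  expect_equal(cd$class_fret, c(0.3, 0.7))
  # the low-E class mixes a fast and a slow pathway: its CDF lies above a
  # single-exponential with the class-average exit rate at short times
  cls <- fretkin:::fret_classes(het$model$fret, 0.05)
  expect_equal(max(cls), 2L)
})

test_that("oversampling changes precision, not the distribution", {
  m <- kinetic_model(rbind(c(0, 0.2), c(0.5, 0)), fret = c(0.3, 0.7))
  set.seed(75)
  lo <- cumulative_dwell_cdf(m, oversample_factor = 5,
                             reference_points = 2000, frame_period = 0.2)
  hi <- cumulative_dwell_cdf(m, oversample_factor = 50,
                             reference_points = 2000, frame_period = 0.2,
                             times = lo$times)
  # agreement limited by the sparser sample's own sampling error
  expect_lt(max(abs(lo$cdf - hi$cdf), na.rm = TRUE),
            1.7 / sqrt(min(lo$n_dwells)))
})

test_that("SNR from Gaussian mixture fit matches the generating parameters", {
  set.seed(76)
  e <- c(stats::rnorm(6000, 0.2, 0.1), stats::rnorm(4000, 0.8, 0.1))
  res <- snr_from_fret(e)
  expect_equal(res$snr, 0.6 / (0.1 * sqrt(2)), tolerance = 0.02 * 4.243)
  expect_equal(res$means, c(0.2, 0.8), tolerance = 0.01)

  # a single population has no resolvable separation: any 2-component
  # decomposition leaves the means within the combined component width
  set.seed(77)
  same <- stats::rnorm(5000, 0.5, 0.1)
  res2 <- snr_from_fret(same)
  expect_lt(res2$snr, 1)

  expect_error(snr_from_fret(stats::rnorm(10)), "too few")
})

test_that("percent deviation is exact, order-invariant and mismatch-aware", {
  gt <- kinetic_model(rbind(c(0, 0.10), c(0.20, 0)), fret = c(0.3, 0.7))
  expect_equal(percent_deviation(gt, gt)$max_rate, 0)
  expect_equal(percent_deviation(gt, gt)$max_fret, 0)

  inf <- kinetic_model(rbind(c(0, 0.11), c(0.20, 0)), fret = c(0.3, 0.7))
  d <- percent_deviation(inf, gt)
  expect_equal(d$rate_deviation[1, 2], 10)
  expect_equal(d$max_rate, 10)
  expect_equal(d$mean_rate, 5)

  # permuted input states canonicalize to the same result
  inf_perm <- kinetic_model(rbind(c(0, 0.20), c(0.11, 0)), fret = c(0.7, 0.3))
  expect_equal(percent_deviation(inf_perm, gt), d)

  three <- driven_three_state()$model
  expect_true(percent_deviation(three, gt)$mismatch)
})

test_that("coefficient of variation uses the sample SD", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  v <- c(0.8, 1.1, 1.4)
  expect_equal(coefficient_of_variation(v * 7), coefficient_of_variation(v))
  expect_error(coefficient_of_variation(1), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  # two submissions at (0.1, 0.1) and (0.12, 0.12): CV ~ 12.9% per rate
  expect_equal(100 * coefficient_of_variation(c(0.1, 0.12)), 12.86, tolerance = 0.01)
})

test_that("benchmark report assembles deviations, CVs and plausibility flags", {
  gt <- kinetic_model(rbind(c(0, 0.10), c(0.20, 0)), fret = c(0.3, 0.7))
  rep0 <- benchmark_report(gt, gt, cdf_oversample = 0)
  expect_equal(rep0$deviations[[1]]$max_rate, 0)
  expect_equal(rep0$equilibrium_constants, 2)

  m1 <- kinetic_model(rbind(c(0, 0.10), c(0.20, 0)), fret = c(0.3, 0.7))
  m2 <- kinetic_model(rbind(c(0, 0.12), c(0.24, 0)), fret = c(0.3, 0.7))
  rep2 <- benchmark_report(gt, list(m1, m2), cdf_oversample = 0)
  expect_equal(100 * rep2$cv[1, 2], 12.86, tolerance = 0.01)
  expect_equal(100 * rep2$cv[2, 1], 12.86, tolerance = 0.01)

  # a CI narrower than the finite-data lower bound gets flagged
  arc <- two_state_archetype(n_traces = 12, max_length = 100, seed = 81)
  ds <- simulate_dataset(arc$model, arc$config)
  fit <- fit_ensemble_hmm(ds, 2, restarts = 1, seed = 11)
  fit$ci95 <- list(level = 95,
                   low = fit$rates * 0.999, high = fit$rates * 1.001,
                   draws = NULL, failed_refits = 0L)
  set.seed(82)
  rep3 <- benchmark_report(arc$model, fit, dataset = ds, cdf_oversample = 0,
                           lower_bound_replicates = 2e3)
  flags <- rep3$ci_flags[[1]]
  expect_true(all(vapply(flags, `[[`, logical(1), "implausibly_narrow")))
})

test_that("simulate-infer loop recovers the sign of the cycle free energy", {
  drv <- driven_three_state(n_traces = 20, max_length = 80, seed = 1)
  n_neg <- 0L
  n_runs <- 20L
  for (s in seq_len(n_runs)) {
    cfg <- drv$config
    cfg$seed <- 9000 + s
    ds <- simulate_dataset(drv$model, cfg)
    fit <- fit_ensemble_hmm(ds, 3, restarts = 1, seed = s, max_iter = 300)
    dg <- tryCatch(
      cycle_flow_free_energy(as_kinetic_model(fit), 1:3)$delta_g,
      error = function(e) NA_real_)
    if (is.finite(dg) && dg < 0) n_neg <- n_neg + 1L
  }
  expect_gte(n_neg, ceiling(0.95 * n_runs))
})

test_that("systematic analysis shifts cancel in the equilibrium constant", {
  # re-analyzing the same data on a coarser time base shifts both rate
  # constants systematically; their ratio K is nearly unchanged because
  # the common factor cancels
  arc <- two_state_archetype(n_traces = 40, seed = 610)
  ds <- simulate_dataset(arc$model, arc$config)
  fit <- fit_ensemble_hmm(ds, 2, restarts = 1, seed = 1)
  sub <- lapply(ds$traces, function(tr) tr$fret[seq(1, length(tr$fret), by = 3)])
  fit3 <- fit_ensemble_hmm(sub, 2, frame_period = 3 / 5, restarts = 1, seed = 1)

  rel <- function(a, b) abs(a - b) / mean(c(a, b))
  d12 <- rel(fit$rates[1, 2], fit3$rates[1, 2])
  d21 <- rel(fit$rates[2, 1], fit3$rates[2, 1])
  dK <- rel(fit$rates[2, 1] / fit$rates[1, 2],
            fit3$rates[2, 1] / fit3$rates[1, 2])
  expect_lt(dK, min(d12, d21))
})
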