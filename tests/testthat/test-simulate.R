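test_that("trace lengths follow rejection-plus-truncation of the bleach law", {
  expect_equal(draw_trace_length(0.5, 25, 25, n = 5), rep(25, 5))

  set.seed(101)
  d <- draw_trace_length(0.01, 10, 1000, n = 1e5)
  expect_true(all(d >= 10 & d <= 1000))

  # independent rejection + truncation sampler
  set.seed(202)
  keep <- numeric(0)
  while (length(keep) < 1e5) {
    x <- stats::rexp(2e5, 0.01)
    keep <- c(keep, x[x >= 10])
  }
  oracle <- pmin(keep[1:1e5], 1000)
  expect_equal(mean(d), mean(oracle), tolerance = 0.01)
})

test_that("initial states are drawn from the stationary distribution", {
  m <- kinetic_model(rbind(c(0, 0.3), c(0.1, 0)), fret = c(0.3, 0.7))
  set.seed(5)
  s <- draw_initial_state(m, n = 1e5)
  expect_equal(mean(s == 1L), 0.25, tolerance = 0.02)

  sym <- kinetic_model(rbind(c(0, 0.2), c(0.2, 0)), fret = c(0.3, 0.7))
  set.seed(6)
  expect_equal(mean(draw_initial_state(sym, 1e5) == 1L), 0.5, tolerance = 0.02)

  one <- kinetic_model(matrix(0, 1, 1), fret = 0.4)
  expect_equal(draw_initial_state(one, 10), rep(1L, 10))
})

test_that("state paths have exponential dwells and correct branching", {
  m <- kinetic_model(rbind(c(0, 0.1), c(0.5, 0)), fret = c(0.3, 0.7))
  set.seed(11)
  d1 <- numeric(0)
  for (i in 1:60) {
    p <- simulate_state_path(m, 2000)
    durs <- diff(c(p$entry_times, p$duration))
    inner <- durs[-c(1L, length(durs))]
    d1 <- c(d1, inner[p$states[-c(1L, length(durs))] == 1L])
  }
  expect_gt(length(d1), 5000)
  expect_equal(mean(d1), 10, tolerance = 0.02)
  # pooled uncensored dwells pass a KS test against Exponential(k12)
  ks <- suppressWarnings(stats::ks.test(d1[1:10^4], "pexp", 0.1))
  expect_gt(ks$p.value, 0.01)

  one <- kinetic_model(matrix(0, 1, 1), fret = 0.4)
  p1 <- simulate_state_path(one, 50)
  expect_equal(p1$states, 1L)
  expect_equal(p1$entry_times, 0)

  # branching from state 1: k12/(k12+k13) = 2/3
  k <- matrix(0, 3, 3)
  k[1, 2] <- 0.2; k[1, 3] <- 0.1
  k[2, 1] <- 1; k[3, 1] <- 1
  m3 <- kinetic_model(k, fret = c(0.2, 0.5, 0.8))
  set.seed(12)
  to2 <- 0L; tot <- 0L
  for (i in 1:40) {
    p <- simulate_state_path(m3, 3000, initial_state = 1L)
    st <- p$states
    from1 <- which(st[-length(st)] == 1L)
    tot <- tot + length(from1)
    to2 <- to2 + sum(st[from1 + 1L] == 2L)
  }
  expect_equal(to2 / tot, 2 / 3, tolerance = 0.03)
})

test_that("discretization yields exact per-frame occupancy fractions", {
  const <- structure(list(states = 2L, entry_times = 0, duration = 3),
                     class = "state_path")
  occ <- discretize_path(const, 5)
  expect_equal(nrow(occ), 15L)
  expect_true(all(occ[, 2] == 1))

  # transition exactly at the midpoint of frame 3 (frames of 0.2 s)
  mid <- structure(list(states = c(1L, 2L), entry_times = c(0, 0.5),
                        duration = 1), class = "state_path")
  occ2 <- discretize_path(mid, 5)
  expect_equal(occ2[3, ], c(0.5, 0.5))
  expect_equal(occ2[1, ], c(1, 0))
  expect_equal(occ2[5, ], c(0, 1))

  set.seed(13)
  m <- kinetic_model(rbind(c(0, 1), c(2, 0)), fret = c(0.3, 0.7))
  for (i in 1:20) {
    p <- simulate_state_path(m, stats::runif(1, 1, 20))
    occ <- discretize_path(p, 7)
    expect_equal(nrow(occ), floor(p$duration * 7))
    if (nrow(occ)) expect_equal(rowSums(occ), rep(1, nrow(occ)), tolerance = 1e-12)
  }
})

test_that("per-trace mean jitter has the specified scale and no bias", {
  expect_equal(perturb_state_means(matrix(100, 1, 1), 0), matrix(100, 1, 1))
  # truncation-free regime: mean far from zero in units of the jitter SD
  mu <- matrix(1e4, 1, 1)
  set.seed(21)
  draws <- replicate(1e5, perturb_state_means(mu, 5)[1, 1])
  expect_equal(stats::sd(draws), 5 * sqrt(1e4), tolerance = 0.02)
  expect_equal(mean(draws), 1e4, tolerance = 0.01)
  # near zero the resampling of negative draws keeps means physical
  set.seed(22)
  low <- replicate(2e3, perturb_state_means(matrix(100, 1, 1), 5)[1, 1])
  expect_true(all(low >= 0))
  expect_gt(mean(low), 100)  # truncation shifts the mean up slightly
})

test_that("brightness factors are bounded powers of the base", {
  expect_equal(1.20^0, 1)
  expect_equal(1.20^-1, 0.8333, tolerance = 1e-4)
  set.seed(22)
  f <- draw_brightness_factor(1.20, n = 1e5)
  expect_true(all(f >= 1 / 1.20 & f <= 1.20))
  expect_error(draw_brightness_factor(0.9), "must be > 1")
})

test_that("blinking is a two-state process with the right dark fraction", {
  set.seed(23)
  b <- simulate_blinking(1e5, list(donor = c(0.01, 0.09),
                                   acceptor = c(0, 1)))
  expect_equal(b$acceptor$states, 1L)  # never dark with zero to-dark rate
  p <- b$donor
  durs <- diff(c(p$entry_times, p$duration))
  dark_frac <- sum(durs[p$states == 2L]) / p$duration
  expect_equal(dark_frac, 0.1, tolerance = 0.15)
})

test_that("trace emission reproduces means, mixing and channel independence", {
  mu <- rbind(c(100, 300, 50), c(200, 100, 50))
  covs <- list(diag(c(25, 25, 1)), diag(c(25, 25, 1)))
  occ <- matrix(0, 2e4, 2); occ[, 1] <- 1
  set.seed(31)
  tr <- emit_trace(occ, mu, covs, sampling_rate = 5, trace_id = "t")
  expect_equal(mean(tr$donor), 100, tolerance = 0.005)
  expect_equal(mean(tr$acceptor), 300, tolerance = 0.005)
  expect_lt(abs(stats::cor(tr$donor, tr$acceptor)), 0.03)
  expect_equal(tr$fret, tr$acceptor / (tr$donor + tr$acceptor))

  # 50/50 frame between state means 100 and 200 -> expected 150
  occ2 <- matrix(0.5, 2e4, 2)
  set.seed(32)
  tr2 <- emit_trace(occ2, mu, covs, sampling_rate = 5)
  expect_equal(mean(tr2$donor), 150, tolerance = 0.01)
})

test_that("FRET efficiency is the proximity ratio with undefined frames NA", {
  expect_equal(compute_fret(50, 50), 0.5)
  expect_equal(compute_fret(0, 70), 1.0)
  expect_equal(compute_fret(30, 70), 0.7)
  expect_true(is.na(compute_fret(0, 0)))
  expect_true(is.na(compute_fret(-10, 5)))
})

test_that("datasets are deterministic per seed and match stationary occupancy", {
  arc <- two_state_archetype(n_traces = 10, max_length = 100, seed = 77)
  ds1 <- simulate_dataset(arc$model, arc$config)
  ds2 <- simulate_dataset(arc$model, arc$config)
  d1 <- tempfile(); d2 <- tempfile()
  write_traces(ds1, d1); write_traces(ds2, d2)
  f1 <- list.files(d1, pattern = "csv$")
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)

  # frame-occupancy fractions track the stationary distribution
  occ <- Reduce(`+`, lapply(ds1$ground_truth, function(g)
    colSums(discretize_path(g$path, arc$config$sampling_rate))))
  p_emp <- occ / sum(occ)
  p_true <- stationary_distribution(arc$model)
  expect_equal(unname(p_emp[1]), unname(p_true[1]), tolerance = 0.08)
})

test_that("acceptor-dark periods drive the apparent FRET to zero", {
  arc <- two_state_archetype(n_traces = 4, max_length = 80, seed = 5)
  cfg <- arc$config
  cfg$enable_blinking <- TRUE
  cfg$blink_rates <- list(donor = c(0, 1), acceptor = c(0.05, 0.05))
  ds <- simulate_dataset(arc$model, cfg)
  fret_dark <- unlist(lapply(seq_along(ds$traces), function(i) {
    occ <- fretkin:::blink_combo_occupancy(
      ds$ground_truth[[i]]$blinking, length(ds$traces[[i]]$fret),
      cfg$sampling_rate)
    ds$traces[[i]]$fret[occ[, 2] == 1]  # frames fully acceptor-dark
  }))
  expect_gt(length(fret_dark), 50)
  expect_lt(abs(mean(fret_dark)), 0.05)
})

test_that("clean two-state FRET histogram is a two-Gaussian mixture with pi weights", {
  arc <- two_state_archetype(n_traces = 30, seed = 99)
  ds <- simulate_dataset(arc$model, arc$config)
  pooled <- unlist(lapply(ds$traces, `[[`, "fret"))
  e_ok <- pooled[is.finite(pooled)]
  km <- stats::kmeans(e_ok, centers = c(0.3, 0.7))
  fit <- mclust::emV(
    data = e_ok,
    parameters = list(pro = km$size / length(e_ok),
                      mean = as.numeric(km$centers),
                      variance = list(modelName = "V", d = 1, G = 2,
                                      sigmasq = c(0.005, 0.005))))
  w <- fit$parameters$pro[order(fit$parameters$mean)]
  p_true <- unname(stationary_distribution(arc$model))
  expect_lt(abs(w[1] - p_true[1]), 0.02)
  expect_lt(abs(w[2] - p_true[2]), 0.02)
})
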