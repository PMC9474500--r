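# Benchmark statistics: finite-data uncertainty lower bound, model-implied
# cumulative dwell-time distributions, SNR, deviation and CV metrics, and
# the ground-truth-vs-inferred report.

#' Finite-data lower bound on rate-constant uncertainty
#'
#' Even a perfect analysis cannot beat the sampling noise of a finite dwell
#' sample: with `n_dwells` exponential dwells at true rate `k`, replicate
#' maximum-likelihood estimates `1/mean(dwells)` scatter with standard
#' deviation `k * n / ((n - 1) * sqrt(n - 2))` (the MLE is inverse-Gamma
#' distributed). This function measures that scatter by Monte-Carlo
#' replication and returns it as the lower bound against which reported
#' uncertainties can be judged: a confidence interval narrower than this
#' bound is implausible.
#'
#' @param rate true rate constant in 1/s.
#' @param n_dwells dwells per replicate set (>= 3; the closed-form SD is
#'   undefined below that).
#' @param n_replicates number of replicate MLE draws (default 1e5; 1e6
#'   halves the Monte-Carlo error at 10x the cost).
#' @return An object of class `uncertainty_bound`: `rate`, `n_dwells`,
#'   `n_replicates`, `sd_absolute` (1/s), `sd_relative` (fraction of `k`)
#'   and `sd_closed_form`.
#' @export
mle_uncertainty_lower_bound <- function(rate, n_dwells, n_replicates = 1e5) {
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  n_dwells <- as.integer(round(n_dwells))
  if (n_dwells < 3L)
    stop("n_dwells must be >= 3 (MLE variance undefined below)", call. = FALSE)
  n_replicates <- as.integer(n_replicates)
  # chunked so 1e6 replicates of large n stay within memory
  chunk <- max(1L, min(n_replicates, floor(2e7 / n_dwells)))
  est <- numeric(n_replicates)
  done <- 0L
  while (done < n_replicates) {
    m <- min(chunk, n_replicates - done)
    d <- matrix(stats::rexp(m * n_dwells, rate), nrow = m)
    est[done + seq_len(m)] <- 1 / rowMeans(d)
    done <- done + m
  }
  sd_abs <- stats::sd(est)
  structure(
    list(rate = rate, n_dwells = n_dwells, n_replicates = n_replicates,
         sd_absolute = sd_abs, sd_relative = sd_abs / rate,
         sd_closed_form = mle_sd_closed_form(rate, n_dwells)),
    class = "uncertainty_bound")
}

#' Closed-form SD of the exponential-rate MLE
#'
#' The sum of `n` exponential dwells at rate `k` is Gamma(`n`, `k`), so the
#' MLE `n / sum` is inverse-Gamma with standard deviation
#' `k * n / ((n - 1) * sqrt(n - 2))`, about `k / sqrt(n)` for large `n`.
#'
#' @inheritParams mle_uncertainty_lower_bound
#' @return SD of the MLE in 1/s.
#' @export
mle_sd_closed_form <- function(rate, n_dwells) {
  n <- n_dwells
  if (any(n < 3)) stop("closed form requires n_dwells >= 3", call. = FALSE)
  rate * n / ((n - 1) * sqrt(n - 2))
}

#' @export
print.uncertainty_bound <- function(x, ...) {
  cat(sprintf("MLE uncertainty lower bound: k = %g /s, n = %d dwells\n",
              x$rate, x$n_dwells))
  cat(sprintf("  SD = %.4g /s (%.2f%% of k) from %d replicates; closed form %.4g /s\n",
              x$sd_absolute, 100 * x$sd_relative, x$n_replicates,
              x$sd_closed_form))
  invisible(x)
}

# group states whose FRET efficiencies agree within tol (greedy on sorted E)
fret_classes <- function(fret, tol = 0.05) {
  ord <- order(fret)
  cls <- integer(length(fret))
  cur <- 1L
  cls[ord[1L]] <- 1L
  anchor <- fret[ord[1L]]
  for (i in seq_along(ord)[-1L]) {
    if (fret[ord[i]] - anchor > tol) { cur <- cur + 1L; anchor <- fret[ord[i]] }
    cls[ord[i]] <- cur
  }
  cls
}

#' Cumulative dwell-time distribution implied by a kinetic model
#'
#' Characterizes a kinetic model by the dwell-time distribution an observer
#' of FRET classes would see: continuous-time state paths are simulated from
#' the model, hidden states whose FRET efficiencies agree within
#' `fret_tolerance` are merged into one apparent class (so transitions
#' inside a class do not interrupt a dwell), and the empirical CDF of the
#' per-class residence times is evaluated on a log-spaced grid. Models with
#' hidden kinetic heterogeneity yield multi-exponential class dwells that a
#' single-exponential model cannot reproduce -- the basis for comparing
#' inferred models with the same apparent states but different hidden
#' structure. Simulated path length is `oversample_factor` times
#' `reference_points` frame periods, heavily oversampling the data the model
#' was inferred from.
#'
#' @param model a `kinetic_model` (or `inferred_model`).
#' @param fret_tolerance merge hidden states with `|dE| <=` this value.
#' @param oversample_factor how many times `reference_points` of simulated
#'   time to accumulate (typical values 200 or 400).
#' @param reference_points size of the reference dataset in frames.
#' @param frame_period seconds per frame of the reference grid.
#' @param grid_points number of log-spaced CDF evaluation times.
#' @param times optional explicit evaluation-time grid (seconds); overrides
#'   `grid_points` so several models can be compared on one grid.
#' @return Object of class `dwell_cdf`: `times`, per-class `cdf` matrix,
#'   `n_dwells` per class, `class_fret`, `oversample_factor`.
#' @export
cumulative_dwell_cdf <- function(model, fret_tolerance = 0.05,
                                 oversample_factor = 200,
                                 reference_points = 1000,
                                 frame_period = 0.2,
                                 grid_points = 200, times = NULL) {
  model <- as_kinetic_model(model)
  if (oversample_factor < 1) stop("oversample_factor must be >= 1", call. = FALSE)
  cls <- fret_classes(model$fret, fret_tolerance)
  n_cls <- max(cls)
  if (n_cls == 1L && model$n_states > 1L)
    warning("FRET tolerance merges all states into one class")
  total_time <- oversample_factor * reference_points * frame_period
  # simulate in manageable segments; boundary dwells dropped as censored
  seg_time <- min(total_time, max(1000 * frame_period, 200 / max(model$rates)))
  dwells <- rep(list(numeric(0)), n_cls)
  acc <- 0
  while (acc < total_time) {
    L <- min(seg_time, total_time - acc)
    p <- simulate_state_path(model, L)
    acc <- acc + L
    cpath <- cls[p$states]
    keep <- c(TRUE, cpath[-1L] != cpath[-length(cpath)])
    cstates <- cpath[keep]
    centry <- p$entry_times[keep]
    if (length(cstates) < 3L) next
    durs <- diff(c(centry, L))
    for (i in seq.int(2L, length(cstates) - 1L))
      dwells[[cstates[i]]] <- c(dwells[[cstates[i]]], durs[i])
  }
  if (is.null(times)) {
    slowest <- 1 / min(model$rates[model$rates > 0])
    times <- exp(seq(log(frame_period / 10), log(10 * slowest),
                     length.out = grid_points))
  }
  cdf <- vapply(seq_len(n_cls), function(cl) {
    if (!length(dwells[[cl]])) return(rep(NA_real_, grid_points))
    stats::ecdf(dwells[[cl]])(times)
  }, numeric(grid_points))
  class_fret <- vapply(seq_len(n_cls), function(cl)
    mean(model$fret[cls == cl]), numeric(1))
  structure(
    list(times = times, cdf = cdf,
         n_dwells = vapply(dwells, length, integer(1)),
         class_fret = class_fret, classes = cls,
         oversample_factor = oversample_factor),
    class = "dwell_cdf")
}

#' @export
print.dwell_cdf <- function(x, ...) {
  cat("Cumulative dwell-time distribution over", ncol(x$cdf), "FRET class(es)\n")
  for (cl in seq_along(x$class_fret))
    cat(sprintf("  class %d (E ~ %.2f): %d dwells\n", cl, x$class_fret[cl],
                x$n_dwells[cl]))
  invisible(x)
}

#' @export
plot.dwell_cdf <- function(x, ..., log = "x") {
  graphics::matplot(x$times, x$cdf, type = "l", lty = 1, log = log,
                    xlab = "dwell time (s)", ylab = "cumulative probability",
                    main = "Cumulative dwell-time distribution", ...)
  graphics::legend("bottomright", bty = "n", lty = 1,
                   col = seq_along(x$class_fret),
                   legend = sprintf("E ~ %.2f", x$class_fret))
  invisible(x)
}

#' Signal-to-noise ratio of a FRET histogram
#'
#' Fits an `n_components` Gaussian mixture (unequal variances) to the
#' pooled FRET efficiencies by expectation-maximization with k-means
#' initialization, and reports
#' `SNR = |mu1 - mu2| / sqrt(sigma1^2 + sigma2^2)` for the two dominant
#' (largest-weight) components.
#'
#' @param e_values pooled FRET efficiencies.
#' @param n_components number of mixture components (>= 2).
#' @param restarts jittered EM restarts; the best log-likelihood is kept.
#' @return List with `snr`, `means`, `sds`, `weights` (all components,
#'   sorted by mean), `dominant` (indices used for the SNR) and `loglik`.
#' @export
snr_from_fret <- function(e_values, n_components = 2, restarts = 10) {
  e_values <- e_values[is.finite(e_values)]
  if (length(e_values) < 2 * n_components * 10)
    stop("too few FRET values for a ", n_components, "-component fit",
         call. = FALSE)
  km <- stats::kmeans(e_values, centers = n_components, nstart = 10)
  ord0 <- order(km$centers)
  mu0 <- as.numeric(km$centers)[ord0]
  s20 <- as.numeric(tapply(e_values, km$cluster, stats::var))[ord0]
  s20[!is.finite(s20) | s20 < 1e-8] <- 1e-4
  w0 <- (km$size / length(e_values))[ord0]
  best <- NULL
  for (r in seq_len(max(1L, restarts))) {
    mu_r <- if (r == 1L) mu0 else mu0 + stats::rnorm(n_components, 0, 0.02)
    fit <- tryCatch(mclust::emV(
      data = e_values,
      parameters = list(pro = w0, mean = mu_r,
                        variance = list(modelName = "V", d = 1,
                                        G = n_components, sigmasq = s20))),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$loglik) &&
        (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) stop("Gaussian mixture fit did not converge", call. = FALSE)
  mu <- as.numeric(best$parameters$mean)
  sd_ <- sqrt(as.numeric(best$parameters$variance$sigmasq))
  if (length(sd_) == 1L) sd_ <- rep(sd_, n_components)
  w <- as.numeric(best$parameters$pro)
  ord <- order(mu)
  mu <- mu[ord]; sd_ <- sd_[ord]; w <- w[ord]
  dom <- sort(order(w, decreasing = TRUE)[1:2])
  snr <- abs(mu[dom[1]] - mu[dom[2]]) / sqrt(sd_[dom[1]]^2 + sd_[dom[2]]^2)
  list(snr = snr, means = mu, sds = sd_, weights = w, dominant = dom,
       loglik = best$loglik)
}

#' Percent deviation of an inferred model from the ground truth
#'
#' After both models are brought to canonical state order, every rate
#' constant present in the ground truth is compared as
#' `100 * |k_inf - k_gt| / k_gt`, and FRET efficiencies likewise. Models
#' with mismatched state counts are not compared numerically; a structured
#' mismatch report is returned instead.
#'
#' @param inferred,gt `kinetic_model`s (or `inferred_model`s).
#' @return List with `rate_deviation` (matrix, % per ground-truth rate),
#'   `fret_deviation` (% per state), `max_rate`, `mean_rate`, `max_fret`,
#'   `mean_fret`; or a list with `mismatch = TRUE` and both state counts.
#' @export
percent_deviation <- function(inferred, gt) {
  inferred <- as_kinetic_model(inferred)
  gt <- as_kinetic_model(gt)
  if (inferred$n_states != gt$n_states)
    return(list(mismatch = TRUE, n_states_inferred = inferred$n_states,
                n_states_gt = gt$n_states))
  idx <- which(gt$rates > 0, arr.ind = TRUE)
  dev <- matrix(NA_real_, gt$n_states, gt$n_states)
  dev[idx] <- 100 * abs(inferred$rates[idx] - gt$rates[idx]) / gt$rates[idx]
  fret_dev <- 100 * abs(inferred$fret - gt$fret) / gt$fret
  list(mismatch = FALSE,
       rate_deviation = dev, fret_deviation = fret_dev,
       max_rate = max(dev, na.rm = TRUE), mean_rate = mean(dev, na.rm = TRUE),
       max_fret = max(fret_dev), mean_fret = mean(fret_dev))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean: the
#' consistency measure used to compare results across analyses when no
#' ground truth exists.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return The CV (a fraction; multiply by 100 for percent).
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean", call. = FALSE)
  stats::sd(values) / m
}

#' Benchmark report: inferred models against ground truth
#'
#' Assembles the full evaluation of one or more inferred kinetic models:
#' percent deviations from the ground truth (when available), per-rate
#' coefficients of variation across submissions, equilibrium constants,
#' cycle free energies, the dataset's SNR, sup-norm distances between
#' model-implied cumulative dwell distributions and the ground truth's, and
#' plausibility flags for reported confidence intervals narrower than the
#' finite-data MLE lower bound.
#'
#' @param gt ground-truth `kinetic_model`, or `NULL` for the no-ground-truth
#'   (CV-only) mode used with experimental data.
#' @param inferred a single model or list of `inferred_model` /
#'   `kinetic_model` objects.
#' @param dataset optional `fret_dataset` (enables the SNR and dwell-count
#'   based lower bound).
#' @param fret_tolerance class-merging tolerance for the dwell CDFs.
#' @param cdf_oversample oversampling factor for dwell CDFs (0 skips them).
#' @param lower_bound_replicates Monte-Carlo replicates for the MLE bound.
#' @return Object of class `benchmark_report`.
#' @export
benchmark_report <- function(gt, inferred, dataset = NULL,
                             fret_tolerance = 0.05, cdf_oversample = 50,
                             lower_bound_replicates = 1e4) {
  if (!is.list(inferred) || inherits(inferred, c("inferred_model", "kinetic_model")))
    inferred <- list(inferred)
  models <- lapply(inferred, as_kinetic_model)
  has_gt <- !is.null(gt)
  if (has_gt) gt <- as_kinetic_model(gt)

  deviations <- if (has_gt) lapply(models, percent_deviation, gt = gt) else NULL

  # CV across submissions, per ground-truth (or first-model) rate position
  ref <- if (has_gt) gt else models[[1L]]
  cv <- NULL
  matched <- vapply(models, function(m) m$n_states == ref$n_states, logical(1))
  if (sum(matched) >= 2L) {
    idx <- which(ref$rates > 0, arr.ind = TRUE)
    cv <- matrix(NA_real_, ref$n_states, ref$n_states)
    for (r in seq_len(nrow(idx))) {
      vals <- vapply(models[matched], function(m) m$rates[idx[r, 1], idx[r, 2]],
                     numeric(1))
      if (mean(vals) > 0) cv[idx[r, 1], idx[r, 2]] <- coefficient_of_variation(vals)
    }
  }

  eq_constants <- lapply(models, function(m) {
    if (m$n_states == 2L && m$rates[1, 2] > 0)
      equilibrium_constant(m$rates[1, 2], m$rates[2, 1]) else NA_real_
  })

  delta_g <- lapply(models, function(m) {
    if (m$n_states < 3L) return(NA_real_)
    tryCatch(cycle_flow_free_energy(m, seq_len(m$n_states))$delta_g,
             error = function(e) NA_real_)
  })
  delta_g_gt <- if (has_gt && ref$n_states >= 3L)
    tryCatch(cycle_flow_free_energy(gt, seq_len(gt$n_states))$delta_g,
             error = function(e) NA_real_) else NA_real_

  snr <- NULL
  if (!is.null(dataset)) {
    pooled <- unlist(lapply(dataset$traces, `[[`, "fret"))
    snr <- tryCatch(snr_from_fret(pooled), error = function(e) NULL)
  }

  # plausibility: reported CI half-width vs finite-data lower bound
  ci_flags <- NULL
  if (!is.null(dataset)) {
    n_frames_total <- n_frames(dataset)
    ci_flags <- lapply(seq_along(inferred), function(i) {
      m <- inferred[[i]]
      if (!inherits(m, "inferred_model") || is.null(m$ci95)) return(NULL)
      km <- models[[i]]
      pi_hat <- tryCatch(stationary_distribution(km), error = function(e) NULL)
      if (is.null(pi_hat)) return(NULL)
      total_time <- n_frames_total * m$frame_period
      flags <- list()
      for (a in seq_len(km$n_states)) for (b in seq_len(km$n_states)) {
        k <- km$rates[a, b]
        if (a == b || k <= 0) next
        n_dw <- expected_dwell_count(km, a, total_time, pi_hat)
        if (n_dw < 3) next
        lb <- mle_uncertainty_lower_bound(k, n_dw, lower_bound_replicates)
        half <- (m$ci95$high[a, b] - m$ci95$low[a, b]) / 2
        flags[[sprintf("k%d%d", a, b)]] <- list(
          rate = k, ci_half_width = half, lower_bound_sd = lb$sd_absolute,
          implausibly_narrow = is.finite(half) && half < lb$sd_absolute)
      }
      flags
    })
  }

  cdfs <- NULL; cdf_sup_dist <- NULL
  if (has_gt && cdf_oversample > 0) {
    fp <- if (!is.null(dataset)) 1 / dataset$config$sampling_rate else 0.2
    npts <- if (!is.null(dataset)) n_frames(dataset) else 1000
    npts <- min(npts, 5000)  # reference scale for the oversampled simulation
    gt_cdf <- cumulative_dwell_cdf(gt, fret_tolerance, cdf_oversample, npts, fp)
    cdfs <- lapply(models, function(m)
      tryCatch(cumulative_dwell_cdf(m, fret_tolerance, cdf_oversample, npts, fp,
                                    times = gt_cdf$times),
               error = function(e) NULL))
    cdf_sup_dist <- vapply(cdfs, function(cd) {
      if (is.null(cd) || ncol(cd$cdf) != ncol(gt_cdf$cdf)) return(NA_real_)
      max(abs(cd$cdf - gt_cdf$cdf), na.rm = TRUE)
    }, numeric(1))
    cdfs <- c(list(gt = gt_cdf), cdfs)
  }

  structure(
    list(has_gt = has_gt, n_models = length(models),
         deviations = deviations, cv = cv,
         equilibrium_constants = unlist(eq_constants),
         delta_g = unlist(delta_g), delta_g_gt = delta_g_gt,
         snr = snr, ci_flags = ci_flags,
         dwell_cdfs = cdfs, cdf_sup_dist = cdf_sup_dist),
    class = "benchmark_report")
}

# expected number of completed dwells in state `a` during total_time
expected_dwell_count <- function(model, a, total_time, pi_hat) {
  k_exit <- sum(model$rates[a, ])
  round(pi_hat[[a]] * total_time * k_exit)
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark report over", x$n_models, "inferred model(s)",
      if (x$has_gt) "(ground truth available)\n" else "(no ground truth: CV mode)\n")
  if (!is.null(x$deviations)) {
    for (i in seq_along(x$deviations)) {
      d <- x$deviations[[i]]
      if (isTRUE(d$mismatch)) {
        cat(sprintf("  model %d: state-count mismatch (%d vs GT %d)\n", i,
                    d$n_states_inferred, d$n_states_gt))
      } else {
        cat(sprintf("  model %d: max rate dev %.1f%%, mean %.1f%%; max FRET dev %.1f%%\n",
                    i, d$max_rate, d$mean_rate, d$max_fret))
      }
    }
  }
  if (!is.null(x$cv))
    cat("  CV across submissions (max):",
        sprintf("%.1f%%", 100 * max(x$cv, na.rm = TRUE)), "\n")
  if (!is.null(x$snr)) cat(sprintf("  dataset SNR: %.2f\n", x$snr$snr))
  if (any(is.finite(x$delta_g)))
    cat(sprintf("  delta G (kBT): %s%s\n",
                paste(round(x$delta_g[is.finite(x$delta_g)], 3), collapse = ", "),
                if (is.finite(x$delta_g_gt))
                  paste0(" (GT ", round(x$delta_g_gt, 3), ")") else ""))
  if (!is.null(x$cdf_sup_dist))
    cat("  dwell-CDF sup distance to GT:",
        paste(round(x$cdf_sup_dist, 3), collapse = ", "), "\n")
  if (!is.null(x$ci_flags)) {
    for (i in seq_along(x$ci_flags)) {
      fl <- x$ci_flags[[i]]
      if (is.null(fl)) next
      bad <- names(fl)[vapply(fl, `[[`, logical(1), "implausibly_narrow")]
      if (length(bad))
        cat(sprintf("  model %d: CI narrower than finite-data bound for %s\n",
                    i, paste(bad, collapse = ", ")))
    }
  }
  invisible(x)
}
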