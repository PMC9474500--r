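#' Fit a kinetic model to smFRET traces
#'
#' The main modelling entry point: fits an ensemble hidden Markov model with
#' Gaussian FRET emissions to a dataset of single-molecule traces and
#' returns a fitted-model object with the usual accessor methods. When
#' `n_states` is missing the number of states is chosen by BIC over
#' `1:max_states`. Dwell times and their exponential maximum-likelihood
#' rates are computed alongside the HMM transition-matrix rates, giving two
#' complementary routes to the kinetics.
#'
#' @param data a `fret_dataset` (from [simulate_dataset()] or
#'   [read_traces()]), a list of `fret_trace` objects, or a list of numeric
#'   FRET vectors (then `frame_period` is required).
#' @param n_states number of hidden states; `NULL` selects by BIC.
#' @param max_states upper bound for BIC model selection.
#' @param emission_groups optional list of integer vectors tying the
#'   emission parameters of hidden-state groups (kinetic heterogeneity).
#' @param restarts jittered EM restarts per candidate.
#' @param boot number of parametric-bootstrap replicates for rate-constant
#'   confidence intervals; 0 skips the bootstrap.
#' @param level confidence level in percent for the bootstrap interval.
#' @param frame_period seconds per frame, if not stored in `data`.
#' @param seed integer seed for initialization and bootstrap.
#' @param ... passed to [fit_ensemble_hmm()] (`max_iter`, `tol`).
#' @return An object of class `fret_fit` wrapping the `inferred_model`
#'   together with idealized paths, the dwell set and dwell-based rates.
#' @examples
#' arc <- two_state_archetype(n_traces = 8, max_length = 60, seed = 2)
#' ds <- simulate_dataset(arc$model, arc$config)
#' fit <- fit_kinetics(ds, n_states = 2)
#' coef(fit)
#' @export
fit_kinetics <- function(data, n_states = NULL, max_states = 3,
                         emission_groups = NULL, restarts = 5, boot = 0,
                         level = 95, frame_period = NULL, seed = 1L, ...) {
  cl <- match.call()
  frame_period <- dataset_frame_period(data, frame_period)
  model <- if (is.null(n_states)) {
    select_model(data, max_states = max_states, restarts = restarts,
                 seed = seed, frame_period = frame_period, ...)
  } else {
    fit_ensemble_hmm(data, n_states, emission_groups = emission_groups,
                     restarts = restarts, seed = seed,
                     frame_period = frame_period, ...)
  }
  if (boot > 0) model <- bootstrap_ci(model, data, n_boot = boot,
                                      level = level, seed = seed)
  paths <- viterbi_paths(model, data)
  dwells <- extract_dwells(paths, frame_period)
  structure(
    list(model = model, paths = paths, dwells = dwells,
         dwell_rates = dwell_rate_matrix(dwells, model$n_states),
         data = data, frame_period = frame_period, call = cl),
    class = "fret_fit")
}

# per-transition exponential MLE rates from uncensored dwells:
# k_ij = (n_ij / n_i.) / mean(dwell in i), the branching-weighted exit rate
dwell_rate_matrix <- function(dwells, K) {
  out <- matrix(NA_real_, K, K)
  u <- dwells[!dwells$censored, , drop = FALSE]
  for (i in seq_len(K)) {
    di <- u[u$from_state == i, , drop = FALSE]
    if (!nrow(di)) next
    k_exit <- exponential_mle(di$duration)
    for (j in seq_len(K)) {
      if (j == i) next
      out[i, j] <- k_exit * sum(di$to_state == j) / nrow(di)
    }
  }
  diag(out) <- 0
  out
}

#' @export
print.fret_fit <- function(x, ...) {
  cat("Kinetic fit of", length(x$paths), "smFRET traces (",
      x$model$n_frames, "frames at", signif(1 / x$frame_period, 4), "Hz )\n")
  print(x$model)
  invisible(x)
}

#' @export
summary.fret_fit <- function(object, ...) {
  m <- object$model
  u <- object$dwells[!object$dwells$censored, , drop = FALSE]
  out <- list(
    n_traces = length(object$paths),
    n_frames = m$n_frames,
    n_states = m$n_states,
    fret = data.frame(state = seq_len(m$n_states),
                      mean = m$fret_means, sd = m$fret_sds,
                      occupancy = as.numeric(table(factor(
                        unlist(object$paths), levels = seq_len(m$n_states)))) /
                        sum(lengths(object$paths))),
    rates_hmm = m$rates,
    rates_dwell = object$dwell_rates,
    n_dwells_uncensored = nrow(u),
    equilibrium_constant = if (m$n_states == 2L)
      equilibrium_constant(m$rates[1, 2], m$rates[2, 1]) else NULL,
    loglik = m$loglik, bic = m$bic,
    bic_table = attr(m, "bic_table"),
    ci95 = m$ci95,
    converged = m$converged)
  class(out) <- "summary.fret_fit"
  out
}

#' @export
print.summary.fret_fit <- function(x, ...) {
  cat("Ensemble smFRET kinetic fit\n")
  cat(sprintf("  %d traces, %d frames, %d state(s); logL = %.2f, BIC = %.2f\n",
              x$n_traces, x$n_frames, x$n_states, x$loglik, x$bic))
  cat("\nFRET states:\n")
  print(transform(x$fret, mean = round(mean, 4), sd = round(sd, 4),
                  occupancy = round(occupancy, 3)), row.names = FALSE)
  cat("\nRate constants (1/s), transition-matrix route:\n")
  print(round(x$rates_hmm, 5))
  cat("\nRate constants (1/s), dwell-time route (",
      x$n_dwells_uncensored, "uncensored dwells ):\n")
  print(round(x$rates_dwell, 5))
  if (!is.null(x$equilibrium_constant))
    cat("\nEquilibrium constant K = k21/k12:",
        round(x$equilibrium_constant, 4), "\n")
  if (!is.null(x$bic_table)) {
    cat("\nModel selection:\n"); print(x$bic_table, row.names = FALSE)
  }
  if (!is.null(x$ci95))
    cat("\nBootstrap", paste0(x$ci95$level, "%"), "CI attached (see confint())\n")
  invisible(x)
}

#' @export
coef.fret_fit <- function(object, type = c("rates", "fret", "transition"), ...) {
  type <- match.arg(type)
  switch(type,
         rates = object$model$rates,
         fret = stats::setNames(object$model$fret_means,
                                paste0("S", seq_len(object$model$n_states))),
         transition = object$model$A)
}

#' @export
logLik.fret_fit <- function(object, ...) {
  structure(object$model$loglik, df = object$model$n_params,
            nobs = object$model$n_frames, class = "logLik")
}

#' @export
confint.fret_fit <- function(object, parm, level = 0.95, ...) {
  ci <- object$model$ci95
  if (is.null(ci))
    stop("no bootstrap interval attached; refit with boot > 0 or call bootstrap_ci()",
         call. = FALSE)
  K <- object$model$n_states
  idx <- which(upper.tri(matrix(0, K, K)) | lower.tri(matrix(0, K, K)),
               arr.ind = TRUE)
  out <- data.frame(
    rate = sprintf("k%d%d", idx[, 1], idx[, 2]),
    estimate = object$model$rates[idx],
    low = ci$low[idx], high = ci$high[idx])
  out[order(out$rate), ]
}

#' Idealized state paths of a fitted kinetic model
#'
#' `predict()` returns the Viterbi-decoded state sequence of every trace --
#' with `type = "fret"` the corresponding sequence of fitted state FRET
#' means (the idealized trace).
#'
#' @param object a `fret_fit`.
#' @param newdata optional new traces to decode under the fitted parameters.
#' @param type `"states"` for integer paths, `"fret"` for idealized FRET.
#' @param ... unused.
#' @return List of vectors, one per trace.
#' @export
predict.fret_fit <- function(object, newdata = NULL,
                             type = c("states", "fret"), ...) {
  type <- match.arg(type)
  paths <- if (is.null(newdata)) object$paths
           else viterbi_paths(object$model, newdata)
  if (type == "states") return(paths)
  lapply(paths, function(p) object$model$fret_means[p])
}

#' @export
residuals.fret_fit <- function(object, ...) {
  series <- fret_series(object$data)
  mapply(function(x, p) x - object$model$fret_means[p],
         series, object$paths, SIMPLIFY = FALSE)
}

#' Re-simulate data from a fitted kinetic model
#'
#' The consistency test for an inferred model: simulate synthetic datasets
#' from the fitted rate constants and FRET parameters at the original trace
#' count and sampling rate, for comparison with the input data (histograms,
#' dwell distributions) or for re-analysis.
#'
#' @param object a `fret_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param total_intensity photon budget used to re-emit intensity traces.
#' @param ... unused.
#' @return A `fret_dataset` (or list of them when `nsim > 1`).
#' @export
simulate.fret_fit <- function(object, nsim = 1, seed = 1L,
                              total_intensity = 1000, ...) {
  m <- object$model
  km <- as_kinetic_model(m)
  fret_sd <- mean(m$fret_sds)
  n_tr <- length(object$paths)
  mean_len <- mean(lengths(object$paths)) * object$frame_period
  cfg <- simulation_config(
    sampling_rate = 1 / object$frame_period,
    bleach_rate = 1 / mean_len,
    min_length = max(object$frame_period * 2,
                     min(lengths(object$paths)) * object$frame_period),
    max_length = max(lengths(object$paths)) * object$frame_period,
    n_traces = n_tr,
    emission_means = fret_emission_means(km$fret, total_intensity),
    emission_cov = fret_emission_cov(km$fret, total_intensity, fret_sd),
    seed = seed)
  simulate.kinetic_model(km, nsim = nsim, seed = seed, config = cfg)
}

#' Plot a fitted smFRET kinetic model
#'
#' `which = "histogram"` draws the pooled FRET-efficiency histogram with the
#' fitted per-state Gaussian components; `which = "trace"` draws one trace's
#' FRET time series with its Viterbi-idealized path on top.
#'
#' @param x a `fret_fit`.
#' @param which `"histogram"` or `"trace"`.
#' @param trace index of the trace to draw when `which = "trace"`.
#' @param ... passed to the underlying plotting functions.
#' @return Invisibly, `x`.
#' @export
plot.fret_fit <- function(x, which = c("histogram", "trace"), trace = 1L, ...) {
  which <- match.arg(which)
  m <- x$model
  series <- fret_series(x$data)
  if (which == "histogram") {
    pooled <- unlist(series)
    pooled <- pooled[is.finite(pooled)]
    h <- graphics::hist(pooled, breaks = 60, freq = FALSE,
                        main = "FRET efficiency histogram",
                        xlab = "FRET efficiency", border = "grey70", ...)
    occ <- tabulate_frequencies(x$paths, m$n_states)
    xs <- seq(min(h$breaks), max(h$breaks), length.out = 400)
    for (k in seq_len(m$n_states))
      graphics::lines(xs, occ[k] * stats::dnorm(xs, m$fret_means[k], m$fret_sds[k]),
                      col = k + 1, lwd = 2)
    graphics::legend("top", bty = "n", lwd = 2, col = seq_len(m$n_states) + 1,
                     legend = sprintf("E = %.2f", m$fret_means))
  } else {
    e <- series[[trace]]
    t_s <- (seq_along(e) - 1) * x$frame_period
    graphics::plot(t_s, e, type = "l", col = "grey50", ylim = c(-0.1, 1.1),
                   xlab = "time (s)", ylab = "FRET efficiency",
                   main = paste("Trace", trace), ...)
    graphics::lines(t_s, m$fret_means[x$paths[[trace]]], col = 2, lwd = 2)
  }
  invisible(x)
}
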