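# Ensemble HMM inference on FRET traces: one shared Gaussian-emission
# parameter set estimated across all traces by Baum-Welch, then Viterbi
# idealization, dwell extraction and rate conversion.

# pull FRET vectors out of a dataset / list of traces / list of vectors
fret_series <- function(traces) {
  if (inherits(traces, "fret_dataset")) traces <- traces$traces
  lapply(traces, function(tr) {
    if (inherits(tr, "fret_trace")) tr$fret else as.numeric(tr)
  })
}

dataset_frame_period <- function(traces, frame_period = NULL) {
  if (!is.null(frame_period)) return(frame_period)
  if (inherits(traces, "fret_dataset")) return(1 / traces$config$sampling_rate)
  tr1 <- traces[[1L]]
  if (inherits(tr1, "fret_trace")) return(1 / tr1$sampling_rate)
  stop("frame_period must be given when traces are bare numeric vectors",
       call. = FALSE)
}

#' Cluster frames into FRET states by k-means
#'
#' Pools the FRET efficiencies of all traces and partitions them into
#' `n_states` clusters by k-means, relabelled in ascending order of the
#' cluster mean. Used to initialize the ensemble HMM and as a simple
#' stand-alone state assignment.
#'
#' @param traces a `fret_dataset`, list of `fret_trace`, or list of numeric
#'   FRET vectors.
#' @param n_states number of states (>= 1).
#' @param nstart random restarts passed to [stats::kmeans()].
#' @return List with `labels` (per-trace integer vectors, `NA` for frames
#'   with undefined FRET), `means` and `sds` (per state).
#' @export
kmeans_state_assignment <- function(traces, n_states, nstart = 10) {
  series <- fret_series(traces)
  pooled <- unlist(series, use.names = FALSE)
  ok <- is.finite(pooled)
  x <- pooled[ok]
  if (n_states < 1L) stop("n_states must be >= 1", call. = FALSE)
  if (length(unique(x)) < n_states)
    stop("fewer distinct FRET values than requested states", call. = FALSE)
  if (n_states == 1L) {
    lab <- rep(1L, length(x))
    centers <- mean(x)
  } else {
    km <- stats::kmeans(x, centers = stats::quantile(x, seq(0.1, 0.9, length.out = n_states)),
                        nstart = nstart, iter.max = 100)
    ord <- order(km$centers)
    relabel <- match(seq_len(n_states), ord)
    lab <- relabel[km$cluster]
    centers <- sort(as.numeric(km$centers))
  }
  sds <- vapply(seq_len(n_states), function(k) {
    v <- stats::sd(x[lab == k])
    if (!is.finite(v) || v < 1e-4) 1e-2 else v
  }, numeric(1))
  full <- rep(NA_integer_, length(pooled))
  full[ok] <- lab
  lens <- lengths(series)
  split_labels <- split(full, rep(seq_along(series), lens))
  names(split_labels) <- NULL
  list(labels = split_labels, means = centers, sds = sds)
}

#' Fit an ensemble hidden Markov model to FRET traces
#'
#' Baum-Welch expectation-maximization with a single shared parameter set
#' (per-state Gaussian FRET mean and SD, transition matrix, initial
#' distribution) across all traces: forward-backward statistics are computed
#' per trace and summed before each M-step, so every molecule contributes to
#' one ensemble kinetic model. Frames with undefined FRET (zero total
#' intensity) are masked out of the likelihood. The fitted transition matrix
#' (per frame period) is converted to rate constants via the principal
#' matrix logarithm (see [transition_probs_to_rates()]).
#'
#' States may optionally be tied into emission groups sharing one mean and
#' SD (`emission_groups`), the device needed to resolve kinetic
#' heterogeneity: several hidden states with indistinguishable FRET
#' efficiencies but different kinetics.
#'
#' @inheritParams kmeans_state_assignment
#' @param init optional list with `means`, `sds`, `A`, `pi` to start from;
#'   defaults to k-means initialization with a 0.95-diagonal transition
#'   matrix.
#' @param max_iter,tol EM stopping rule: stop when the relative
#'   log-likelihood change drops below `tol` or after `max_iter` iterations.
#' @param emission_groups optional list of integer vectors partitioning the
#'   states; states in one group share their emission mean and SD.
#' @param frame_period seconds per frame; inferred from the dataset when
#'   possible.
#' @param restarts number of jittered restarts (best log-likelihood kept).
#' @param seed integer seed for initialization jitter.
#' @return An object of class `inferred_model`: per-state `fret_means` and
#'   `fret_sds`, transition matrix `A` (per frame), `initial`, derived
#'   `rates` (1/s), `loglik`, `bic`, `n_frames`, `n_params`, convergence
#'   metadata, and the `loglik_trace` of the best run.
#' @export
fit_ensemble_hmm <- function(traces, n_states, init = NULL, max_iter = 1000,
                             tol = 1e-6, emission_groups = NULL,
                             frame_period = NULL, restarts = 1, seed = NULL) {
  frame_period <- dataset_frame_period(traces, frame_period)
  series <- fret_series(traces)
  series <- series[lengths(series) >= 1L]
  if (!length(series)) stop("no traces with frames to fit", call. = FALSE)
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  if (is.null(init)) {
    if (is.null(emission_groups)) {
      ka <- kmeans_state_assignment(series, n_states)
      init <- list(means = ka$means, sds = ka$sds,
                   A = init_transition_matrix(n_states),
                   pi = tabulate_frequencies(ka$labels, n_states))
    } else {
      # tied emissions: cluster into the apparent FRET classes, then give
      # each hidden state its group's emission parameters; kinetic
      # differentiation within a group must come from the transition
      # structure, so the transition matrix is randomized per restart
      ka <- kmeans_state_assignment(series, length(emission_groups))
      means <- numeric(n_states); sds <- numeric(n_states)
      for (g in seq_along(emission_groups)) {
        means[emission_groups[[g]]] <- ka$means[g]
        sds[emission_groups[[g]]] <- ka$sds[g]
      }
      init <- list(means = means, sds = sds,
                   A = random_transition_matrix(n_states),
                   pi = rep(1 / n_states, n_states))
    }
  }
  best <- NULL
  for (r in seq_len(max(1L, restarts))) {
    ini <- init
    if (r > 1L) {
      ini$means <- ini$means + stats::runif(n_states, -0.02, 0.02)
      ini$A <- random_transition_matrix(n_states)
    }
    fit <- tryCatch(
      baum_welch(series, n_states, ini, max_iter, tol, emission_groups),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) stop("all HMM restarts failed", call. = FALSE)
  finalize_inferred_model(best, n_states, frame_period, emission_groups)
}

init_transition_matrix <- function(K, diag_p = 0.95) {
  if (K == 1L) return(matrix(1, 1, 1))
  A <- matrix((1 - diag_p) / (K - 1), K, K)
  diag(A) <- diag_p
  A
}

# diagonal-dominant stochastic matrix with randomized off-diagonal split
# and mildly varied self-transition, used to break symmetry across restarts
random_transition_matrix <- function(K) {
  if (K == 1L) return(matrix(1, 1, 1))
  A <- matrix(0, K, K)
  for (i in seq_len(K)) {
    p_stay <- stats::runif(1, 0.85, 0.99)
    w <- stats::runif(K - 1L)
    A[i, -i] <- (1 - p_stay) * w / sum(w)
    A[i, i] <- p_stay
  }
  A
}

tabulate_frequencies <- function(labels, K) {
  tb <- tabulate(unlist(labels, use.names = FALSE), nbins = K)
  if (sum(tb) == 0) rep(1 / K, K) else tb / sum(tb)
}

# core EM loop; emission densities in R, recursions in C++
baum_welch <- function(series, K, init, max_iter, tol, emission_groups) {
  means <- init$means; sds <- pmax(init$sds, 1e-4)
  A <- init$A; pi0 <- init$pi / sum(init$pi)
  masks <- lapply(series, is.finite)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ll <- 0
    xi_sum <- matrix(0, K, K)
    pi_sum <- numeric(K)
    w_sum <- numeric(K); wx_sum <- numeric(K); wx2_sum <- numeric(K)
    for (i in seq_along(series)) {
      x <- series[[i]]; m <- masks[[i]]
      B <- matrix(1, length(x), K)
      if (any(m))
        B[m, ] <- vapply(seq_len(K), function(k)
          stats::dnorm(x[m], means[k], sds[k]), numeric(sum(m)))
      B[B < 1e-300] <- 1e-300
      fb <- .fb_cpp(B, A, pi0)
      ll <- ll + fb$loglik
      xi_sum <- xi_sum + fb$xi
      pi_sum <- pi_sum + fb$gamma[1L, ]
      g <- fb$gamma[m, , drop = FALSE]
      xm <- x[m]
      w_sum <- w_sum + colSums(g)
      wx_sum <- wx_sum + as.numeric(crossprod(g, xm))
      wx2_sum <- wx2_sum + as.numeric(crossprod(g, xm^2))
    }
    if (!is.finite(ll))
      stop("non-finite log-likelihood at EM iteration ", iter, call. = FALSE)
    ll_trace <- c(ll_trace, ll)
    if (iter > 1L && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M-step
    if (K > 1L) {
      rs <- rowSums(xi_sum)
      upd <- rs > 0
      A[upd, ] <- xi_sum[upd, , drop = FALSE] / rs[upd]
    }
    pi0 <- pi_sum / sum(pi_sum)
    mu_new <- ifelse(w_sum > 0, wx_sum / w_sum, means)
    var_new <- ifelse(w_sum > 0, wx2_sum / w_sum - mu_new^2, sds^2)
    if (!is.null(emission_groups)) {
      for (grp in emission_groups) {
        w <- sum(w_sum[grp])
        if (w > 0) {
          mu_g <- sum(wx_sum[grp]) / w
          var_g <- sum(wx2_sum[grp]) / w - mu_g^2
          mu_new[grp] <- mu_g; var_new[grp] <- var_g
        }
      }
    }
    means <- mu_new
    sds <- sqrt(pmax(var_new, 1e-8))
  }
  list(means = means, sds = sds, A = A, pi = pi0, loglik = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace, iterations = length(ll_trace),
       converged = converged, n_frames = sum(vapply(masks, sum, integer(1))))
}

finalize_inferred_model <- function(fit, K, frame_period, emission_groups) {
  ord <- order(fit$means, -(1 - diag(fit$A)))
  means <- fit$means[ord]; sds <- fit$sds[ord]
  A <- fit$A[ord, ord, drop = FALSE]
  pi0 <- fit$pi[ord]
  conv <- transition_probs_to_rates(A, frame_period)
  n_params <- count_free_params(K, emission_groups)
  model <- structure(
    list(n_states = K, fret_means = means, fret_sds = sds,
         A = A, initial = pi0,
         rates = conv$rates, rate_method = conv$method,
         loglik = fit$loglik, n_frames = fit$n_frames,
         n_params = n_params,
         bic = bic(fit$loglik, n_params, fit$n_frames),
         frame_period = frame_period,
         iterations = fit$iterations, converged = fit$converged,
         loglik_trace = fit$loglik_trace,
         emission_groups = emission_groups, ci95 = NULL),
    class = "inferred_model")
  model
}

# free parameters: emission means + SDs (per tied group where grouped),
# K*(K-1) transition probabilities, K-1 initial probabilities
count_free_params <- function(K, emission_groups = NULL) {
  n_emission_sets <- if (is.null(emission_groups)) K else length(emission_groups)
  2L * n_emission_sets + K * (K - 1L) + (K - 1L)
}

#' @export
print.inferred_model <- function(x, ...) {
  cat("Ensemble HMM:", x$n_states, "state(s),", x$n_frames, "frames, logL =",
      format(x$loglik, digits = 8), "\n")
  cat("FRET means:", paste(sprintf("%.3f (sd %.3f)", x$fret_means, x$fret_sds),
                           collapse = ", "), "\n")
  if (x$n_states > 1L) {
    cat("Rate constants (1/s, via", x$rate_method, "):\n")
    print(round(x$rates, 5))
  }
  cat("BIC:", format(x$bic, digits = 8), "| converged:", x$converged,
      "in", x$iterations, "iterations\n")
  invisible(x)
}

#' Convert an inferred model to a kinetic model
#'
#' @param x an `inferred_model`.
#' @param ... unused.
#' @return A [kinetic_model()] carrying the derived rate constants and
#'   inferred FRET efficiencies (clamped to `[0, 1]`).
#' @export
as_kinetic_model <- function(x, ...) UseMethod("as_kinetic_model")

#' @export
as_kinetic_model.inferred_model <- function(x, ...) {
  kinetic_model(x$rates, fret = pmin(pmax(x$fret_means, 0), 1))
}

#' @export
as_kinetic_model.kinetic_model <- function(x, ...) x

#' Viterbi-idealized state sequences
#'
#' Decodes each trace into its single most probable hidden-state sequence
#' under the fitted model (maximum a posteriori path). Frames with undefined
#' FRET carry no emission information and are decoded from the transition
#' structure alone.
#'
#' @param inferred an `inferred_model`.
#' @inheritParams kmeans_state_assignment
#' @return List of integer state sequences, one per trace.
#' @export
viterbi_paths <- function(inferred, traces) {
  series <- fret_series(traces)
  K <- inferred$n_states
  logA <- log(pmax(inferred$A, 1e-300))
  logpi <- log(pmax(inferred$initial, 1e-300))
  lapply(series, function(x) {
    if (!length(x)) return(integer(0))
    m <- is.finite(x)
    logB <- matrix(0, length(x), K)
    if (any(m))
      logB[m, ] <- vapply(seq_len(K), function(k)
        stats::dnorm(x[m], inferred$fret_means[k], inferred$fret_sds[k], log = TRUE),
        numeric(sum(m)))
    .viterbi_cpp(logB, logA, logpi)
  })
}

#' Extract censoring-annotated dwell times from idealized paths
#'
#' Each maximal run of a constant state becomes one dwell record. The first
#' and last run of every trace are flagged as censored: their true duration
#' is cut off by the start of the observation or by photobleaching, so they
#' would bias a naive exponential fit and are excluded from rate estimation.
#'
#' @param paths list of integer state sequences (e.g. from
#'   [viterbi_paths()]).
#' @param frame_period seconds per frame.
#' @return A data frame of class `dwell_set` with columns `from_state`,
#'   `to_state` (`NA` when censored), `duration` (s), `censored`, `trace`;
#'   `frame_period` stored as an attribute.
#' @export
extract_dwells <- function(paths, frame_period) {
  recs <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    if (!length(p)) return(NULL)
    r <- rle(p)
    n <- length(r$values)
    censored <- seq_len(n) %in% c(1L, n)
    data.frame(from_state = r$values,
               to_state = c(r$values[-1L], NA_integer_),
               duration = r$lengths * frame_period,
               censored = censored,
               trace = i)
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(from_state = integer(0), to_state = integer(0),
                      duration = numeric(0), censored = logical(0),
                      trace = integer(0))
  out$to_state[out$censored] <- NA_integer_
  attr(out, "frame_period") <- frame_period
  class(out) <- c("dwell_set", "data.frame")
  out
}

#' Maximum-likelihood rate from exponential dwell times
#'
#' For exponentially distributed dwell times the maximum-likelihood
#' estimator of the rate constant is the reciprocal of the mean dwell:
#' `k = 1 / mean(dwells)`.
#'
#' @param dwells positive uncensored dwell durations in seconds.
#' @return Rate constant in 1/s.
#' @export
exponential_mle <- function(dwells) {
  dwells <- as.numeric(dwells)
  if (!length(dwells)) stop("no uncensored dwells to fit", call. = FALSE)
  if (any(!is.finite(dwells) | dwells <= 0))
    stop("dwell durations must be positive and finite", call. = FALSE)
  1 / mean(dwells)
}

#' Convert a per-frame transition matrix to rate constants
#'
#' The discrete-time transition matrix `P` over one frame period relates to
#' the continuous-time generator `Q` by `P = expm(Q * dt)`, so
#' `Q = logm(P) / dt`: the principal matrix logarithm (computed by
#' eigendecomposition) correctly accounts for multiple transitions within
#' one frame. Small negative off-diagonal entries produced by noise are
#' clipped to zero and the diagonal rebalanced. When the principal logarithm
#' is not real (a non-embeddable `P`), the first-order approximation
#' `k_ij = P_ij / dt` is used instead and recorded in the result.
#'
#' @param P row-stochastic transition matrix.
#' @param frame_period frame duration in seconds.
#' @return List with `rates` (off-diagonal rate matrix in 1/s, zero
#'   diagonal) and `method` (`"matrix_log"` or `"linear"`).
#' @export
transition_probs_to_rates <- function(P, frame_period) {
  P <- as.matrix(P)
  if (frame_period <= 0) stop("frame_period must be > 0", call. = FALSE)
  if (any(P < -1e-8) || any(abs(rowSums(P) - 1) > 1e-6))
    stop("P must be row-stochastic", call. = FALSE)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  K <- nrow(P)
  if (K == 1L) return(list(rates = matrix(0, 1, 1), method = "matrix_log"))
  Q <- tryCatch({
    e <- eigen(P)
    if (any(Mod(e$values) < 1e-12)) stop("singular")
    L <- e$vectors %*% diag(log(as.complex(e$values)), K) %*% solve(e$vectors)
    if (max(abs(Im(L))) > 1e-8) stop("non-real principal logarithm")
    Re(L) / frame_period
  }, error = function(e) NULL)
  method <- "matrix_log"
  if (is.null(Q)) {
    Q <- P / frame_period
    method <- "linear"
  }
  rates <- Q
  diag(rates) <- 0
  rates[rates < 0] <- 0
  list(rates = rates, method = method)
}

#' Bayesian information criterion
#'
#' `BIC = -2 logL + p ln N` with `p` free parameters and `N` observed
#' frames. Parameter counting for the ensemble HMM: one mean and one SD per
#' emission set (per state, or per tied group when emissions are shared),
#' `K (K - 1)` free transition probabilities and `K - 1` free initial
#' probabilities.
#'
#' @param logL maximized log-likelihood.
#' @param n_params number of free parameters.
#' @param n_frames number of observations.
#' @return The BIC value (smaller is better).
#' @export
bic <- function(logL, n_params, n_frames) {
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  -2 * logL + n_params * log(n_frames)
}

#' Select the number of states by BIC
#'
#' Fits ensemble HMMs with 1 to `max_states` states (multiple jittered
#' restarts each, best log-likelihood kept) and returns the model with the
#' smallest BIC. The full BIC table and any per-candidate fit errors are
#' attached to the returned model.
#'
#' Camera integration blurs transition frames into artificial mid-FRET
#' observations, and raw likelihood rewards an extra "state" that collects
#' them. Such a state has a fitted lifetime at or below the frame period,
#' i.e. kinetics faster than the sampling can resolve. Candidate models
#' containing a state with self-transition probability below
#' `min_self_transition` (expected lifetime under two frames at the
#' default 0.5) are therefore excluded from the BIC ranking as
#' unidentifiable at this sampling rate, unless every candidate is
#' excluded; the screen is reported per candidate in the BIC table.
#'
#' @inheritParams fit_ensemble_hmm
#' @param max_states largest state count to try.
#' @param min_self_transition identifiability screen: candidates with any
#'   diagonal transition probability below this are not ranked.
#' @return The minimum-BIC `inferred_model`, with attributes `bic_table`
#'   (data frame) and `fit_errors` (named character vector, possibly empty).
#' @export
select_model <- function(traces, max_states, restarts = 5, seed = 1L,
                         max_iter = 1000, tol = 1e-6, frame_period = NULL,
                         min_self_transition = 0.5) {
  fits <- vector("list", max_states)
  errors <- character(0)
  for (K in seq_len(max_states)) {
    fits[[K]] <- tryCatch(
      fit_ensemble_hmm(traces, K, restarts = restarts, seed = seed + K,
                       max_iter = max_iter, tol = tol,
                       frame_period = frame_period),
      error = function(e) {
        errors[[as.character(K)]] <<- conditionMessage(e)
        NULL
      })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all candidate state counts failed to fit", call. = FALSE)
  tab <- data.frame(
    n_states = which(ok),
    loglik = vapply(fits[ok], `[[`, numeric(1), "loglik"),
    n_params = vapply(fits[ok], `[[`, numeric(1), "n_params"),
    bic = vapply(fits[ok], `[[`, numeric(1), "bic"),
    subframe_state = vapply(fits[ok], function(f)
      any(diag(f$A) < min_self_transition), logical(1)))
  rank_ok <- if (all(tab$subframe_state)) rep(TRUE, nrow(tab))
             else !tab$subframe_state
  best <- fits[ok][rank_ok][[which.min(tab$bic[rank_ok])]]
  attr(best, "bic_table") <- tab
  attr(best, "fit_errors") <- errors
  best
}

#' Parametric-bootstrap confidence intervals for rate constants
#'
#' Implements the re-simulation consistency loop as an uncertainty measure:
#' the inferred kinetic model is used to simulate `n_boot` synthetic
#' datasets at matched trace count and comparable trace lengths, each is
#' re-fitted with the same ensemble HMM, and percentile intervals of the
#' re-inferred rate constants give the confidence bounds.
#'
#' @param model an `inferred_model`.
#' @param traces the dataset the model was fitted to (sets trace count,
#'   lengths and noise scale for the re-simulation).
#' @param n_boot number of bootstrap datasets.
#' @param level confidence level in percent (default 95).
#' @param seed integer seed.
#' @return The model with `ci95` set: a list with arrays `low` and `high`
#'   (rate matrices), the per-replicate rate draws, and the number of failed
#'   refits.
#' @export
bootstrap_ci <- function(model, traces, n_boot = 100, level = 95, seed = 1L) {
  if (n_boot < 10) warning("n_boot < 10 gives unstable percentile intervals")
  series <- fret_series(traces)
  frame_period <- model$frame_period
  K <- model$n_states
  km <- as_kinetic_model(model)
  lens <- lengths(series) * frame_period
  noise_sd <- mean(model$fret_sds)
  draws <- array(NA_real_, c(K, K, n_boot))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(trace_substream_seed(seed, b))
    sim <- lapply(lens, function(L) {
      p <- simulate_state_path(km, L)
      occ <- discretize_path(p, 1 / frame_period)
      if (ncol(occ) < K) occ <- cbind(occ, matrix(0, nrow(occ), K - ncol(occ)))
      mu <- as.numeric(occ %*% model$fret_means)
      s2 <- as.numeric(occ %*% model$fret_sds^2)  # per-state draws, weighted
      mu + stats::rnorm(length(mu), 0, sqrt(pmax(s2, noise_sd^2 * 0.01)))
    })
    fit <- tryCatch(
      fit_ensemble_hmm(sim, K, frame_period = frame_period,
                       emission_groups = model$emission_groups,
                       max_iter = 300, tol = 1e-5),
      error = function(e) NULL)
    if (is.null(fit)) { failed <- failed + 1L; next }
    draws[, , b] <- fit$rates
  }
  alpha <- (100 - level) / 200
  qs <- apply(draws, c(1, 2), stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE)
  model$ci95 <- list(level = level,
                     low = qs[1L, , ], high = qs[2L, , ],
                     draws = draws, failed_refits = failed)
  model
}
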