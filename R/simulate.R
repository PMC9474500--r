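#' Simulation configuration for smFRET datasets
#'
#' Collects every knob of the trace simulator. The defaults reproduce a
#' clean camera-based (TIRF-like) acquisition: 5 Hz sampling, exponential
#' photobleach-limited trace lengths between 30 s and 300 s, state-specific
#' Gaussian channel noise, and all optional imperfections (per-trace mean
#' jitter, per-molecule brightness variation, dye blinking) switched off.
#'
#' @param sampling_rate frames per second (Hz).
#' @param bleach_rate photobleaching rate in 1/s; trace lengths are drawn
#'   from `Exponential(bleach_rate)`, redrawn below `min_length` and clipped
#'   at `max_length`.
#' @param min_length,max_length trace-length bounds in seconds.
#' @param n_traces number of molecules to simulate.
#' @param emission_means numeric matrix `n_states x 3` of mean counts per
#'   channel (`donor`, `acceptor`, `acceptor_direct`) at donor / acceptor
#'   excitation.
#' @param emission_cov either one `3 x 3` covariance matrix shared by all
#'   states or a list of per-state `3 x 3` covariance matrices (counts^2).
#' @param mean_jitter_scale per-trace state-mean perturbation scale: each
#'   trace redraws its state means from `Normal(mu, scale * sqrt(mu))`.
#' @param brightness_base base `b` of the per-molecule brightness factor
#'   `b^r`, `r ~ Uniform[-1, 1]`; all channels of a trace share the factor.
#' @param enable_mean_jitter,enable_brightness,enable_blinking logical
#'   switches for the three imperfections.
#' @param blink_rates named list with elements `donor` and `acceptor`, each
#'   `c(to_dark, to_bright)` in 1/s.
#' @param donor_dark_baseline mean donor counts while the donor is dark.
#' @param seed integer seed; per-trace substreams are derived from it so any
#'   single trace can be regenerated.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(sampling_rate = 5,
                              bleach_rate = 1 / 160,
                              min_length = 30,
                              max_length = 300,
                              n_traces = 75,
                              emission_means,
                              emission_cov,
                              mean_jitter_scale = 5,
                              brightness_base = 1.20,
                              enable_mean_jitter = FALSE,
                              enable_brightness = FALSE,
                              enable_blinking = FALSE,
                              blink_rates = list(donor = c(to_dark = 0.01, to_bright = 0.1),
                                                 acceptor = c(to_dark = 0.01, to_bright = 0.1)),
                              donor_dark_baseline = 0,
                              seed = 1L) {
  if (!(min_length > 0 && min_length <= max_length))
    stop("need 0 < min_length <= max_length", call. = FALSE)
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  emission_means <- as.matrix(emission_means)
  if (ncol(emission_means) == 2L)  # no direct-excitation channel supplied
    emission_means <- cbind(emission_means, acceptor_direct = 0)
  colnames(emission_means) <- c("donor", "acceptor", "acceptor_direct")
  if (any(emission_means < 0)) stop("emission means must be >= 0", call. = FALSE)
  if (is.matrix(emission_cov))
    emission_cov <- rep(list(emission_cov), nrow(emission_means))
  emission_cov <- lapply(emission_cov, function(S) {
    S <- as.matrix(S)
    if (nrow(S) == 2L) S <- rbind(cbind(S, 0), 0)  # pad direct channel, noiseless
    if (!isSymmetric(unname(S), tol = 1e-8))
      stop("emission covariance must be symmetric", call. = FALSE)
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("emission covariance must be positive semi-definite", call. = FALSE)
    unname(S)
  })
  structure(
    list(sampling_rate = sampling_rate, bleach_rate = bleach_rate,
         min_length = min_length, max_length = max_length, n_traces = n_traces,
         emission_means = emission_means, emission_cov = emission_cov,
         mean_jitter_scale = mean_jitter_scale, brightness_base = brightness_base,
         enable_mean_jitter = enable_mean_jitter,
         enable_brightness = enable_brightness,
         enable_blinking = enable_blinking, blink_rates = blink_rates,
         donor_dark_baseline = donor_dark_baseline, seed = as.integer(seed)),
    class = "simulation_config")
}

#' Draw a photobleach-limited trace length
#'
#' Trace durations follow the photobleaching kinetics: exponential with rate
#' `bleach_rate`, values shorter than `min_length` rejected and redrawn,
#' values longer than `max_length` truncated to `max_length` (the movie
#' ends).
#'
#' @inheritParams simulation_config
#' @param n number of durations to draw.
#' @return Numeric vector of durations in seconds, all in
#'   `[min_length, max_length]`.
#' @export
draw_trace_length <- function(bleach_rate, min_length, max_length, n = 1L) {
  if (min_length > max_length) stop("min_length > max_length", call. = FALSE)
  if (min_length == max_length) return(rep(min_length, n))
  if (bleach_rate <= 0)
    stop("bleach_rate must be > 0 unless min_length == max_length", call. = FALSE)
  out <- numeric(n)
  need <- seq_len(n)
  tries <- 0L
  while (length(need)) {
    tries <- tries + 1L
    if (tries > 1e6L) stop("rejection sampling of trace lengths did not terminate",
                           call. = FALSE)
    d <- stats::rexp(length(need), rate = bleach_rate)
    ok <- d >= min_length
    out[need[ok]] <- d[ok]
    need <- need[!ok]
  }
  pmin(out, max_length)
}

#' Draw the initial state of a molecule
#'
#' The initial state is sampled from the stationary distribution of the
#' kinetic model, i.e. the probability of finding the molecule in each state
#' at an arbitrary observation start.
#'
#' @param model a validated `kinetic_model`.
#' @param n number of draws.
#' @return Integer state indices.
#' @export
draw_initial_state <- function(model, n = 1L) {
  p <- stationary_distribution(model)
  sample.int(model$n_states, size = n, replace = TRUE, prob = p)
}

#' Simulate a continuous-time state trajectory
#'
#' Generates the molecule's path through the kinetic states by competing
#' exponential clocks: from the current state, candidate dwell times to every
#' connected state are drawn from exponentials with the corresponding rate
#' constants, and the shortest one wins and sets the next state. The final
#' dwell is truncated at `duration` (censored by bleaching).
#'
#' @param model a validated `kinetic_model`.
#' @param duration trace length in seconds.
#' @param initial_state optional starting state index; drawn from the
#'   stationary distribution when missing.
#' @return A list of class `state_path` with `states` (integer vector),
#'   `entry_times` (seconds, starting at 0) and `duration`.
#' @export
simulate_state_path <- function(model, duration, initial_state = NULL) {
  stopifnot(duration > 0)
  n <- model$n_states
  s <- if (is.null(initial_state)) draw_initial_state(model) else as.integer(initial_state)
  states <- integer(0); entries <- numeric(0)
  t <- 0
  repeat {
    states <- c(states, s); entries <- c(entries, t)
    if (n == 1L) break
    k_out <- model$rates[s, ]
    cand <- which(k_out > 0)
    dt <- stats::rexp(length(cand), rate = k_out[cand])
    w <- which.min(dt)
    t <- t + dt[w]
    if (t >= duration) break
    s <- cand[w]
  }
  structure(list(states = states, entry_times = entries, duration = duration),
            class = "state_path")
}

#' Discretize a state path into per-frame occupancy fractions
#'
#' Converts a continuous-time path into camera frames of length
#' `1/sampling_rate`: frame `f` covers the half-open interval
#' `[(f-1) dt, f dt)` and its row holds the fraction of that interval spent
#' in each state. Frames during which a transition occurred have fractional
#' occupancies -- the origin of camera blurring.
#'
#' @param path a `state_path`.
#' @param sampling_rate frames per second.
#' @return Numeric matrix `n_frames x n_states` (zero rows if the path is
#'   shorter than one frame); rows sum to 1.
#' @export
discretize_path <- function(path, sampling_rate) {
  dt <- 1 / sampling_rate
  n_frames <- floor(path$duration * sampling_rate)
  n_states <- max(path$states)
  occ <- matrix(0, n_frames, n_states)
  if (n_frames == 0L) return(occ)
  starts <- path$entry_times
  ends <- c(path$entry_times[-1L], path$duration)
  for (seg in seq_along(path$states)) {
    a <- starts[seg]; b <- min(ends[seg], n_frames * dt)
    if (b <= a) next
    f0 <- floor(a / dt) + 1L
    f1 <- ceiling(b / dt)
    f1 <- min(f1, n_frames)
    for (f in f0:f1) {
      lo <- (f - 1L) * dt; hi <- f * dt
      overlap <- min(b, hi) - max(a, lo)
      if (overlap > 0) occ[f, path$states[seg]] <- occ[f, path$states[seg]] + overlap / dt
    }
  }
  # snap floating-point dust so pure frames are exactly 0/1, then restore
  # the exact per-frame unit sum
  occ[occ < 1e-9] <- 0
  occ[occ > 1 - 1e-9] <- 1
  rs <- rowSums(occ)
  occ[rs > 0, ] <- occ[rs > 0, , drop = FALSE] / rs[rs > 0]
  occ
}

#' Per-trace perturbation of state emission means
#'
#' Molecule-to-molecule variation of the fluorescence level is modelled by
#' redrawing each state/channel mean once per trace from
#' `Normal(mu, scale * sqrt(mu))`; negative draws are rejected and redrawn
#' so means stay physical without a point mass at zero.
#'
#' @param emission_means matrix of mean counts (states x channels).
#' @param mean_jitter_scale scale of the perturbation SD in units of
#'   `sqrt(mu)`; 0 disables the jitter.
#' @return Matrix of the same shape with perturbed means.
#' @export
perturb_state_means <- function(emission_means, mean_jitter_scale = 5) {
  if (mean_jitter_scale == 0) return(emission_means)
  out <- emission_means
  sdv <- mean_jitter_scale * sqrt(emission_means)
  idx <- which(sdv > 0)
  for (i in idx) {
    repeat {
      v <- stats::rnorm(1L, emission_means[i], sdv[i])
      if (v >= 0) break
    }
    out[i] <- v
  }
  out
}

#' Per-molecule brightness factor
#'
#' Draws `base^r` with `r ~ Uniform[-1, 1]`; for the default base 1.20 the
#' factor lies in `[0.83, 1.20]`. One factor multiplies all channels of a
#' trace, so the FRET efficiency is unaffected up to noise.
#'
#' @param brightness_base base of the factor, > 1.
#' @param n number of draws.
#' @return Numeric factors in `[1/base, base]`.
#' @export
draw_brightness_factor <- function(brightness_base = 1.20, n = 1L) {
  if (brightness_base <= 1) stop("brightness_base must be > 1", call. = FALSE)
  brightness_base^stats::runif(n, -1, 1)
}

#' Simulate dye blinking intervals
#'
#' Each dye independently switches between a bright and a dark state as a
#' two-state continuous-time process started bright. The long-run dark
#' fraction is `to_dark / (to_dark + to_bright)`.
#'
#' @param duration trace length in seconds.
#' @param blink_rates named list with `donor` and `acceptor` elements, each
#'   `c(to_dark, to_bright)` in 1/s.
#' @return List with elements `donor` and `acceptor`, each a `state_path`
#'   over states 1 = bright, 2 = dark.
#' @export
simulate_blinking <- function(duration, blink_rates) {
  one_dye <- function(r) {
    to_dark <- r[[1]]; to_bright <- r[[2]]
    states <- integer(0); entries <- numeric(0)
    s <- 1L; t <- 0
    repeat {
      states <- c(states, s); entries <- c(entries, t)
      rate <- if (s == 1L) to_dark else to_bright
      if (rate <= 0) break
      t <- t + stats::rexp(1L, rate)
      if (t >= duration) break
      s <- 3L - s
    }
    structure(list(states = states, entry_times = entries, duration = duration),
              class = "state_path")
  }
  list(donor = one_dye(blink_rates$donor), acceptor = one_dye(blink_rates$acceptor))
}

#' FRET efficiency from donor and acceptor intensities
#'
#' The uncorrected proximity ratio `acceptor / (donor + acceptor)`. Frames
#' with non-positive total intensity get `NA` (undefined).
#'
#' @param donor,acceptor numeric intensity vectors.
#' @return Numeric FRET efficiencies with `NA` where undefined.
#' @export
compute_fret <- function(donor, acceptor) {
  tot <- donor + acceptor
  out <- ifelse(is.finite(tot) & tot > 0, acceptor / tot, NA_real_)
  as.numeric(out)
}

# per-frame occupancy of the four dye-brightness combinations
# 1 both bright, 2 acceptor dark, 3 donor dark, 4 both dark
blink_combo_occupancy <- function(blink, n_frames, sampling_rate) {
  combo_path_states <- function(d, a) {
    ts <- sort(unique(c(d$entry_times, a$entry_times)))
    d_state <- function(t) d$states[findInterval(t, d$entry_times)]
    a_state <- function(t) a$states[findInterval(t, a$entry_times)]
    st <- vapply(ts, function(t) {
      dd <- d_state(t) == 2L; ad <- a_state(t) == 2L
      if (!dd && !ad) 1L else if (!dd && ad) 2L else if (dd && !ad) 3L else 4L
    }, integer(1))
    keep <- c(TRUE, st[-1L] != st[-length(st)])
    structure(list(states = st[keep], entry_times = ts[keep], duration = d$duration),
              class = "state_path")
  }
  cp <- combo_path_states(blink$donor, blink$acceptor)
  occ <- discretize_path(cp, sampling_rate)
  if (ncol(occ) < 4L) occ <- cbind(occ, matrix(0, nrow(occ), 4L - ncol(occ)))
  occ[seq_len(n_frames), , drop = FALSE]
}

#' Emit a noisy intensity trace from per-frame occupancies
#'
#' For every frame, one multichannel Gaussian intensity is drawn per kinetic
#' state visited during that frame (and per dye-brightness condition when
#' blinking is active) and the draws are combined by their time weights --
#' the camera's frame integration. An acceptor dark period reroutes the
#' transferred energy back to the donor: the donor recovers the full
#' (donor + acceptor) signal and the apparent FRET efficiency drops to zero.
#' A donor dark period suppresses both the donor signal and the
#' FRET-sensitized acceptor signal.
#'
#' @param occupancies matrix `n_frames x n_states` of time fractions.
#' @param emission_means matrix (states x 3 channels) of mean counts for this
#'   trace (already jittered / scaled if applicable).
#' @param emission_cov list of per-state `3 x 3` covariance matrices.
#' @param blink_occ optional `n_frames x 4` matrix of dye-condition
#'   occupancies (both bright / acceptor dark / donor dark / both dark).
#' @param donor_dark_baseline mean donor counts while the donor is dark.
#' @param sampling_rate frames per second (sets the frame timestamps).
#' @param trace_id identifier stored with the trace.
#' @return An object of class `fret_trace`: a list with `time_s`, `donor`,
#'   `acceptor`, `acceptor_direct`, `fret`, `gt_occupancy` and `trace_id`.
#' @export
emit_trace <- function(occupancies, emission_means, emission_cov,
                       blink_occ = NULL, donor_dark_baseline = 0,
                       sampling_rate = 5, trace_id = "trace_1") {
  n_frames <- nrow(occupancies)
  n_states <- ncol(occupancies)
  sig <- matrix(0, n_frames, 3L)
  if (is.null(blink_occ)) {
    blink_occ <- matrix(0, n_frames, 4L); blink_occ[, 1L] <- 1
  }
  # condition-specific channel means for state s:
  #   both bright: (muD, muA, muAA); acceptor dark: (muD + muA, 0, 0)
  #   donor dark: (baseline, 0, muAA); both dark: (baseline, 0, 0)
  cond_means <- function(mu) rbind(
    mu,
    c(mu[1L] + mu[2L], 0, 0),
    c(donor_dark_baseline, 0, mu[3L]),
    c(donor_dark_baseline, 0, 0))
  for (s in seq_len(n_states)) {
    w_s <- occupancies[, s]
    frames <- which(w_s > 0)
    if (!length(frames)) next
    cm <- cond_means(emission_means[s, ])
    R <- chol_psd(emission_cov[[s]])
    for (cond in 1:4) {
      w <- w_s[frames] * blink_occ[frames, cond]
      nz <- which(w > 0)
      if (!length(nz)) next
      draws <- matrix(stats::rnorm(length(nz) * 3L), ncol = 3L) %*% R
      draws <- sweep(draws, 2L, cm[cond, ], "+")
      sig[frames[nz], ] <- sig[frames[nz], ] + draws * w[nz]
    }
  }
  time_s <- (seq_len(n_frames) - 1L) / sampling_rate
  structure(
    list(time_s = time_s, donor = sig[, 1L], acceptor = sig[, 2L],
         acceptor_direct = sig[, 3L],
         fret = compute_fret(sig[, 1L], sig[, 2L]),
         gt_occupancy = occupancies, trace_id = trace_id,
         sampling_rate = sampling_rate),
    class = "fret_trace")
}

# upper-triangular factor tolerating PSD (zero-variance) matrices
chol_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  v <- pmax(ev$values, 0)
  t(ev$vectors %*% (t(ev$vectors) * sqrt(v)))
}

#' Simulate a full smFRET dataset with ground truth
#'
#' Runs the whole generative pipeline for `config$n_traces` molecules:
#' photobleach-limited duration, stationary initial state, continuous-time
#' state path, frame discretization, optional per-trace mean jitter and
#' brightness factor, optional dye blinking, and Gaussian channel noise.
#' Each trace uses an RNG substream derived deterministically from
#' `(config$seed, trace index)`, so the same seed reproduces the dataset
#' exactly and any single trace can be regenerated in isolation.
#'
#' @param model a validated `kinetic_model` (the ground truth).
#' @param config a `simulation_config`.
#' @return An object of class `fret_dataset`: list with `traces` (list of
#'   `fret_trace`), `model`, `config` and `ground_truth` (per-trace state
#'   paths, jittered means, brightness factors, blinking intervals).
#' @examples
#' arc <- two_state_archetype(n_traces = 3, max_length = 40)
#' ds <- simulate_dataset(arc$model, arc$config)
#' length(ds$traces)
#' @export
simulate_dataset <- function(model, config) {
  model <- validate_model(model)
  if (nrow(config$emission_means) != model$n_states)
    stop("emission_means must have one row per model state", call. = FALSE)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  traces <- vector("list", config$n_traces)
  gt <- vector("list", config$n_traces)
  for (i in seq_len(config$n_traces)) {
    set.seed(trace_substream_seed(config$seed, i))
    for (attempt in 1:100) {
      duration <- draw_trace_length(config$bleach_rate, config$min_length,
                                    config$max_length)
      if (floor(duration * config$sampling_rate) >= 1L) break
      if (attempt == 100L)
        stop("could not draw a trace of at least one frame; check config",
             call. = FALSE)
    }
    path <- simulate_state_path(model, duration)
    occ <- discretize_path(path, config$sampling_rate)
    if (ncol(occ) < model$n_states)
      occ <- cbind(occ, matrix(0, nrow(occ), model$n_states - ncol(occ)))
    mu <- config$emission_means
    if (config$enable_mean_jitter)
      mu <- perturb_state_means(mu, config$mean_jitter_scale)
    bf <- 1
    if (config$enable_brightness) {
      bf <- draw_brightness_factor(config$brightness_base)
      mu <- mu * bf
    }
    blink <- NULL; blink_occ <- NULL
    if (config$enable_blinking) {
      blink <- simulate_blinking(duration, config$blink_rates)
      blink_occ <- blink_combo_occupancy(blink, nrow(occ), config$sampling_rate)
    }
    id <- sprintf("trace_%04d", i)
    traces[[i]] <- emit_trace(occ, mu, config$emission_cov, blink_occ,
                              config$donor_dark_baseline, config$sampling_rate, id)
    gt[[i]] <- list(trace_id = id, path = path, emission_means = mu,
                    brightness_factor = bf, blinking = blink)
  }
  structure(list(traces = traces, model = model, config = config,
                 ground_truth = gt),
            class = "fret_dataset")
}

# deterministic 32-bit substream seed for (dataset seed, trace index)
trace_substream_seed <- function(seed, i) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 2654435761 + as.double(i) * 40503 + 12345) %% 2147483647
  as.integer(x)
}

#' @export
print.fret_dataset <- function(x, ...) {
  nf <- sum(vapply(x$traces, function(tr) length(tr$time_s), integer(1)))
  cat("smFRET dataset:", length(x$traces), "traces,", nf, "frames at",
      x$config$sampling_rate, "Hz\n")
  cat("Ground-truth model:", x$model$n_states, "states, E =",
      paste(round(x$model$fret, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a dataset
#' @param dataset a `fret_dataset` or list of `fret_trace`.
#' @return Total frame count.
#' @export
n_frames <- function(dataset) {
  tr <- if (inherits(dataset, "fret_dataset")) dataset$traces else dataset
  sum(vapply(tr, function(t) length(t$time_s), integer(1)))
}

#' Simulate datasets from a kinetic model
#'
#' `simulate()` method for `kinetic_model`: draws `nsim` independent datasets
#' under a given simulation configuration (the re-simulation consistency
#' loop used for benchmarking inferred models).
#'
#' @param object a `kinetic_model`.
#' @param nsim number of datasets.
#' @param seed integer seed; overrides `config$seed` (dataset `i` uses
#'   `seed + i - 1`).
#' @param config a `simulation_config`.
#' @param ... unused.
#' @return A `fret_dataset` when `nsim = 1`, else a list of them.
#' @export
simulate.kinetic_model <- function(object, nsim = 1, seed = NULL, config, ...) {
  if (is.null(seed)) seed <- config$seed
  out <- lapply(seq_len(nsim), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seed + i - 1L)
    simulate_dataset(object, cfg)
  })
  if (nsim == 1L) out[[1L]] else out
}
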