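#' Benchmark archetype: dynamic two-state system
#'
#' The simplest benchmark condition: a molecule alternating between two
#' conformations at `k12 = 0.10` and `k21 = 0.20` per second, FRET
#' efficiencies 0.3 and 0.7, sampled at 5 Hz with photobleach-limited trace
#' lengths (mean about 160 s between 30 s and 300 s) so that 75 traces carry
#' about 59,500 frames. Channel noise is calibrated so the FRET histogram
#' has a signal-to-noise ratio of 4 (per-state FRET SD about 0.0707). All
#' optional imperfections are off: the "clean" condition.
#'
#' @param n_traces,sampling_rate,bleach_rate,min_length,max_length,seed,...
#'   overrides passed to [simulation_config()].
#' @param k12,k21 rate constants (1/s).
#' @param fret per-state FRET efficiencies.
#' @param total_intensity summed donor + acceptor mean counts.
#' @param fret_sd target per-state SD of the FRET efficiency.
#' @return List with elements `model` (a [kinetic_model()]) and `config`
#'   (a [simulation_config()]).
#' @export
two_state_archetype <- function(k12 = 0.10, k21 = 0.20, fret = c(0.3, 0.7),
                                total_intensity = 1000, fret_sd = 0.0707,
                                n_traces = 75, sampling_rate = 5,
                                bleach_rate = 1 / 160, min_length = 30,
                                max_length = 300, seed = 1L, ...) {
  model <- kinetic_model(rbind(c(0, k12), c(k21, 0)), fret = fret)
  list(model = model,
       config = simulation_config(
         sampling_rate = sampling_rate, bleach_rate = bleach_rate,
         min_length = min_length,
         max_length = max_length, n_traces = n_traces,
         emission_means = fret_emission_means(model$fret, total_intensity),
         emission_cov = fret_emission_cov(model$fret, total_intensity, fret_sd),
         seed = seed, ...))
}

#' Benchmark archetype: driven three-state cycle
#'
#' A non-equilibrium steady-state condition: three clearly separated FRET
#' states (0.2, 0.5, 0.8) on a cycle whose counter-clockwise rates exceed
#' the clockwise ones, so the cycle free energy is negative
#' (`delta_g = -ln 8` for the defaults) and the molecule steps through the
#' states in a preferred order. Per-molecule intensity variation (state-mean
#' jitter and brightness factor) is on, as in the matching benchmark
#' condition; sampling at 10 Hz with shorter traces.
#'
#' @param rates_ccw counter-clockwise rate constants `k21, k32, k13` (1/s).
#' @param rates_cw clockwise rate constants `k12, k23, k31` (1/s).
#' @inheritParams two_state_archetype
#' @return List with `model` and `config`.
#' @export
driven_three_state <- function(rates_ccw = c(0.2, 0.2, 0.2),
                               rates_cw = c(0.1, 0.1, 0.1),
                               fret = c(0.2, 0.5, 0.8),
                               total_intensity = 1000, fret_sd = 0.0707,
                               n_traces = 150, sampling_rate = 10,
                               bleach_rate = 1 / 48, min_length = 10,
                               max_length = 150, seed = 1L, ...) {
  k <- matrix(0, 3, 3)
  k[1, 2] <- rates_cw[1]; k[2, 3] <- rates_cw[2]; k[3, 1] <- rates_cw[3]
  k[2, 1] <- rates_ccw[1]; k[3, 2] <- rates_ccw[2]; k[1, 3] <- rates_ccw[3]
  model <- kinetic_model(k, fret = fret)
  list(model = model,
       config = simulation_config(
         sampling_rate = sampling_rate, bleach_rate = bleach_rate,
         min_length = min_length, max_length = max_length,
         n_traces = n_traces,
         emission_means = fret_emission_means(model$fret, total_intensity),
         emission_cov = fret_emission_cov(model$fret, total_intensity, fret_sd),
         enable_mean_jitter = TRUE, enable_brightness = TRUE,
         seed = seed, ...))
}

#' Benchmark archetype: kinetic heterogeneity with degenerate FRET states
#'
#' Four hidden states but only two apparent FRET populations: two hidden
#' states share the low efficiency and two share the high efficiency, with a
#' slow and a fast exchange pathway, so the dwell-time distribution of each
#' FRET class is double-exponential. Intensity variation and dye blinking
#' are both on -- the hardest simulated condition.
#'
#' @param rates 4x4 rate matrix; the default couples a slow pair
#'   (`S1 <-> S3`) and a fast pair (`S2 <-> S4`) with slow exchange inside
#'   each FRET class.
#' @inheritParams two_state_archetype
#' @return List with `model` and `config`.
#' @export
heterogeneous_four_state <- function(rates = NULL,
                                     fret = c(0.3, 0.3, 0.7, 0.7),
                                     total_intensity = 1000, fret_sd = 0.0707,
                                     n_traces = 250, sampling_rate = 5,
                                     bleach_rate = 1 / 160, min_length = 30,
                                     max_length = 300, seed = 1L, ...) {
  if (is.null(rates)) {
    rates <- matrix(0, 4, 4)
    rates[1, 3] <- 0.05; rates[3, 1] <- 0.05   # slow pathway
    rates[2, 4] <- 0.50; rates[4, 2] <- 0.50   # fast pathway
    rates[1, 2] <- 0.02; rates[2, 1] <- 0.02   # intra-class exchange (low E)
    rates[3, 4] <- 0.02; rates[4, 3] <- 0.02   # intra-class exchange (high E)
  }
  model <- kinetic_model(rates, fret = fret)
  list(model = model,
       config = simulation_config(
         sampling_rate = sampling_rate, bleach_rate = bleach_rate,
         min_length = min_length, max_length = max_length,
         n_traces = n_traces,
         emission_means = fret_emission_means(model$fret, total_intensity),
         emission_cov = fret_emission_cov(model$fret, total_intensity, fret_sd),
         enable_mean_jitter = TRUE, enable_brightness = TRUE,
         enable_blinking = TRUE, seed = seed, ...))
}

#' Channel emission means implied by FRET efficiencies
#'
#' Splits a total photon budget between donor and acceptor according to each
#' state's FRET efficiency: donor mean `(1 - E) * I`, acceptor mean `E * I`.
#' The direct-excitation acceptor channel gets a constant level (default
#' half the total) independent of `E`.
#'
#' @param fret per-state FRET efficiencies.
#' @param total_intensity summed donor + acceptor mean counts.
#' @param direct_level mean counts of the acceptor under direct excitation.
#' @return Matrix (states x 3) of channel means.
#' @export
fret_emission_means <- function(fret, total_intensity = 1000,
                                direct_level = total_intensity / 2) {
  cbind(donor = (1 - fret) * total_intensity,
        acceptor = fret * total_intensity,
        acceptor_direct = rep(direct_level, length(fret)))
}

#' Channel covariances calibrated to a target FRET-efficiency SD
#'
#' With independent equal-variance donor and acceptor noise of SD `s`, error
#' propagation through `E = a/(d + a)` gives a FRET SD of
#' `s * sqrt((1 - E)^2 + E^2) / I`. This helper inverts that relation per
#' state so the simulated FRET histogram has the requested per-state SD
#' (and hence the requested SNR for a given state separation).
#'
#' @inheritParams fret_emission_means
#' @param fret_sd target per-state FRET-efficiency SD.
#' @return List of per-state diagonal 3x3 covariance matrices.
#' @export
fret_emission_cov <- function(fret, total_intensity = 1000, fret_sd = 0.0707) {
  lapply(fret, function(E) {
    s <- fret_sd * total_intensity / sqrt((1 - E)^2 + E^2)
    diag(c(s^2, s^2, s^2))
  })
}
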