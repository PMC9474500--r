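---
title: "Simulating and inferring smFRET kinetics with fretkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and inferring smFRET kinetics with fretkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretkin)
```

## The problem

Camera-based single-molecule FRET experiments record, for each molecule, a
donor and an acceptor intensity per camera frame. The FRET efficiency
`E = acceptor / (donor + acceptor)` reports on the conformational state of
the molecule, and the dynamics of `E` encode the kinetic rate constants of
the underlying conformational exchange. Inferring those rate constants is a
multi-step, error-prone procedure — state identification, idealization,
dwell-time statistics, uncertainty estimation — and different analysis
pipelines can disagree substantially. `fretkin` closes the loop needed to
benchmark such pipelines:

1. **simulate** realistic trace data from a kinetic model with known
   ground truth,
2. **infer** a kinetic model back from the traces with a reference
   ensemble hidden Markov model (HMM), and
3. **evaluate** the inference against the ground truth with statistics
   that separate method error from the irreducible finite-data limit.

## The generative model

A molecule's conformational dynamics are a continuous-time Markov chain
over `n` states with rate matrix `k[i, j]` (s⁻¹) and per-state FRET
efficiencies `E_i`. `simulate_dataset()` composes the following stages, all
individually exported and testable:

* **Trace length.** Photobleaching terminates observation after an
  `Exponential(bleach_rate)` time; draws below `min_length` are rejected
  (such traces would be discarded in practice) and draws above
  `max_length` are truncated (the movie ends). Defaults
  (`bleach_rate = 1/160` s⁻¹, bounds 30–300 s at 5 Hz, 75 traces) yield
  about 59,500 frames per dataset, the scale of the package's reference
  two-state benchmark condition.
* **State path.** The initial state is drawn from the stationary
  distribution `π` (solving `πQ = 0`); subsequent transitions follow
  competing exponential clocks — one candidate dwell per outgoing rate,
  the shortest wins.
* **Discretization.** Frames are half-open intervals `[t, t + Δt)`
  timestamped at the interval start. Each frame records the fraction of
  frame time spent in each state; a transition inside a frame therefore
  produces a time-weighted mixture ("camera blurring").
* **Emission.** Per frame, one trivariate Gaussian intensity draw
  (donor, acceptor, acceptor-direct) is taken per state visited and
  combined by the occupancy weights. Drawing noise *before* averaging
  (rather than drawing once from the weighted-mean distribution) was a
  deliberate choice: it reproduces the detector reading out a signal that
  switched mid-integration, and for mixed frames it gives a smaller noise
  variance than the single-draw alternative, which matters only for the
  small minority of transition frames.
* **Per-molecule variation (optional).** Each trace may redraw its state
  means from `Normal(μ_I, 5·√μ_I)` (negative draws resampled, not
  clipped, to avoid a point mass at zero), and scale all channels by a
  brightness factor `1.20^r`, `r ~ Uniform[−1, 1]`, i.e. a factor in
  `[0.83, 1.20]`. The common factor leaves `E` unchanged up to noise.
* **Blinking (optional).** Each dye independently switches
  bright ↔ dark as a two-state process started bright (defaults: to-dark
  0.01 s⁻¹, to-bright 0.1 s⁻¹ — rare, short dark events). During an
  acceptor-dark period the transferred energy is rerouted: the donor
  recovers the full summed signal and the apparent FRET drops to zero.
  Donor-dark behaviour is less standardized than acceptor-dark, so it
  is explicit configuration: the donor falls to a configurable dark
  baseline (default 0) and the FRET-sensitized acceptor signal vanishes
  while direct acceptor excitation is unaffected.

Channel noise is parameterized through `fret_emission_cov()`, which
inverts the error propagation `sd(E) = s·√((1−E)² + E²)/I` so that a
requested per-state FRET standard deviation (and hence a requested
histogram SNR `|μ₁−μ₂|/√(σ₁²+σ₂²)`) is realized exactly in expectation.
The archetype default `fret_sd = 0.0707` with states at `E = 0.3/0.7`
gives SNR 4, the "clean" benchmark condition.

**Reproducibility.** Each trace uses an RNG substream derived
deterministically from `(seed, trace index)`, so a dataset is byte-stable
under its seed and any single trace can be regenerated alone.

### What the generator does *not* emulate

Single-photon discretization and the resulting non-Gaussian noise at
kilohertz sampling; spectral crosstalk and γ-correction; diffusion-based
confocal bursts; video-level (point-spread-function) simulation. Passing
tests therefore demonstrate correctness of the kinetic loop under
Gaussian camera noise, not robustness to photon-counting statistics.

## The inference engine

`fit_kinetics()` (or the lower-level `fit_ensemble_hmm()`) fits **one**
shared parameter set to **all** traces: per-state Gaussian emissions on
the 1-D FRET efficiency (mean and SD), a per-frame transition matrix, and
an initial distribution. Per-trace forward–backward statistics are summed
before each M-step, so short traces contribute without being fit
individually. 1-D FRET emissions are the common denominator of existing
tools (2-D donor/acceptor emissions are an extension hook, not
implemented). Implementation notes:

* Scaled forward–backward and Viterbi recursions run in C++ (Rcpp); the
  EM loop, initialization and M-steps are plain R.
* Initialization: k-means cluster means on pooled FRET values, ascending;
  within-cluster SDs; transition matrix 0.95 on the diagonal; initial
  probabilities from cluster frequencies. Restarts jitter the means by
  ±0.02 and randomize the transition matrix.
* Convergence: relative log-likelihood change below `tol = 1e-6`, at most
  `max_iter = 1000` iterations; the log-likelihood trace is retained and
  asserted non-decreasing in the tests.
* Frames with undefined FRET (non-positive total intensity) are masked
  from the likelihood rather than imputed.
* **Rate conversion.** The per-frame transition matrix relates to the
  generator by `P = expm(QΔt)`; `transition_probs_to_rates()` inverts
  this with the principal matrix logarithm (eigendecomposition), which
  correctly compensates frame-averaging of multiple events. Noise-induced
  small negative off-diagonal rates are clipped to zero. When `P` is not
  embeddable (non-real principal logarithm), the first-order `P_ij/Δt` is
  used and the method recorded — both routes are reported by
  `summary()` alongside the independent dwell-time MLE route.
* **Dwells and censoring.** Viterbi paths are compressed to dwell records;
  the first and last run of every trace are marked censored (their true
  length is unknown) and excluded from the exponential MLE `k = 1/mean`.
  Censoring conventions vary across analysis tools; exclusion is the
  standard bias-avoiding choice and is documented here as this
  package's convention.
* **Kinetic heterogeneity.** `emission_groups` ties the emission mean and
  SD of designated hidden states, so e.g. four hidden states can share
  two apparent FRET efficiencies; the kinetic differentiation within a
  group then comes entirely from the transition structure, which is why
  grouped fits randomize their initial transition matrix across restarts.
  The group structure is user-specified, not searched.

### Model selection under camera blurring

`select_model()` ranks 1..`max_states` by BIC
(`−2 logL + p·ln N`, with `p` counting one mean and SD per emission set,
`K(K−1)` transition and `K−1` initial probabilities). Raw BIC, however,
reliably rewards an artifact: frame-averaged transition observations form
a mid-FRET pseudo-population, and an extra state with a fitted lifetime
at or below the frame period absorbs it. Rates at the sampling-rate scale
are not identifiable from camera data, so candidates containing a state
with self-transition probability below 0.5 (expected lifetime under two
frames) are excluded from the ranking — they are still fitted and shown
in the BIC table with a `subframe_state` flag. With the screen, selection
recovers the true state count on the clean two-state and
variation-free driven three-state conditions. With strong per-molecule
intensity variation a 1-D ensemble HMM may still prefer additional
(slow, genuine-lifetime) states that model trace-to-trace FRET shifts;
this is a known limitation of ensemble 1-D emission models; multi-lab
comparisons of analysis tools likewise report model selection under
intensity variation as the main open challenge.

### Uncertainty

`bootstrap_ci()` implements the re-simulation consistency loop as a
parametric bootstrap: simulate replicate datasets from the inferred model
at matched trace count and lengths, refit each, and report percentile
intervals (default 95%, the most common convention). Failed refits are
dropped and counted.

## Evaluation statistics

* **Finite-data lower bound.** With `n` observed dwells no estimator can
  beat the sampling scatter of the MLE itself:
  `mle_uncertainty_lower_bound()` measures the SD of `1/mean` over
  replicate exponential samples and checks it against the closed form
  `k·n/((n−1)·√(n−2))` (the MLE is inverse-Gamma). Reported confidence
  intervals narrower than this bound are flagged as implausible in
  `benchmark_report()`. Tests and the default use 1e5 replicates; 1e6
  is available by argument and only halves the Monte-Carlo error of the
  bound itself.
* **Cumulative dwell-time distributions.** `cumulative_dwell_cdf()`
  simulates long state paths from a model, merges states whose FRET
  efficiencies agree within `fret_tolerance = 0.05` (degenerate states
  are exactly equal; the tolerance absorbs inference jitter) into
  apparent classes, and returns the empirical CDF of class residence
  times on a log grid from a tenth of the frame period to ten times the
  slowest expected dwell. Transitions inside a class do not interrupt a
  dwell, so hidden heterogeneity shows up as multi-exponential curvature
  that a single-exponential model cannot reproduce — the basis for
  comparing models with equal apparent states but different hidden
  structure. Oversampling factors of 200–400 relative to the reference
  dataset resolve multi-exponential tails; smaller factors only widen
  sampling error.
* **Deviation, CV, flow.** `percent_deviation()` compares canonically
  ordered models rate-by-rate (`100·|k_inf − k_gt|/k_gt`); mismatched
  state counts produce a structured report, never a silent comparison.
  `coefficient_of_variation()` uses the sample SD (n−1; the n−1 denominator is this
  package's convention). `cycle_flow_free_energy()`
  reports `ΔG = −ln[(k21·k32·k13)/(k12·k23·k31)]` in units of `k_BT` —
  only the ratio ever enters, so no temperature parameter exists; a
  negative value flags net flow along the listed cycle order.
  `is_detailed_balanced()` applies the Kolmogorov criterion over the
  fundamental cycles of a spanning tree.
* **Equilibrium constants.** `K = k21/k12` is reported for two-state
  fits because systematic analysis shifts common to both rates (e.g.
  missed fast events on a coarser time base) cancel in the ratio; the
  test suite demonstrates this by re-analyzing one dataset at a 3×
  coarser sampling.

## Numerical and design choices

* Canonical state order: ascending FRET efficiency, ties broken by larger
  total exit rate — makes ground-truth/inferred comparisons well defined
  for degenerate efficiencies.
* Stationary distribution: SVD null space of the transposed generator,
  residual tolerance 1e−10; reducible matrices are reported with the
  disconnected states named.
* Emission covariances are accepted if symmetric PSD (eigenvalue
  tolerance −1e−8); sampling uses an eigen-based square root so
  zero-variance channels are legal.
* Zero-frame traces (shorter than one frame) are redrawn up to 100 times,
  then reported as a configuration error.
* The SNR mixture fit uses EM (unequal variances) with k-means
  initialization and 10 jittered restarts, avoiding histogram binning
  choices.
* Model documents and trace files are plain text (JSON / headered CSV)
  at 12 significant digits; FRET is recomputed from intensities on load
  so the file's derived column can never disagree with its sources.

## Problem sizes used by the test suite

The suite regenerates every fixture from seeds at runtime. The two-state
recovery check runs at the full reference scale (75 traces, ≈59,500
frames); parameter-recovery sweeps, model-selection, bootstrap-coverage
and flow-direction repetitions use reduced replicas (15–40 traces,
shorter maximum lengths, 20–100 seeds) chosen to keep each property's
Monte-Carlo error comfortably inside the asserted margins.

## Known limitations

1-D Gaussian emissions cannot use donor/acceptor correlations; ensemble
fitting assumes homogeneous kinetics across molecules (per-molecule
intensity variation is tolerated, per-molecule *kinetic* variation is
not modelled); blur frames are screened at model selection rather than
modelled explicitly; dwell-based rates ignore censored dwells rather than
using a censored likelihood. All are documented extension points rather
than silent assumptions.
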