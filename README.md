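# fretkin

Simulation and kinetic inference for single-molecule FRET trajectories.

Camera-based smFRET experiments watch one molecule at a time switch
between conformational states, each with a characteristic FRET efficiency
`E = I_acceptor / (I_donor + I_acceptor)`. The kinetic information — the
rate constants `k_ij` (s⁻¹) of a continuous-time Markov model over those
states — must be inferred from noisy, photobleach-limited intensity
traces, and different analysis pipelines can disagree. `fretkin` is for
developers and users of such pipelines: it closes the
*simulate → infer → evaluate* benchmarking loop in one package with a
single shared data dialect.

**Simulate.** Continuous-time state paths from a rate matrix;
exponential photobleach-limited trace lengths (rejected below a minimum,
truncated at a maximum); frame discretization with time-weighted
averaging (camera blurring); state-specific Gaussian channel noise;
optional per-molecule intensity variation (state-mean jitter
`Normal(μ_I, 5√μ_I)` and a brightness factor `1.20^r`, `r ∈ [−1, 1]`)
and two-state dye blinking (acceptor dark ⇒ apparent FRET 0). Ground
truth is retained alongside every dataset.

**Infer.** An ensemble hidden Markov model with Gaussian emissions on
the FRET efficiency, one parameter set learned across all traces by
Baum–Welch (C++ recursions); Viterbi idealization; censoring-annotated
dwell times with the exponential MLE `k = 1/mean(Δt)`; conversion of the
per-frame transition matrix to rate constants via the principal matrix
logarithm `Q = logm(P)/Δt`; BIC model selection with an identifiability
screen for sub-frame "blur" states; parametric-bootstrap confidence
intervals by re-simulation.

**Evaluate.** The finite-data lower bound on rate uncertainty — the SD
of replicate MLEs over `n` dwells, `k·n/((n−1)√(n−2))` in closed form —
against which reported confidence intervals are judged; cumulative
dwell-time distributions implied by a kinetic model (heavily oversampled,
degenerate-FRET states merged into apparent classes); histogram SNR
`|μ₁−μ₂|/√(σ₁²+σ₂²)` from a Gaussian mixture fit; percent deviations
from ground truth; coefficients of variation; equilibrium constants
`K = k21/k12`; and the cycle free energy
`ΔG = −k_BT · ln[(k21·k32·k13)/(k12·k23·k31)]`, whose sign detects
non-equilibrium steady-state flow.

## Worked example

```r
library(fretkin)

arc <- two_state_archetype(n_traces = 20, seed = 7)  # k12 = 0.1, k21 = 0.2, SNR 4
ds  <- simulate_dataset(arc$model, arc$config)
fit <- fit_kinetics(ds, n_states = 2, seed = 1)
summary(fit)
```

```
Ensemble smFRET kinetic fit
  20 traces, 11955 frames, 2 state(s); logL = 12614.86, BIC = -25163.99

FRET states:
 state   mean     sd occupancy
     1 0.2979 0.0754     0.687
     2 0.7001 0.0774     0.313

Rate constants (1/s), transition-matrix route:
        [,1]    [,2]
[1,] 0.00000 0.08371
[2,] 0.18124 0.00000

Rate constants (1/s), dwell-time route ( 244 uncensored dwells ):
        [,1]    [,2]
[1,] 0.00000 0.09207
[2,] 0.18756 0.00000

Equilibrium constant K = k21/k12: 2.1651
```

The two FRET efficiencies are recovered to within 0.01 of the ground
truth (0.3 / 0.7) and the occupancies match the stationary distribution
(2/3, 1/3). The two independent rate routes agree: the transition-matrix
route gives `k12 = 0.084`, `k21 = 0.181` s⁻¹ from only 20 traces
(deviations up to ~16% from the ground truth at this reduced size; at the
full 75-trace benchmark scale they fall inside the 12% cross-tool
accuracy envelope that `scripts/acceptance.R` checks). How much of that deviation is even avoidable? The
finite-data lower bound at the full dataset's dwell statistics:

```r
mle_uncertainty_lower_bound(rate = 0.10, n_dwells = 793, n_replicates = 1e5)
```

```
MLE uncertainty lower bound: k = 0.1 /s, n = 793 dwells
  SD = 0.003553 /s (3.55% of k) from 100000 replicates; closed form 0.00356 /s
```

i.e. no analysis of a dataset this size can pin `k12` tighter than ±3.5%
— any tool reporting a smaller uncertainty is flagged by
`benchmark_report()`.

A command-line interface wrapping the same functions ships in
`inst/scripts/fretkin`:

```sh
fretkin simulate  --model config.json --out data/ --seed 7
fretkin infer     --traces data/ --states 2 --out model.json --seed 7
fretkin evaluate  --gt data/ground_truth.json --inferred model.json --traces data/ --out report.json
fretkin benchmark --model config.json --out run/ --seed 7   # all three chained
```

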