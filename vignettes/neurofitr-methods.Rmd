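---
title: "Fitting neuronal models and benchmarking the search algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting neuronal models and benchmarking the search algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofitr)
```

## The problem

Data-driven neuron models almost always contain parameters — maximal
conductance densities, synaptic kinetics, adaptation constants — that are
not directly measurable. They are estimated by minimizing a cost function
that quantifies the discrepancy between simulated and target behaviour.
`neurofitr` provides the three ingredients of that workflow: a library of
electrophysiological cost functions, native implementations of the global
and local search algorithms most used for this task, and a harness of
surrogate-data benchmarks on which the algorithms can be compared under
identical conditions.

All internal units follow compartmental-simulator conventions: time in ms,
voltage in mV, current in nA, conductance densities in S/cm².

## Cost functions

Ten trace-comparison components are implemented. Each takes a model trace
and a target trace, aligns the model onto the target grid (the target is
the fixed experimental reference and is never resampled; the model is
linearly interpolated if the grids differ), and returns a unitless,
non-negative scalar that is exactly zero for identical traces:

* `mse_error` — pointwise mean squared difference over the squared target
  range;
* `mse_excl_spikes_error` — the same after removing samples near action
  potentials of *either* trace (±5 ms around each peak by default), with
  the normalizing range recomputed on the retained target samples;
* `derivative_difference_error` — mean squared difference of the
  forward-difference derivatives over the squared range of the target
  derivative (insensitive to voltage offsets);
* `spike_count_error` — `|n_m − n_t| / (n_m + n_t)`, zero when both are
  silent; `spike_count_during_stimulus_error` restricts the counts to the
  stimulus window;
* `isi_difference_error` — inter-spike intervals paired in order, absolute
  differences summed, unpaired intervals contributing their own value,
  normalized by the trace duration;
* `latency_error` — squared difference of the times to the first spike
  after stimulus onset, over the squared trace duration; a silent trace
  contributes the trace duration as a sentinel latency, which makes the
  "no spike versus any spike" error large but bounded;
* `ap_overshoot_error`, `ap_width_error`, `ahp_depth_error` — per-spike
  amplitude (peak minus onset voltage), base width (duration at the onset
  voltage, sub-sample interpolated) and after-hyperpolarization depth,
  paired in temporal order up to the shorter spike count, normalized by
  the squared maximal target amplitude, squared mean target width, and
  squared subthreshold target range respectively. A spike-free model is
  penalized with the maximal normalized value 1 rather than an unbounded
  one.

Pairing spikes in order up to the shorter count is a deliberate choice:
mismatched counts are the business of the spike-count component, so shape
components should not be contaminated by them. For the after-
hyperpolarization component we compute the mean of squared differences,
consistent with the neighbouring definitions.

`feature_stat_error` supports feature-statistics targets: the absolute
deviation of a model feature from the experimental mean in units of the
experimental standard deviation; undefined features (an AP feature of a
silent model) score a conventional large penalty of 250.

Components are combined by `evaluate_error_vector` as a weighted average
with weights normalized to sum to one, so only weight ratios matter and a
run's reported raw values stay interpretable pre-weighting. Multi-objective
algorithms treat the same components as separate objectives; after such a
run, a single preferred solution is chosen with `select_winner` by the same
normalized weighted sum (ties broken by the earliest evaluation).

## Spike detection

The detection rule (none is mandated by the data): one spike per maximal
upward crossing of a detection threshold (0 mV default, suitable for
full-height biophysical spikes); the AP onset is the foot of the contiguous
run of dV/dt at or above a slope criterion leading through the steepest
point of the rising phase. The default criterion is 20 mV/ms, a common
electrophysiological convention. The Hodgkin-Huxley benchmark overrides it
to 40 mV/ms because its 0.3 nA step charges the membrane at 21–24 mV/ms:
at 20 mV/ms the first spike's onset walk-back would continue through the
stimulus-onset charging phase down to the resting potential, producing a
meaningless ~150 ms "base width". All three detection settings (threshold,
slope criterion, exclusion half-width) are per-call options.

Integrate-and-fire traces carry no spike shape, so for the AdEx benchmark
spike times come from the simulator's explicit event train
(`spike_analysis_from_events`), never from threshold crossings of the
clipped trace.

## Benchmark models

Three desk-scale simulators generate surrogate targets — the model itself
run at known "true" parameters — so a zero-error solution exists by
construction and parameter recovery is measurable:

* **Hodgkin-Huxley (`benchmark_hh`)** — single compartment with the
  canonical squid-axon Na⁺/K⁺/leak kinetics; the three conductance
  densities (truth 0.12, 0.036, 0.0003 S/cm²) are searched over 0.1× to 3×
  their true values. Fixed constants: E_Na 50 mV, E_K −77 mV, E_leak
  −54.3 mV, C_m 1 µF/cm², and a 20 µm × 20 µm cylindrical compartment
  (≈1.257e−5 cm²), which makes the 0.3 nA / 200 ms / 500 ms protocol step
  (1000 ms trace) safely suprathreshold. Four equally weighted components:
  spike count, AP overshoot, AP width, MSE excluding spikes. Integration is
  fixed-step — exponential Euler for the gates (with the usual tabulated
  rate functions) and an implicit frozen-conductance voltage update — at
  0.025 ms by default; the benchmark samples at 0.05 ms, which preserves
  the spike count and shifts peak times by well under half a millisecond
  relative to dt-halving or an adaptive-step reference.
* **Voltage clamp (`benchmark_vclamp`)** — a bi-exponential conductance
  synapse under an ideal clamp at −70 mV, reversal 0 mV; the trace is the
  closed-form clamp current (baseline subtracted) for four presynaptic
  events at 10 Hz (100…400 ms of a 600 ms trace). Truth: weight 0.01 µS,
  rise 0.5 ms, decay 5 ms, delay 2 ms; the box spans roughly an order of
  magnitude around the truth (delay 0.1–10 ms) and keeps rise < decay
  everywhere, so the closed form is defined over the entire search space.
  Mean squared error is the single objective, so only single-objective
  algorithms apply.
* **AdEx (`benchmark_adex`)** — adaptive exponential integrate-and-fire
  neuron, ten free parameters, four current steps (0.30/0.35/0.40/0.45 nA,
  100 ms delay, 900 ms duration, 1100 ms traces, 5 kHz sampling). The truth
  (C 200 pF, g_L 10 nS, E_L −70 mV, V_T −50 mV, V_reset −58 mV, t_ref 2 ms,
  Δ_T 2 mV, a 2 nS, b 40 pA, τ_w 120 ms) is a standard regular-spiking,
  adapting parameter set whose rheobase (≈220 pA) lies below the weakest
  protocol step, so every protocol elicits spiking. Components: MSE
  excluding spikes, spike count during the stimulus, latency to first
  spike — equal weights, averaged over the four protocols. The spike
  cut-off is V_T + 5Δ_T; V is clamped at the reset during the refractory
  period while the adaptation current keeps integrating.

A simulation whose state diverges maps to a maximal-error sentinel (1e9)
rather than aborting the optimizer run, so algorithms that propose extreme
parameter combinations simply discard them.

The surrogate targets emulate the *structure* of real fitting problems —
nonlinear spiking dynamics, mixed discrete/continuous error components,
parameters spanning orders of magnitude — but not measurement noise,
electrode artifacts, trial-to-trial variability, or model misspecification
(the fitted model generates its own target). Passing benchmarks therefore
demonstrates correct optimization behaviour, not expected accuracy on
experimental recordings.

## Optimizers

All algorithms operate in normalized [0, 1]^d coordinates with an affine
map to the physical box (the benchmarks mix parameters spanning orders of
magnitude, so hyperparameters such as mutation widths are stated in
normalized units). All draw randomness exclusively from a generator seeded
by the run configuration, submit whole generations for evaluation through
a single batch entry point (results ordered as submitted, no shared state
between evaluations), and spend exactly `pop_size × n_generations`
evaluations unless an explicit early-stopping error level is configured.
Out-of-bounds proposals are clipped to the box, except CMA-ES which
resamples up to a retry cap before clipping.

* `random_search` — i.i.d. uniform sampling; the baseline.
* `nelder_mead` — the classic simplex with coefficients (1, 2, 0.5, 0.5),
  restarting from a fresh uniform point when the simplex collapses.
* `ceo` — an elitist evolutionary algorithm: binary-tournament selection,
  blend crossover (α = 0.1), per-gene Gaussian mutation with probability
  0.25 and σ = 0.5 (normalized), elitism preserving the best half of the
  population.
* `cmaes` — standard covariance matrix adaptation: weighted recombination
  of the best μ = λ/2, rank-1 plus rank-μ covariance updates, cumulative
  step-size adaptation; initial mean at the box center, initial σ 0.3; a
  covariance that loses positive definiteness triggers a restart with
  inflated σ within the same budget.
* `pso` — generational particle swarm with the constriction defaults
  ω = 0.7298, c₁ = c₂ = 1.49618, velocities clamped to half the box width,
  all particles updated from the same global-best snapshot per generation.
* `de` — differential evolution, DE/rand/1/bin, F = 0.8, CR = 0.9, greedy
  one-to-one replacement.
* `nsga2` — fast non-dominated sorting, crowding-distance truncation of
  the merged parent+child population, binary tournaments on
  (rank, crowding), simulated binary crossover (η = 15) and polynomial
  mutation (η = 20, rate 1/d); the final population is returned as the
  front approximation.

These hyperparameter defaults are the literature-standard values; every
run's effective settings are echoed into its JSON record so results remain
attributable.

## Evaluation protocol

The study protocol fixes 10,000 evaluations per run, split as 100
candidates × 100 generations, with 10 independently seeded repeats
(`study_protocol`). Two scores summarize each run:

* **final score** — the lowest total error found (`final_score`), the last
  value of the cumulative-minimum convergence curve;
* **convergence score** — the sum over generations of log₁₀ of the
  cumulative-minimum error (`convergence_score`), i.e. the area under the
  logarithmic convergence curve; lower means faster convergence. The
  cumulative minimum is used rather than the per-generation best (the two
  differ only for non-elitist algorithms), log base 10 is a pure rescaling
  choice, and the argument is floored at 1e-12 because surrogate fits can
  reach exactly zero.

Algorithms are ranked per benchmark by the median of a score across seeds,
tied medians sharing the mean of the tied ranks (`rank_algorithms`), and
rank statistics are aggregated across benchmarks (`overall_rank_stats`).
`write_metadata` emits the machine-readable JSON record of a run —
parameters with bounds and best values, per-component errors of the winner
(name, raw, weight, weighted), full algorithm settings and seed, and
per-generation statistics — at 17 significant digits so scores survive the
round trip bit-exactly.

## Numerical choices and degenerate inputs

* The normalized MSE errors are undefined for a constant target (zero
  range): this raises an error rather than returning an arbitrary value.
* Latency uses the trace duration as its silent-trace sentinel, which caps
  the normalized latency error at 1.
* Early stopping (`target_error`) ends a run after the first *completed*
  generation whose cumulative minimum reaches the level, so budgets remain
  whole generations.
* The CMA-ES bound rule (resample up to 100 times, then clip) keeps the
  sampling distribution honest near the optimum while guaranteeing
  progress when the distribution mass leaves the box.
* Ties in winner selection go to the earliest evaluated candidate, which
  makes selection deterministic and reproducible.
* The benchmark objectives for the Hodgkin-Huxley and voltage-clamp
  problems use a streamlined evaluation path (compiled simulation and
  detection feeding the component arithmetic directly); the test suite
  asserts its agreement with the documented component functions to
  1e-10 at random parameter points, and the JSON records always report
  components recomputed through the documented path.

## Worked example

```{r, eval = FALSE}
bench <- benchmark_vclamp()
runs <- run_study(bench, "cmaes",
                  study_protocol(n_repeats = 3, seeds = 1:3),
                  target_error = 1e-9)
score_table(runs)
vapply(runs, generations_to_floor, 0L, floor = 1e-9)
```

On this benchmark CMA-ES typically reaches the 1e-9 error floor — the
level at which the recovered synaptic parameters agree with the hidden
truth to well under 1% — in 20 to 25 generations of 100 evaluations.

## Problem sizes used in the shipped checks

The package's own test suite runs the full 100 × 100 study protocol with
10 seeds for the Hodgkin-Huxley and voltage-clamp benchmarks (CMA-ES runs
stop at their error floors; particle swarm and random search spend the
full budget), and exercises the AdEx benchmark at its definition and
truth-consistency level. Algorithm unit checks use smaller splits (tens of
candidates × tens of generations) on analytic test functions, which is
where each operator property is decidable quickly.

## Known limitations

* Only step-current and event-train protocols are built in; arbitrary
  stimulus waveforms would need a new protocol type.
* Spike detection assumes full-height spikes for threshold crossing;
  traces with strongly attenuated spikes need a per-call detection
  threshold.
* The AdEx benchmark's ten-parameter recovery is not identifiable at the
  1e-9 level from three feature-like components alone; it is shipped as a
  harder, degenerate-optima problem rather than a recovery guarantee.
* No parallel execution: the batch-evaluation contract is parallel-ready,
  but evaluation is serial in this implementation.
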