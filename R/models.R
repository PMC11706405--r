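#' Hodgkin-Huxley conductance-density parameters
#'
#' The three free parameters of the single-compartment squid-axon model: the
#' maximal densities of the transient Na+, delayed-rectifier K+ and leak
#' conductances. The reversal potentials, specific capacitance and the
#' compartment area are fixed constants of the benchmark (standard values:
#' `ena` 50 mV, `ek` -77 mV, `el` -54.3 mV, `cm` 1 uF/cm2; the compartment is
#' a 20 um x 20 um cylinder of lateral area ~1.2566e-5 cm2, which makes the
#' 0.3 nA benchmark step suprathreshold).
#'
#' @param gna,gk,gl Maximal conductance densities, S/cm2 (non-negative).
#' @param ena,ek,el Reversal potentials, mV.
#' @param cm Specific membrane capacitance, uF/cm2.
#' @param area Compartment membrane area, cm2.
#' @return An object of class `hh_params`.
#' @export
hh_params <- function(gna = 0.12, gk = 0.036, gl = 0.0003,
                      ena = 50, ek = -77, el = -54.3,
                      cm = 1, area = pi * 20e-4 * 20e-4) {
  stopifnot(gna >= 0, gk >= 0, gl >= 0, cm > 0, area > 0)
  structure(list(gna = gna, gk = gk, gl = gl, ena = ena, ek = ek, el = el,
                 cm = cm, area = area),
            class = "hh_params")
}

#' Simulate the single-compartment Hodgkin-Huxley model
#'
#' Integrates `C dV/dt = -I_Na - I_K - I_L + I_stim / area` with the
#' canonical squid-axon gating kinetics (m^3 h and n^4 with the standard
#' alpha/beta rate functions) using a fixed step: exponential Euler for the
#' gating variables and an implicit (frozen-conductance) update for the
#' voltage. The initial state is the resting steady state at zero current.
#'
#' @param params An [hh_params()].
#' @param stim A [step_stimulus()].
#' @param dt Integration/sampling step, ms; must be at most 0.05 ms.
#' @return A voltage [neuro_trace()] with the stimulus attached.
#' @export
simulate_hh <- function(params, stim, dt = 0.025) {
  stopifnot(inherits(params, "hh_params"), inherits(stim, "step_stimulus"))
  if (dt > 0.05)
    stop("simulate_hh requires dt <= 0.05 ms", call. = FALSE)
  v <- .hh_sim_cpp(params$gna, params$gk, params$gl,
                   params$ena, params$ek, params$el,
                   params$cm, params$area,
                   stim$amplitude, stim$delay, stim$duration,
                   stim$total_duration, dt)
  if (anyNA(v))
    stop(simulation_failure("Hodgkin-Huxley state became non-finite"))
  neuro_trace(v, dt = dt, t0 = 0, unit = "mV", stimulus = stim)
}

#' Bi-exponential synapse parameters (voltage-clamp benchmark)
#'
#' @param weight Peak synaptic conductance, uS (non-negative).
#' @param tau_rise,tau_decay Rise and decay time constants, ms;
#'   `0 < tau_rise < tau_decay`.
#' @param delay Synaptic delay from each presynaptic event, ms.
#' @param e_syn Synaptic reversal potential, mV (fixed constant).
#' @param hold_v Holding potential of the ideal clamp, mV (fixed constant).
#' @return An object of class `syn_params`.
#' @export
syn_params <- function(weight = 0.01, tau_rise = 0.5, tau_decay = 5,
                       delay = 2, e_syn = 0, hold_v = -70) {
  stopifnot(weight >= 0, delay >= 0)
  if (!(tau_rise > 0 && tau_rise < tau_decay))
    stop("requires 0 < tau_rise < tau_decay", call. = FALSE)
  structure(list(weight = weight, tau_rise = tau_rise, tau_decay = tau_decay,
                 delay = delay, e_syn = e_syn, hold_v = hold_v),
            class = "syn_params")
}

#' Time from conductance onset to the bi-exponential peak
#'
#' `t_peak = tau_rise * tau_decay / (tau_decay - tau_rise) *
#' log(tau_decay / tau_rise)`, the closed-form argmax of
#' `exp(-t/tau_decay) - exp(-t/tau_rise)`.
#'
#' @param tau_rise,tau_decay Time constants, ms.
#' @return Peak time, ms.
#' @export
biexp_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

#' Simulate an ideal voltage-clamp recording of a bi-exponential synapse
#'
#' Closed-form clamp current: each presynaptic event at `t_e` contributes a
#' conductance `weight * N * (exp(-(t - t_e - delay)/tau_decay) -
#' exp(-(t - t_e - delay)/tau_rise))` for `t >= t_e + delay`, with `N`
#' normalizing the per-event peak conductance to `weight`; contributions sum
#' linearly and the current is `g(t) * (hold_v - e_syn)`. The constant
#' holding (baseline) current is subtracted, so the trace depends only on
#' the synaptic parameters.
#'
#' @param params A [syn_params()].
#' @param events An [event_train()] of presynaptic spike times, ms.
#' @param duration Trace duration, ms.
#' @param dt Sampling interval, ms.
#' @return A current [neuro_trace()] (nA).
#' @export
simulate_vclamp <- function(params, events, duration, dt = 0.1) {
  stopifnot(inherits(params, "syn_params"), inherits(events, "event_train"))
  if (any(events$times < 0 | events$times > duration))
    stop("presynaptic events must lie within [0, duration]", call. = FALSE)
  tt <- seq(0, duration, by = dt)
  g <- vclamp_conductance(tt, params, events$times)
  neuro_trace(g * (params$hold_v - params$e_syn), dt = dt, t0 = 0,
              unit = "nA")
}

# summed bi-exponential conductance (uS) at times tt for events `ev`
vclamp_conductance <- function(tt, params, ev) {
  tr <- params$tau_rise; td <- params$tau_decay
  tp <- biexp_peak_time(tr, td)
  N <- 1 / (exp(-tp / td) - exp(-tp / tr))
  g <- numeric(length(tt))
  for (te in ev) {
    s <- tt - te - params$delay
    on <- s >= 0
    g[on] <- g[on] + params$weight * N * (exp(-s[on] / td) - exp(-s[on] / tr))
  }
  g
}

#' Adaptive exponential integrate-and-fire parameters
#'
#' The ten free parameters of the AdEx point neuron: membrane capacitance,
#' leak conductance and reversal, exponential threshold `V_T` and slope
#' `Delta_T`, reset voltage, refractory period, subthreshold adaptation
#' conductance `a`, spike-triggered adaptation increment `b`, and adaptation
#' time constant `tau_w`.
#'
#' @param C Capacitance, pF (> 0).
#' @param g_L Leak conductance, nS (> 0).
#' @param E_L Leak reversal potential, mV.
#' @param V_T Exponential threshold voltage, mV.
#' @param V_reset Post-spike reset voltage, mV.
#' @param t_ref Refractory period, ms (>= 0).
#' @param Delta_T Slope factor of the exponential term, mV (> 0).
#' @param a Subthreshold adaptation conductance, nS.
#' @param b Spike-triggered adaptation current increment, pA.
#' @param tau_w Adaptation time constant, ms (> 0).
#' @return An object of class `adex_params`.
#' @export
adex_params <- function(C = 200, g_L = 10, E_L = -70, V_T = -50,
                        V_reset = -58, t_ref = 2, Delta_T = 2,
                        a = 2, b = 40, tau_w = 120) {
  stopifnot(C > 0, g_L > 0, tau_w > 0, Delta_T > 0, t_ref >= 0)
  structure(list(C = C, g_L = g_L, E_L = E_L, V_T = V_T, V_reset = V_reset,
                 t_ref = t_ref, Delta_T = Delta_T, a = a, b = b,
                 tau_w = tau_w),
            class = "adex_params")
}

#' Simulate the adaptive exponential integrate-and-fire neuron
#'
#' Integrates `C dV/dt = -g_L (V - E_L) + g_L Delta_T exp((V - V_T)/Delta_T)
#' - w + I` and `tau_w dw/dt = a (V - E_L) - w` by forward Euler. When `V`
#' reaches the cut-off `V_T + 5 Delta_T` a spike time is recorded, `V` is
#' reset, `w` is incremented by `b`, and `V` is held at the reset for
#' `t_ref`. The returned trace clips `V` at the cut-off (spike shape carries
#' no information in this model); spike times are returned as an
#' [event_train()].
#'
#' @param params An [adex_params()].
#' @param stim A [step_stimulus()].
#' @param dt Integration step, ms; must be at most 0.1 ms.
#' @param record_every Record every k-th integration step, so the trace
#'   sampling interval is `record_every * dt`.
#' @return A list with `trace` (voltage [neuro_trace()]) and `spikes`
#'   ([event_train()]).
#' @export
simulate_adex <- function(params, stim, dt = 0.05, record_every = 1L) {
  stopifnot(inherits(params, "adex_params"), inherits(stim, "step_stimulus"))
  if (dt > 0.1)
    stop("simulate_adex requires dt <= 0.1 ms", call. = FALSE)
  res <- .adex_sim_cpp(params$C, params$g_L, params$E_L, params$V_T,
                       params$V_reset, params$t_ref, params$Delta_T,
                       params$a, params$b, params$tau_w,
                       stim$amplitude, stim$delay, stim$duration,
                       stim$total_duration, dt, as.integer(record_every))
  if (isTRUE(res$failed))
    stop(simulation_failure("AdEx state became non-finite"))
  list(trace = neuro_trace(res$v, dt = dt * record_every, t0 = 0,
                           unit = "mV", stimulus = stim),
       spikes = event_train(res$spikes))
}

# condition signalled when an integrator diverges; optimizers map it to a
# maximal-error sentinel instead of aborting the run
simulation_failure <- function(msg) {
  structure(class = c("simulation_failure", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Generate surrogate target data for a benchmark
#'
#' Simulates the named benchmark model at its protocol(s) with known "true"
#' parameters and returns the targets together with the hidden truth, so
#' that parameter recovery can be scored. A zero-error solution is known to
#' exist by construction.
#'
#' @param benchmark_id One of `"hh"`, `"vclamp"`, `"adex"`.
#' @param true_params Named numeric vector of the benchmark's free
#'   parameters; defaults to the benchmark's canonical truth.
#' @param dt Override of the benchmark's integration step, ms.
#' @return A list with `targets` (list of target traces; for `adex` each
#'   element also carries `spikes`), `true_params`, and `protocol`.
#' @export
make_surrogate_target <- function(benchmark_id = c("hh", "vclamp", "adex"),
                                  true_params = NULL, dt = NULL) {
  benchmark_id <- match.arg(benchmark_id)
  bench <- switch(benchmark_id,
                  hh = benchmark_hh(dt = if (is.null(dt)) 0.05 else dt),
                  vclamp = benchmark_vclamp(dt = if (is.null(dt)) 0.1 else dt),
                  adex = benchmark_adex())
  if (!is.null(true_params)) {
    if (is.null(names(true_params)) ||
        !setequal(names(true_params), bench$space$names))
      stop("true_params must be named with the benchmark's parameters",
           call. = FALSE)
    true_params <- true_params[bench$space$names]
    if (any(true_params < bench$space$lower | true_params > bench$space$upper))
      stop("true_params outside the benchmark bounds", call. = FALSE)
    bench <- rebuild_benchmark(bench, true_params)
  }
  list(targets = bench$targets, true_params = bench$true_params,
       protocol = bench$protocol)
}
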