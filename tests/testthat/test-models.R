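test_that("HH model rests at its steady state with zero stimulus", {
  tr <- simulate_hh(hh_params(), step_stimulus(1e-12, 0, 1, 200), dt = 0.025)
  expect_lt(max(abs(tr$values - tr$values[1])), 0.5)
  expect_lt(abs(tr$values[1] - (-65)), 2) # squid-axon rest near -65 mV
})

test_that("HH spiking response matches an adaptive-step ODE oracle", {
  skip_if_not_installed("deSolve")
  prm <- hh_params()
  stim <- step_stimulus(0.3, 200, 500, 1000)
  tr <- simulate_hh(prm, stim, dt = 0.025)
  n_fixed <- nrow(detect_spikes(tr)$spikes)
  # independent route: the same membrane equations under deSolve's lsoda
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2),
                                 x / (exp(x / y) - 1))
  rates <- function(v) list(
    am = 0.1 * vtrap(-(v + 40), 10), bm = 4 * exp(-(v + 65) / 18),
    ah = 0.07 * exp(-(v + 65) / 20), bh = 1 / (1 + exp(-(v + 35) / 10)),
    an = 0.01 * vtrap(-(v + 55), 10), bn = 0.125 * exp(-(v + 65) / 80))
  deriv <- function(t, y, p) {
    r <- rates(y[1])
    I <- if (t >= 200 && t < 700) 0.3e-3 / prm$area else 0
    ina <- prm$gna * 1000 * y[2]^3 * y[3] * (y[1] - prm$ena)
    ik <- prm$gk * 1000 * y[4]^4 * (y[1] - prm$ek)
    il <- prm$gl * 1000 * (y[1] - prm$el)
    list(c((I - ina - ik - il) / prm$cm,
           r$am * (1 - y[2]) - r$bm * y[2],
           r$ah * (1 - y[3]) - r$bh * y[3],
           r$an * (1 - y[4]) - r$bn * y[4]))
  }
  v0 <- tr$values[1]
  r0 <- rates(v0)
  y0 <- c(v0, r0$am / (r0$am + r0$bm), r0$ah / (r0$ah + r0$bh),
          r0$an / (r0$an + r0$bn))
  sol <- deSolve::lsoda(y0, seq(0, 1000, by = 0.1), deriv, NULL,
                        rtol = 1e-8, atol = 1e-8)
  ode_tr <- neuro_trace(sol[, 2], dt = 0.1, unit = "mV")
  expect_equal(n_fixed, nrow(detect_spikes(ode_tr)$spikes))
})

test_that("halving dt preserves the HH spike count and peak times", {
  stim <- step_stimulus(0.3, 200, 500, 1000)
  a <- detect_spikes(simulate_hh(hh_params(), stim, dt = 0.025))$spikes
  b <- detect_spikes(simulate_hh(hh_params(), stim, dt = 0.0125))$spikes
  expect_equal(nrow(a), nrow(b))
  expect_lt(max(abs(a$peak_time - b$peak_time)), 0.5)
})

test_that("doubling the leak reduces subthreshold depolarization", {
  stim <- step_stimulus(0.02, 100, 300, 500) # weak, subthreshold step
  v1 <- simulate_hh(hh_params(gl = 0.0003), stim, dt = 0.025)
  v2 <- simulate_hh(hh_params(gl = 0.0006), stim, dt = 0.025)
  depol <- function(tr) max(tr$values) - tr$values[1]
  expect_equal(nrow(detect_spikes(v1)$spikes), 0)
  expect_gt(depol(v1), depol(v2))
})

test_that("simulate_hh validates dt and parameters", {
  expect_error(simulate_hh(hh_params(), step_stimulus(0.3, 0, 1, 10),
                           dt = 0.1), "dt")
  expect_error(hh_params(gna = -1))
})

test_that("voltage-clamp conductance peaks at the closed-form time", {
  p <- syn_params(weight = 0.01, tau_rise = 0.5, tau_decay = 5, delay = 2)
  tr <- simulate_vclamp(p, event_train(50), 200, dt = 0.001)
  tp <- biexp_peak_time(0.5, 5)
  g <- tr$values / (p$hold_v - p$e_syn) # back to conductance
  expect_equal(max(g), p$weight, tolerance = 1e-6)
  tt <- trace_times(tr)
  expect_equal(tt[which.max(g)], 50 + 2 + tp, tolerance = 1e-2)
  # zero weight: flat baseline
  flat <- simulate_vclamp(syn_params(weight = 0), event_train(50), 200)
  expect_true(all(flat$values == 0))
  expect_error(syn_params(tau_rise = 5, tau_decay = 2), "tau_rise")
})

test_that("clamp currents superpose linearly over events", {
  p <- syn_params(weight = 0.008, tau_rise = 0.7, tau_decay = 12, delay = 1.5)
  ev <- c(100, 200, 300, 400)
  full <- simulate_vclamp(p, event_train(ev), 600, dt = 0.1)
  singles <- lapply(ev, function(e)
    simulate_vclamp(p, event_train(e), 600, dt = 0.1)$values)
  expect_equal(full$values, Reduce(`+`, singles), tolerance = 1e-12)
})

test_that("closed-form clamp current agrees with an ODE integration", {
  skip_if_not_installed("deSolve")
  # bi-exponential conductance as a two-state linear ODE:
  # g = N * w * (B - A), dA/dt = -A/tau_rise, dB/dt = -B/tau_decay,
  # A and B jump by 1 at each (delayed) event
  p <- syn_params(weight = 0.01, tau_rise = 0.5, tau_decay = 5, delay = 2)
  ev <- c(100, 200, 300, 400)
  tp <- biexp_peak_time(0.5, 5)
  N <- 1 / (exp(-tp / 5) - exp(-tp / 0.5))
  deriv <- function(t, y, parms) list(c(-y[1] / 0.5, -y[2] / 5))
  times <- seq(0, 600, by = 0.1)
  evd <- ev + p$delay
  sol <- deSolve::lsoda(c(A = 0, B = 0), times, deriv, NULL, rtol = 1e-10,
                        atol = 1e-12,
                        events = list(data = data.frame(
                          var = rep(c("A", "B"), 4),
                          time = rep(evd, each = 2),
                          value = 1, method = "add")))
  g_ode <- p$weight * N * (sol[, 3] - sol[, 2])
  i_ode <- g_ode * (p$hold_v - p$e_syn)
  tr <- simulate_vclamp(p, event_train(ev), 600, dt = 0.1)
  expect_lt(max(abs(tr$values - i_ode)) / max(abs(tr$values)), 1e-6)
})

test_that("AdEx stays at its fixed point without input", {
  sim <- simulate_adex(adex_params(), step_stimulus(0, 0, 1, 500),
                       dt = 0.05)
  expect_equal(length(sim$spikes$times), 0)
  # the exponential term displaces the true rest above E_L by ~1e-4 mV at
  # these parameters (exp((E_L - V_T)/Delta_T) = exp(-10))
  expect_lt(max(abs(sim$trace$values - (-70))), 1e-3)
})

test_that("AdEx without adaptation charges like an RC circuit", {
  # a = b = 0, subthreshold step: V(t) = E_L + (I/g_L)(1 - exp(-t g_L / C))
  p <- adex_params(C = 200, g_L = 10, E_L = -70, a = 0, b = 0)
  stim <- step_stimulus(0.1, 0, 500, 500) # 100 pA -> 10 mV plateau
  sim <- simulate_adex(p, stim, dt = 0.05)
  tt <- trace_times(sim$trace)
  vexp <- -70 + 10 * (1 - exp(-tt * 10 / 200))
  expect_equal(length(sim$spikes$times), 0)
  expect_lt(max(abs(sim$trace$values - vexp)) / 10, 0.01)
})

test_that("spike-triggered adaptation stretches successive ISIs", {
  sim <- simulate_adex(adex_params(b = 60), step_stimulus(0.4, 100, 900, 1100),
                       dt = 0.05)
  isi <- diff(sim$spikes$times)
  expect_gt(length(isi), 3)
  # non-decreasing up to one integration step of spike-time quantization
  expect_true(all(diff(isi) >= -0.0501))
})

test_that("small Delta_T approaches the leaky integrate-and-fire limit", {
  p <- adex_params(C = 200, g_L = 10, E_L = -70, V_T = -50, Delta_T = 0.01,
                   a = 0, b = 0)
  stim <- step_stimulus(0.15, 0, 400, 400) # 15 mV asymptote: subthreshold
  sim <- simulate_adex(p, stim, dt = 0.05)
  tt <- trace_times(sim$trace)
  vlif <- -70 + 15 * (1 - exp(-tt * 10 / 200))
  expect_lt(max(abs(sim$trace$values - vlif)) / 15, 0.01)
})

test_that("AdEx records spikes and clips the returned trace", {
  p <- adex_params()
  sim <- simulate_adex(p, step_stimulus(0.4, 100, 900, 1100), dt = 0.05)
  expect_gt(length(sim$spikes$times), 0)
  cutoff <- p$V_T + 5 * p$Delta_T
  expect_lte(max(sim$trace$values), cutoff)
  expect_true(all(sim$spikes$times > 100))
})

test_that("surrogate targets attain zero error at the hidden truth", {
  for (id in c("hh", "vclamp", "adex")) {
    bench <- switch(id, hh = benchmark_hh(), vclamp = benchmark_vclamp(),
                    adex = benchmark_adex())
    sur <- make_surrogate_target(id)
    expect_equal(sur$true_params, bench$true_params)
    expect_lte(max(bench$objective(rbind(sur$true_params))), 1e-9)
  }
})

test_that("surrogate generation validates the requested truth", {
  expect_error(make_surrogate_target("hh", c(gna = 10, gk = 1, gl = 1)),
               "bounds")
  expect_error(make_surrogate_target("hh", c(a = 1, b = 2, c = 3)), "named")
  alt <- make_surrogate_target("vclamp",
                               c(weight = 0.02, tau_rise = 0.4,
                                 tau_decay = 6, delay = 3))
  expect_equal(unname(alt$true_params["delay"]), 3)
})
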