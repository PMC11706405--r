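flat_pair <- function(m, t, dt = 1) {
  list(model = neuro_trace(m, dt = dt, unit = "mV"),
       target = neuro_trace(t, dt = dt, unit = "mV"))
}

test_that("mean squared error normalizes by the squared target range", {
  p <- flat_pair(c(0, 1), c(0, 2))
  expect_equal(mse_error(p$model, p$target), 0.125) # ((0)^2+(1)^2)/2 / 4
  expect_equal(mse_error(p$target, p$target), 0)
  expect_error(mse_error(p$model, neuro_trace(c(1, 1), dt = 1, unit = "mV")),
               "degenerate")
  # offsetting the model by c changes only the numerator, by c^2
  set.seed(1)
  t <- neuro_trace(rnorm(100), dt = 1, unit = "mV")
  m <- neuro_trace(t$values + 0.5, dt = 1, unit = "mV")
  rng2 <- (max(t$values) - min(t$values))^2
  expect_equal(mse_error(m, t), 0.25 / rng2)
})

test_that("spike-excluding MSE reduces to MSE on spike-free traces and
           ignores perturbations inside exclusion windows", {
  set.seed(2)
  v <- rnorm(200, -65, 2) # all subthreshold: no exclusion windows
  p <- flat_pair(v + 0.3, v, dt = 0.5)
  expect_equal(mse_excl_spikes_error(p$model, p$target),
               mse_error(p$model, p$target))
  tri0 <- triangle_spike_trace(t_on = 10, t_peak = 12, total = 40, dt = 0.05)
  # subthreshold ripple keeps the retained target range positive
  tt <- trace_times(tri0)
  tri <- neuro_trace(tri0$values + 0.5 * sin(tt / 3), dt = tri0$dt,
                     unit = "mV")
  expect_equal(mse_excl_spikes_error(tri, tri), 0)
  # corrupt the model only inside the spike's exclusion window
  v2 <- tri$values
  v2[tt > 11 & tt < 13] <- v2[tt > 11 & tt < 13] + 30
  corrupted <- neuro_trace(v2, dt = tri$dt, unit = "mV")
  expect_equal(mse_excl_spikes_error(corrupted, tri), 0)
  expect_gt(mse_error(corrupted, tri), 0)
})

test_that("derivative difference kills offsets and matches hand arithmetic", {
  set.seed(3)
  t <- neuro_trace(cumsum(rnorm(50)), dt = 1, unit = "mV")
  m <- neuro_trace(t$values + 7, dt = 1, unit = "mV")
  expect_equal(derivative_difference_error(m, t), 0)
  expect_equal(derivative_difference_error(t, t), 0)
  # 4-point traces, dt = 1: model slopes (1,1,-2), target slopes (2,2,-1)
  # derivative range of target = 3; mean sq diff = (1+1+1)/3 = 1
  m2 <- neuro_trace(c(0, 1, 2, 0), dt = 1, unit = "mV")
  t2 <- neuro_trace(c(0, 2, 4, 3), dt = 1, unit = "mV")
  expect_equal(derivative_difference_error(m2, t2), 1 / 9)
})

test_that("spike-count errors follow |nm - nt| / (nm + nt)", {
  m <- fake_spike_analysis(seq(10, 30, by = 10))         # 3 spikes
  t <- fake_spike_analysis(seq(10, 50, by = 10))         # 5 spikes
  expect_equal(spike_count_error(m, t), 0.25)            # 2/8
  expect_equal(spike_count_error(t, t), 0)
  none <- fake_spike_analysis(numeric(0))
  expect_equal(spike_count_error(none, none), 0)
})

test_that("in-stimulus spike count restricts to the stimulus window", {
  stim <- step_stimulus(0.3, 100, 200, 1000)
  all_in <- fake_spike_analysis(c(120, 150, 180))
  t_in <- fake_spike_analysis(c(110, 140, 170, 200, 290))
  expect_equal(spike_count_during_stimulus_error(all_in, t_in, stim),
               spike_count_error(all_in, t_in))
  # model fires only before stimulus onset, target has 4 in-window spikes
  early <- fake_spike_analysis(c(10, 40, 70))
  t4 <- fake_spike_analysis(c(120, 150, 180, 210))
  expect_equal(spike_count_during_stimulus_error(early, t4, stim), 1)
  both_empty <- fake_spike_analysis(c(10, 20))
  expect_equal(spike_count_during_stimulus_error(both_empty, both_empty,
                                                 stim), 0)
})

test_that("ISI differences pair in order and count unpaired intervals", {
  m <- fake_spike_analysis(c(100, 110, 130))   # ISIs 10, 20
  t <- fake_spike_analysis(c(100, 112, 132))   # ISIs 12, 20
  expect_equal(isi_difference_error(m, t, duration = 1000), 2 / 1000)
  m1 <- fake_spike_analysis(c(100, 110))       # ISI 10
  t2 <- fake_spike_analysis(c(100, 110, 140))  # ISIs 10, 30
  expect_equal(isi_difference_error(m1, t2, duration = 1000), 30 / 1000)
  expect_equal(isi_difference_error(t2, t2, duration = 1000), 0)
})

test_that("latency error is the squared latency gap over squared duration", {
  stim <- step_stimulus(0.3, 0, 900, 1000)
  m <- fake_spike_analysis(10)
  t <- fake_spike_analysis(30)
  expect_equal(latency_error(m, t, stim, duration = 1000), 400 / 1e6)
  expect_equal(latency_error(t, t, stim, duration = 1000), 0)
  silent <- fake_spike_analysis(numeric(0)) # sentinel latency 1000
  expect_equal(latency_error(silent, fake_spike_analysis(10), stim,
                             duration = 1000), (990 / 1000)^2)
})

test_that("AP overshoot error normalizes by the maximal target amplitude", {
  m <- fake_spike_analysis(100, amplitude = 80)
  t <- fake_spike_analysis(100, amplitude = 100)
  expect_equal(ap_overshoot_error(m, t), 400 / 10000)
  expect_equal(ap_overshoot_error(t, t), 0)
  silent <- fake_spike_analysis(numeric(0))
  expect_equal(ap_overshoot_error(silent, t), 1)
  expect_error(ap_overshoot_error(t, silent), "no spikes")
})

test_that("AP width error normalizes by the squared mean target width", {
  m <- fake_spike_analysis(100, base_width = 1)
  t <- fake_spike_analysis(100, base_width = 2)
  expect_equal(ap_width_error(m, t), 0.25) # (1-2)^2 / 2^2
  expect_equal(ap_width_error(t, t), 0)
  expect_equal(ap_width_error(fake_spike_analysis(numeric(0)), t), 1)
})

test_that("AHP depth error normalizes by the subthreshold target range", {
  m <- fake_spike_analysis(100, ahp_depth = 5)
  t <- fake_spike_analysis(100, ahp_depth = 8)
  expect_equal(ahp_depth_error(m, t, subthreshold_range = 30), 9 / 900)
  expect_equal(ahp_depth_error(t, t, subthreshold_range = 30), 0)
  expect_equal(ahp_depth_error(fake_spike_analysis(numeric(0)), t,
                               subthreshold_range = 30), 1)
})

test_that("feature-statistics error is a z-score with an undefined penalty", {
  ft <- feature_target("spike_count", exp_mean = 10, exp_std = 4)
  expect_equal(feature_stat_error(10, ft), 0)
  expect_equal(feature_stat_error(12, ft), 0.5)
  expect_equal(feature_stat_error(NA, ft), 250)
  expect_equal(feature_stat_error(NA, ft, penalty = 99), 99)
  expect_error(feature_target("x", 0, 0), "positive")
})

test_that("error vectors normalize weights and sum weighted components", {
  set.seed(4)
  t <- neuro_trace(cumsum(rnorm(60)), dt = 1, unit = "mV")
  m <- neuro_trace(t$values + rnorm(60, 0, 0.1), dt = 1, unit = "mV")
  spec <- list(error_component_spec("mse", weight = 1),
               error_component_spec("derivative_difference", weight = 1))
  ev <- evaluate_error_vector(m, t, spec)
  r1 <- mse_error(m, t)
  r2 <- derivative_difference_error(m, t)
  expect_equal(ev$components$raw_value, c(r1, r2))
  expect_equal(ev$total, (r1 + r2) / 2)
  # rescaling all weights by a common factor changes nothing
  spec10 <- list(error_component_spec("mse", weight = 10),
                 error_component_spec("derivative_difference", weight = 10))
  expect_equal(evaluate_error_vector(m, t, spec10)$total, ev$total)
  # unequal weights: weighted average with weights normalized to sum 1
  spec_w <- list(error_component_spec("mse", weight = 3),
                 error_component_spec("derivative_difference", weight = 1))
  expect_equal(evaluate_error_vector(m, t, spec_w)$total,
               0.75 * r1 + 0.25 * r2)
  expect_equal(evaluate_error_vector(t, t, spec)$total, 0)
})

test_that("a six-component weight vector summing to 1 is used unchanged", {
  # the weighting scheme of the simplified-active-model configuration:
  # 0.2 MSE-excluding-spikes, 0.4 spike count, 0.1 each for latency,
  # AP amplitude, AP width, AHP depth
  w <- c(0.2, 0.4, 0.1, 0.1, 0.1, 0.1)
  expect_equal(sum(w), 1)
  raw <- c(0.5, 0.25, 0.1, 0.2, 0.3, 0.4)
  ev <- neurofitr:::error_vector(paste0("c", 1:6), raw, w)
  expect_equal(ev$components$weight, w)
  expect_equal(ev$total, sum(raw * w))
})

test_that("component values are invariant to a common time shift", {
  tr <- simulate_hh(hh_params(), step_stimulus(0.3, 200, 500, 1000),
                    dt = 0.05)
  tr2 <- simulate_hh(hh_params(0.11, 0.034, 0.00028),
                     step_stimulus(0.3, 200, 500, 1000), dt = 0.05)
  shift <- function(x, by) neuro_trace(x$values, dt = x$dt, t0 = x$t0 + by,
                                       unit = x$unit, stimulus = x$stimulus)
  for (fn in list(mse_error, derivative_difference_error, spike_count_error,
                  ap_overshoot_error, ap_width_error)) {
    expect_equal(fn(shift(tr2, 77), shift(tr, 77)), fn(tr2, tr))
  }
})

test_that("unknown component names and negative weights are rejected", {
  expect_error(error_component_spec("nope"), "unknown")
  expect_error(error_component_spec("mse", weight = -1), "non-negative")
})
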