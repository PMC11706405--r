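# shared fixture builders (all data generated in code)

# flat voltage trace with a triangular spike-like deflection: baseline `base`
# mV, linear rise from t_on to t_peak reaching `peak` mV, symmetric fall
triangle_spike_trace <- function(t_on = 5, t_peak = 10, peak = 40,
                                 base = -65, total = 30, dt = 0.05) {
  tt <- seq(0, total, by = dt)
  up <- base + (peak - base) * (tt - t_on) / (t_peak - t_on)
  down <- peak - (peak - base) * (tt - t_peak) / (t_peak - t_on)
  v <- pmax(base, pmin(up, down))
  neuro_trace(v, dt = dt, unit = "mV")
}

# hand-built spike analysis with explicit per-spike features
fake_spike_analysis <- function(peak_time, amplitude = NA_real_,
                                base_width = NA_real_, ahp_depth = NA_real_,
                                threshold_v = NA_real_,
                                exclusion_half_width = 5) {
  n <- length(peak_time)
  sp <- data.frame(peak_time = peak_time,
                   peak_v = rep(NA_real_, n),
                   threshold_v = rep_len(threshold_v, n),
                   threshold_time = peak_time,
                   amplitude = rep_len(amplitude, n),
                   base_width = rep_len(base_width, n),
                   ahp_depth = rep_len(ahp_depth, n))
  win <- cbind(peak_time - exclusion_half_width,
               peak_time + exclusion_half_width)
  structure(list(spikes = sp, detect_threshold = 0,
                 exclusion_windows = neurofitr:::merge_windows(win)),
            class = "spike_analysis")
}

sphere_problem <- function(d = 3, lim = 5) {
  make_problem(parameter_space(paste0("x", seq_len(d)), rep(-lim, d),
                               rep(lim, d)),
               function(X) rowSums(X^2))
}

rosenbrock_problem <- function(d = 5, lim = 2) {
  make_problem(parameter_space(paste0("x", seq_len(d)), rep(-lim, d),
                               rep(lim, d)),
               function(X) apply(X, 1, function(x)
                 sum(100 * (x[-1] - x[-d]^2)^2 + (1 - x[-d])^2)))
}

# run_result with scripted per-generation totals: the objective replays the
# provided values in submission order, so generation statistics are exactly
# the prescribed ones
scripted_run <- function(gen_values) {
  vals <- unlist(gen_values)
  pop <- length(gen_values[[1]])
  env <- new.env(); env$i <- 0L
  prob <- make_problem(parameter_space("x", 0, 1), function(X) {
    n <- nrow(X)
    out <- vals[env$i + seq_len(n)]
    env$i <- env$i + n
    out
  })
  run_optimizer(prob, optimizer_config("random_search", pop_size = pop,
                                       n_generations = length(gen_values),
                                       seed = 1))
}

# brute-force Pareto ranking: repeatedly peel the non-dominated set
brute_force_ranks <- function(FF) {
  n <- nrow(FF)
  rank <- rep(NA_integer_, n)
  left <- seq_len(n)
  r <- 1L
  while (length(left)) {
    nd <- vapply(left, function(i) {
      !any(vapply(left, function(j) {
        j != i && all(FF[j, ] <= FF[i, ]) && any(FF[j, ] < FF[i, ])
      }, TRUE))
    }, TRUE)
    rank[left[nd]] <- r
    left <- left[!nd]
    r <- r + 1L
  }
  rank
}
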