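#' Detect action potentials and extract per-spike shape features
#'
#' One spike is reported per maximal upward crossing of `detect_threshold`.
#' For each spike:
#' * `peak_time`, `peak_v` — the maximum sample between the upward crossing
#'   and the subsequent downward crossing;
#' * `threshold_v`, `threshold_time` — voltage/time at the spike onset: the
#'   foot of the contiguous fast-upstroke run (forward-difference dV/dt at
#'   or above `slope_criterion`) through the steepest point of the rising
#'   phase, never reaching back beyond the previous spike's downward
#'   crossing; if the rising phase never attains the criterion, the
#'   detection crossing itself is used;
#' * `amplitude` — `peak_v - threshold_v`;
#' * `base_width` — time between the two crossings of `threshold_v` that
#'   bracket the peak, with sub-sample linear interpolation;
#' * `ahp_depth` — `threshold_v` minus the minimum voltage between this peak
#'   and the next spike's onset (or the end of the trace).
#'
#' Exclusion windows (`peak_time +/- exclusion_half_width`) are merged over
#' overlapping spikes and used by spike-excluding cost functions.
#'
#' @param trace A voltage [neuro_trace()] (unit `"mV"`).
#' @param detect_threshold Detection level, mV. Default 0 mV suits
#'   biophysical traces with full-height action potentials.
#' @param slope_criterion AP-onset criterion on dV/dt, mV/ms.
#' @param exclusion_half_width Half-width of the per-spike exclusion window,
#'   ms.
#' @return An object of class `spike_analysis`: a list with `spikes` (a
#'   data frame with one row per spike), `detect_threshold`, and
#'   `exclusion_windows` (two-column matrix of merged start/end times, ms).
#' @export
detect_spikes <- function(trace, detect_threshold = 0,
                          slope_criterion = 20, exclusion_half_width = 5) {
  stopifnot(inherits(trace, "neuro_trace"))
  if (trace$unit != "mV")
    stop("spike detection requires a voltage trace (unit mV)", call. = FALSE)
  m <- .detect_spikes_cpp(trace$values, trace$dt, trace$t0,
                          detect_threshold, slope_criterion)
  sp <- data.frame(peak_time = m[, 1], peak_v = m[, 2],
                   threshold_v = m[, 3], threshold_time = m[, 4],
                   amplitude = m[, 5], base_width = m[, 6],
                   ahp_depth = m[, 7])
  win <- cbind(sp$peak_time - exclusion_half_width,
               sp$peak_time + exclusion_half_width)
  structure(list(spikes = sp, detect_threshold = detect_threshold,
                 exclusion_windows = merge_windows(win)),
            class = "spike_analysis")
}

#' @export
print.spike_analysis <- function(x, ...) {
  cat(sprintf("<spike_analysis> %d spikes (detection threshold %g mV)\n",
              nrow(x$spikes), x$detect_threshold))
  if (nrow(x$spikes)) print(x$spikes)
  invisible(x)
}

#' Build a spike analysis directly from known spike times
#'
#' For models whose spike times are recorded explicitly (e.g. the adaptive
#' exponential integrate-and-fire simulator, whose clipped trace carries no
#' spike shape), detection by threshold crossing is inappropriate. This
#' constructor wraps an [event_train()] as a shape-free `spike_analysis`
#' usable by count/latency/ISI cost functions and exclusion windows.
#'
#' @param events An [event_train()] or numeric vector of spike times, ms.
#' @param exclusion_half_width Half-width of per-spike exclusion windows, ms.
#' @return A `spike_analysis` whose shape columns are `NA`.
#' @export
spike_analysis_from_events <- function(events, exclusion_half_width = 5) {
  times <- if (inherits(events, "event_train")) events$times
           else as.numeric(events)
  n <- length(times)
  na <- rep(NA_real_, n)
  sp <- data.frame(peak_time = times, peak_v = na, threshold_v = na,
                   threshold_time = times, amplitude = na, base_width = na,
                   ahp_depth = na)
  win <- cbind(times - exclusion_half_width, times + exclusion_half_width)
  structure(list(spikes = sp, detect_threshold = NA_real_,
                 exclusion_windows = merge_windows(win)),
            class = "spike_analysis")
}

# merge overlapping [start, end] windows; matrix with 2 columns
merge_windows <- function(win) {
  if (nrow(win) == 0L) return(matrix(numeric(0), ncol = 2))
  win <- win[order(win[, 1]), , drop = FALSE]
  out <- win[1, , drop = FALSE]
  for (i in seq_len(nrow(win))[-1]) {
    j <- nrow(out)
    if (win[i, 1] <= out[j, 2]) {
      out[j, 2] <- max(out[j, 2], win[i, 2])
    } else {
      out <- rbind(out, win[i, , drop = FALSE])
    }
  }
  out
}

# logical mask: which of `times` fall inside any (merged, sorted) window;
# intervals are closed on both ends
in_windows <- function(times, win) {
  if (nrow(win) == 0L) return(rep(FALSE, length(times)))
  bounds <- as.vector(t(win)) # s1 e1 s2 e2 ... strictly increasing
  fi <- findInterval(times, bounds)
  inside <- fi %% 2L == 1L
  on_end <- fi >= 2L & fi %% 2L == 0L
  inside[on_end] <- times[on_end] == bounds[fi[on_end]]
  inside
}

#' Latency from stimulus onset to the first spike
#'
#' Returns the time from `stimulus$delay` to the first spike peak at or
#' after the stimulus onset. If no such spike exists the total trace
#' duration is returned as a sentinel, so that the normalized latency error
#' of "no spike vs. any spike" is large but bounded.
#'
#' @param analysis A `spike_analysis`.
#' @param stimulus A [step_stimulus()].
#' @return Latency in ms.
#' @export
latency_to_first_spike <- function(analysis, stimulus) {
  stopifnot(inherits(analysis, "spike_analysis"),
            inherits(stimulus, "step_stimulus"))
  pk <- analysis$spikes$peak_time
  pk <- pk[pk >= stimulus$delay]
  if (length(pk) == 0L) return(stimulus$total_duration)
  pk[1] - stimulus$delay
}

#' Inter-spike intervals
#'
#' Successive differences of spike peak times; empty when fewer than two
#' spikes were detected.
#'
#' @param analysis A `spike_analysis`.
#' @return Numeric vector of ISIs, ms.
#' @export
isi_sequence <- function(analysis) {
  stopifnot(inherits(analysis, "spike_analysis"))
  pk <- analysis$spikes$peak_time
  if (length(pk) < 2L) return(numeric(0))
  diff(pk)
}
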