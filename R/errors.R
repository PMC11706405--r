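#' @title Trace- and spike-based cost functions
#'
#' @description
#' Each cost function compares a model trace to a target trace and returns a
#' unitless, non-negative scalar that is exactly 0 for identical traces
#' (where applicable). The model is linearly interpolated onto the target
#' grid first (the target is the fixed reference). Per-spike functions pair
#' spikes in temporal order up to the shorter spike count; the count
#' mismatch itself is the job of [spike_count_error()].
#'
#' @param model,target [neuro_trace()] objects; for per-spike errors a
#'   precomputed `spike_analysis` may be passed instead of a trace.
#' @param detect_threshold,slope_criterion,exclusion_half_width Spike
#'   detection settings forwarded to [detect_spikes()].
#' @name cost_functions
NULL

as_spike_analysis <- function(x, detect_threshold = 0, slope_criterion = 20,
                              exclusion_half_width = 5) {
  if (inherits(x, "spike_analysis")) return(x)
  detect_spikes(x, detect_threshold = detect_threshold,
                slope_criterion = slope_criterion,
                exclusion_half_width = exclusion_half_width)
}

#' Mean squared error, normalized by the squared target range
#'
#' Mean over paired samples of the squared difference, divided by
#' `(max(target) - min(target))^2`.
#'
#' @inheritParams cost_functions
#' @return Unitless non-negative scalar.
#' @export
mse_error <- function(model, target) {
  al <- align_traces(model, target)
  rng <- max(al$target) - min(al$target)
  if (rng <= 0)
    stop("degenerate target: constant trace has zero range", call. = FALSE)
  mean((al$model - al$target)^2) / rng^2
}

#' Mean squared error excluding the vicinity of action potentials
#'
#' As [mse_error()], but samples inside the union of the exclusion windows
#' of the spikes of either trace are dropped, and the normalizing range is
#' computed on the retained target samples only.
#'
#' @inheritParams cost_functions
#' @param model_spikes,target_spikes Optional precomputed `spike_analysis`
#'   objects (used by benchmarks whose spike times are recorded explicitly).
#' @return Unitless non-negative scalar.
#' @export
mse_excl_spikes_error <- function(model, target, detect_threshold = 0,
                                  slope_criterion = 20,
                                  exclusion_half_width = 5,
                                  model_spikes = NULL, target_spikes = NULL) {
  if (is.null(model_spikes))
    model_spikes <- as_spike_analysis(model, detect_threshold,
                                      slope_criterion, exclusion_half_width)
  if (is.null(target_spikes))
    target_spikes <- as_spike_analysis(target, detect_threshold,
                                       slope_criterion, exclusion_half_width)
  al <- align_traces(model, target)
  win <- merge_windows(rbind(model_spikes$exclusion_windows,
                             target_spikes$exclusion_windows))
  keep <- !in_windows(al$times, win)
  if (!any(keep))
    stop("all samples fall inside exclusion windows; empty support",
         call. = FALSE)
  m <- al$model[keep]; t <- al$target[keep]
  rng <- max(t) - min(t)
  if (rng <= 0)
    stop("degenerate target: retained samples have zero range", call. = FALSE)
  mean((m - t)^2) / rng^2
}

#' Mean squared difference of temporal derivatives
#'
#' Forward-difference derivatives `d[i] = (x[i+1] - x[i]) / dt` are compared
#' and the mean squared difference is divided by the squared range of the
#' target derivative. Insensitive to constant offsets between the traces.
#'
#' @inheritParams cost_functions
#' @return Unitless non-negative scalar.
#' @export
derivative_difference_error <- function(model, target) {
  al <- align_traces(model, target)
  if (length(al$target) < 3L)
    stop("derivative difference needs at least 3 paired samples",
         call. = FALSE)
  dm <- diff(al$model) / al$dt
  dt_ <- diff(al$target) / al$dt
  rng <- max(dt_) - min(dt_)
  if (rng <= 0)
    stop("degenerate target: derivative has zero range", call. = FALSE)
  mean((dm - dt_)^2) / rng^2
}

#' Spike-count error
#'
#' `|n_model - n_target| / (n_model + n_target)`, defined as 0 when both
#' counts are 0. Always in `[0, 1]`.
#'
#' @inheritParams cost_functions
#' @inheritParams mse_excl_spikes_error
#' @return Unitless scalar in `[0, 1]`.
#' @export
spike_count_error <- function(model, target, detect_threshold = 0,
                              slope_criterion = 20,
                              model_spikes = NULL, target_spikes = NULL) {
  if (is.null(model_spikes))
    model_spikes <- as_spike_analysis(model, detect_threshold, slope_criterion)
  if (is.null(target_spikes))
    target_spikes <- as_spike_analysis(target, detect_threshold,
                                       slope_criterion)
  count_error(nrow(model_spikes$spikes), nrow(target_spikes$spikes))
}

count_error <- function(nm, nt) {
  if (nm + nt == 0L) return(0)
  abs(nm - nt) / (nm + nt)
}

#' Spike-count error restricted to the stimulus window
#'
#' As [spike_count_error()] but only spikes whose peak lies within
#' `[delay, delay + duration]` of the stimulus are counted.
#'
#' @inheritParams spike_count_error
#' @param stimulus A [step_stimulus()]; defaults to the target's stimulus.
#' @return Unitless scalar in `[0, 1]`.
#' @export
spike_count_during_stimulus_error <- function(model, target, stimulus = NULL,
                                              detect_threshold = 0,
                                              slope_criterion = 20,
                                              model_spikes = NULL,
                                              target_spikes = NULL) {
  if (is.null(stimulus) && inherits(target, "neuro_trace"))
    stimulus <- target$stimulus
  if (is.null(stimulus))
    stop("spike_count_during_stimulus requires a stimulus definition",
         call. = FALSE)
  if (is.null(model_spikes))
    model_spikes <- as_spike_analysis(model, detect_threshold, slope_criterion)
  if (is.null(target_spikes))
    target_spikes <- as_spike_analysis(target, detect_threshold,
                                       slope_criterion)
  lo <- stimulus$delay
  hi <- stimulus$delay + stimulus$duration
  nm <- sum(model_spikes$spikes$peak_time >= lo &
            model_spikes$spikes$peak_time <= hi)
  nt <- sum(target_spikes$spikes$peak_time >= lo &
            target_spikes$spikes$peak_time <= hi)
  count_error(nm, nt)
}

#' Inter-spike-interval difference error
#'
#' ISIs of the two trains are paired in order up to the shorter sequence;
#' the sum of absolute paired differences, plus the values of unpaired ISIs,
#' is divided by the trace duration (ms).
#'
#' @inheritParams spike_count_error
#' @param duration Trace duration used for normalization, ms; defaults to
#'   the target's duration.
#' @return Unitless non-negative scalar.
#' @export
isi_difference_error <- function(model, target, duration = NULL,
                                 detect_threshold = 0, slope_criterion = 20,
                                 model_spikes = NULL, target_spikes = NULL) {
  if (is.null(duration)) {
    if (!inherits(target, "neuro_trace"))
      stop("duration must be supplied when target is not a trace",
           call. = FALSE)
    duration <- trace_duration(target)
  }
  if (is.null(model_spikes))
    model_spikes <- as_spike_analysis(model, detect_threshold, slope_criterion)
  if (is.null(target_spikes))
    target_spikes <- as_spike_analysis(target, detect_threshold,
                                       slope_criterion)
  im <- isi_sequence(model_spikes)
  it <- isi_sequence(target_spikes)
  k <- min(length(im), length(it))
  tot <- 0
  if (k > 0) tot <- tot + sum(abs(im[seq_len(k)] - it[seq_len(k)]))
  if (length(im) > k) tot <- tot + sum(im[-seq_len(k)])
  if (length(it) > k) tot <- tot + sum(it[-seq_len(k)])
  tot / duration
}

#' Latency-to-first-spike error
#'
#' Squared difference of the two latencies (model vs. target, measured from
#' stimulus onset, with the no-spike sentinel of
#' [latency_to_first_spike()]), divided by the squared trace duration.
#' Always in `[0, 1]`.
#'
#' @inheritParams spike_count_during_stimulus_error
#' @param duration Trace duration for normalization, ms; defaults to the
#'   target's duration.
#' @return Unitless scalar in `[0, 1]`.
#' @export
latency_error <- function(model, target, stimulus = NULL, duration = NULL,
                          detect_threshold = 0, slope_criterion = 20,
                          model_spikes = NULL, target_spikes = NULL) {
  if (is.null(stimulus) && inherits(target, "neuro_trace"))
    stimulus <- target$stimulus
  if (is.null(stimulus))
    stop("latency error requires a stimulus definition", call. = FALSE)
  if (is.null(duration)) {
    duration <- if (inherits(target, "neuro_trace")) trace_duration(target)
                else stimulus$total_duration
  }
  if (is.null(model_spikes))
    model_spikes <- as_spike_analysis(model, detect_threshold, slope_criterion)
  if (is.null(target_spikes))
    target_spikes <- as_spike_analysis(target, detect_threshold,
                                       slope_criterion)
  lm_ <- latency_to_first_spike(model_spikes, stimulus)
  lt_ <- latency_to_first_spike(target_spikes, stimulus)
  (lm_ - lt_)^2 / duration^2
}

# ordered pairing of a per-spike feature column up to the shorter count;
# returns NULL when the model is silent (penalty handled by caller)
paired_feature <- function(model_spikes, target_spikes, col) {
  fm <- model_spikes$spikes[[col]]
  ft <- target_spikes$spikes[[col]]
  if (length(ft) == 0L)
    stop("target trace has no spikes; per-spike error not applicable",
         call. = FALSE)
  if (length(fm) == 0L) return(NULL)
  k <- min(length(fm), length(ft))
  list(model = fm[seq_len(k)], target = ft[seq_len(k)], all_target = ft)
}

#' Action-potential overshoot (amplitude) error
#'
#' Spike amplitudes (peak voltage minus AP threshold) are paired in order;
#' the mean squared amplitude difference is divided by the squared maximal
#' target amplitude. A spike-free model scores the maximal penalty 1.
#'
#' @inheritParams spike_count_error
#' @param silent_penalty Value returned when the model has no spikes.
#' @return Unitless non-negative scalar.
#' @export
ap_overshoot_error <- function(model, target, detect_threshold = 0,
                               slope_criterion = 20, silent_penalty = 1,
                               model_spikes = NULL, target_spikes = NULL) {
  if (is.null(model_spikes))
    model_spikes <- as_spike_analysis(model, detect_threshold, slope_criterion)
  if (is.null(target_spikes))
    target_spikes <- as_spike_analysis(target, detect_threshold,
                                       slope_criterion)
  p <- paired_feature(model_spikes, target_spikes, "amplitude")
  if (is.null(p)) return(silent_penalty)
  mean((p$model - p$target)^2) / max(p$all_target)^2
}

#' Action-potential base-width error
#'
#' Base widths (duration at the AP threshold level) are paired in order; the
#' mean squared width difference is divided by the squared mean target
#' width. A spike-free model scores the maximal penalty 1.
#'
#' @inheritParams ap_overshoot_error
#' @return Unitless non-negative scalar.
#' @export
ap_width_error <- function(model, target, detect_threshold = 0,
                           slope_criterion = 20, silent_penalty = 1,
                           model_spikes = NULL, target_spikes = NULL) {
  if (is.null(model_spikes))
    model_spikes <- as_spike_analysis(model, detect_threshold, slope_criterion)
  if (is.null(target_spikes))
    target_spikes <- as_spike_analysis(target, detect_threshold,
                                       slope_criterion)
  p <- paired_feature(model_spikes, target_spikes, "base_width")
  if (is.null(p)) return(silent_penalty)
  mean((p$model - p$target)^2) / mean(p$all_target)^2
}

#' After-hyperpolarization depth error
#'
#' AHP depths are paired in order; the mean squared depth difference is
#' divided by the squared range of the target's subthreshold voltage (the
#' samples outside its spike exclusion windows). A spike-free model scores
#' the maximal penalty 1.
#'
#' @inheritParams ap_overshoot_error
#' @param subthreshold_range Optional externally supplied normalization
#'   range, mV; computed from the target trace when omitted.
#' @return Unitless non-negative scalar.
#' @export
ahp_depth_error <- function(model, target, detect_threshold = 0,
                            slope_criterion = 20, silent_penalty = 1,
                            subthreshold_range = NULL,
                            model_spikes = NULL, target_spikes = NULL) {
  if (is.null(model_spikes))
    model_spikes <- as_spike_analysis(model, detect_threshold, slope_criterion)
  if (is.null(target_spikes))
    target_spikes <- as_spike_analysis(target, detect_threshold,
                                       slope_criterion)
  p <- paired_feature(model_spikes, target_spikes, "ahp_depth")
  if (is.null(subthreshold_range)) {
    if (!inherits(target, "neuro_trace"))
      stop("subthreshold_range must be supplied when target is not a trace",
           call. = FALSE)
    keep <- !in_windows(trace_times(target), target_spikes$exclusion_windows)
    sub <- target$values[keep]
    if (length(sub) < 2L)
      stop("no subthreshold samples in target", call. = FALSE)
    subthreshold_range <- max(sub) - min(sub)
  }
  if (subthreshold_range <= 0)
    stop("degenerate target: subthreshold range is zero", call. = FALSE)
  if (is.null(p)) return(silent_penalty)
  mean((p$model - p$target)^2) / subthreshold_range^2
}

#' Feature-statistics error (z-score deviation)
#'
#' Absolute deviation of a model feature value from the experimental mean in
#' units of the experimental standard deviation. Undefined features (e.g. an
#' AP shape feature of a silent model, passed as `NA`) score a large
#' conventional penalty.
#'
#' @param value Model feature value (feature units); `NA` if undefined.
#' @param target A [feature_target()].
#' @param penalty Score for undefined features.
#' @return Unitless non-negative scalar.
#' @export
feature_stat_error <- function(value, target, penalty = 250) {
  stopifnot(inherits(target, "feature_target"))
  if (is.na(value)) return(penalty)
  abs(value - target$exp_mean) / target$exp_std
}

#' Feature target: experimental mean and standard deviation of a feature
#'
#' @param feature_name Feature label.
#' @param exp_mean,exp_std Experimental mean and standard deviation
#'   (feature units); `exp_std` must be positive.
#' @param stimulus_amplitude Associated stimulus amplitude, nA.
#' @param weight Non-negative weight used when combining errors.
#' @return An object of class `feature_target`.
#' @export
feature_target <- function(feature_name, exp_mean, exp_std,
                           stimulus_amplitude = NA_real_, weight = 1) {
  if (!is.numeric(exp_std) || exp_std <= 0)
    stop("exp_std must be positive", call. = FALSE)
  if (weight < 0) stop("weight must be non-negative", call. = FALSE)
  structure(list(feature_name = feature_name, exp_mean = exp_mean,
                 exp_std = exp_std, stimulus_amplitude = stimulus_amplitude,
                 weight = weight),
            class = "feature_target")
}

# registry of trace-comparison component names -> functions
error_component_registry <- function() {
  list(
    mse = function(model, target, opt)
      mse_error(model, target),
    mse_excl_spikes = function(model, target, opt)
      do.call(mse_excl_spikes_error, c(list(model, target), opt)),
    derivative_difference = function(model, target, opt)
      derivative_difference_error(model, target),
    spike_count = function(model, target, opt)
      do.call(spike_count_error, c(list(model, target), opt)),
    spike_count_during_stimulus = function(model, target, opt)
      do.call(spike_count_during_stimulus_error, c(list(model, target), opt)),
    isi_difference = function(model, target, opt)
      do.call(isi_difference_error, c(list(model, target), opt)),
    latency = function(model, target, opt)
      do.call(latency_error, c(list(model, target), opt)),
    ap_overshoot = function(model, target, opt)
      do.call(ap_overshoot_error, c(list(model, target), opt)),
    ap_width = function(model, target, opt)
      do.call(ap_width_error, c(list(model, target), opt)),
    ahp_depth = function(model, target, opt)
      do.call(ahp_depth_error, c(list(model, target), opt))
  )
}

#' Specification of one weighted error component
#'
#' @param name One of `"mse"`, `"mse_excl_spikes"`,
#'   `"derivative_difference"`, `"spike_count"`,
#'   `"spike_count_during_stimulus"`, `"isi_difference"`, `"latency"`,
#'   `"ap_overshoot"`, `"ap_width"`, `"ahp_depth"`.
#' @param weight Non-negative weight. Weights are normalized to sum 1 when
#'   components are combined, so only ratios matter.
#' @param options Named list of options forwarded to the component function
#'   (detection thresholds, exclusion window widths, ...).
#' @return An object of class `error_component_spec`.
#' @export
error_component_spec <- function(name, weight = 1, options = list()) {
  if (!name %in% names(error_component_registry()))
    stop("unknown error component: ", name, call. = FALSE)
  if (!is.numeric(weight) || weight < 0)
    stop("weight must be non-negative", call. = FALSE)
  structure(list(name = name, weight = weight, options = options),
            class = "error_component_spec")
}

#' Evaluate a weighted combination of error components
#'
#' Computes every component of `spec` on the model/target pair, normalizes
#' the weights to sum 1 (the combination is a weighted average, so a common
#' rescaling of all weights has no effect), and returns the per-component
#' raw values, normalized weights, weighted values, and their total.
#'
#' @param model,target [neuro_trace()] objects (or lists of traces of equal
#'   length, in which case each component is averaged over the trace pairs).
#' @param spec A list of [error_component_spec()] objects.
#' @return An object of class `error_vector`: a list with `components` (data
#'   frame with columns `name`, `raw_value`, `weight`, `weighted_value`) and
#'   `total`.
#' @export
evaluate_error_vector <- function(model, target, spec) {
  if (inherits(spec, "error_component_spec")) spec <- list(spec)
  stopifnot(length(spec) >= 1L,
            all(vapply(spec, inherits, TRUE, "error_component_spec")))
  models <- if (inherits(model, "neuro_trace")) list(model) else model
  targets <- if (inherits(target, "neuro_trace")) list(target) else target
  if (length(models) != length(targets))
    stop("model and target trace lists must have equal length", call. = FALSE)
  reg <- error_component_registry()
  w <- vapply(spec, function(s) s$weight, 0)
  if (sum(w) <= 0) stop("weights must not all be zero", call. = FALSE)
  w <- w / sum(w)
  raw <- vapply(seq_along(spec), function(i) {
    s <- spec[[i]]
    vals <- vapply(seq_along(models), function(j) {
      tryCatch(reg[[s$name]](models[[j]], targets[[j]], s$options),
               error = function(e)
                 stop(sprintf("error component '%s' failed: %s",
                              s$name, conditionMessage(e)), call. = FALSE))
    }, 0)
    mean(vals)
  }, 0)
  error_vector(vapply(spec, function(s) s$name, ""), raw, w)
}

# assemble an error_vector from names, raw values and normalized weights
error_vector <- function(names, raw, weights) {
  comp <- data.frame(name = names, raw_value = raw, weight = weights,
                     weighted_value = raw * weights,
                     stringsAsFactors = FALSE)
  structure(list(components = comp, total = sum(comp$weighted_value)),
            class = "error_vector")
}

#' @export
print.error_vector <- function(x, ...) {
  cat("<error_vector>\n")
  print(x$components)
  cat(sprintf("total: %g\n", x$total))
  invisible(x)
}
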