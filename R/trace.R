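#' Step-current stimulus description
#'
#' A rectangular current step: `amplitude` nA delivered from `delay` ms for
#' `duration` ms, within a recording of `total_duration` ms.
#'
#' @param amplitude Step amplitude in nA.
#' @param delay Onset time from the start of the recording, ms.
#' @param duration Step length, ms.
#' @param total_duration Total recording length, ms.
#' @return An object of class `step_stimulus`.
#' @examples
#' step_stimulus(0.3, 200, 500, 1000)
#' @export
step_stimulus <- function(amplitude, delay, duration, total_duration) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude))
  stopifnot(delay >= 0, duration > 0, delay + duration <= total_duration)
  structure(
    list(amplitude = amplitude, delay = delay, duration = duration,
         total_duration = total_duration),
    class = "step_stimulus"
  )
}

#' Uniformly sampled time series (voltage or current trace)
#'
#' The core container shared by simulators, cost functions and I/O. Sample
#' `i` (1-based) occurs at `t0 + (i - 1) * dt`.
#'
#' @param values Numeric vector of samples (mV for voltage, nA for current).
#' @param dt Sampling interval, ms. Must be positive.
#' @param t0 Time of the first sample, ms.
#' @param unit Either `"mV"` or `"nA"`.
#' @param stimulus Optional [step_stimulus()] describing the protocol.
#' @return An object of class `neuro_trace`.
#' @export
neuro_trace <- function(values, dt, t0 = 0, unit = c("mV", "nA"),
                        stimulus = NULL) {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a trace needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(values)))
    stop("trace samples must all be finite", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (ms)", call. = FALSE)
  if (!is.null(stimulus) && !inherits(stimulus, "step_stimulus"))
    stop("stimulus must be a step_stimulus or NULL", call. = FALSE)
  structure(
    list(values = values, dt = dt, t0 = t0, unit = unit, stimulus = stimulus),
    class = "neuro_trace"
  )
}

#' @export
print.neuro_trace <- function(x, ...) {
  cat(sprintf("<neuro_trace> %d samples, dt = %g ms, t0 = %g ms, unit = %s\n",
              length(x$values), x$dt, x$t0, x$unit))
  cat(sprintf("  span [%g, %g] ms, range [%g, %g] %s\n",
              x$t0, trace_end(x), min(x$values), max(x$values), x$unit))
  if (!is.null(x$stimulus))
    cat(sprintf("  stimulus: %g nA, delay %g ms, duration %g ms\n",
                x$stimulus$amplitude, x$stimulus$delay, x$stimulus$duration))
  invisible(x)
}

#' Sample times of a trace
#' @param trace A [neuro_trace()].
#' @return Numeric vector of sample times, ms.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1) * trace$dt
}

#' Time of the last sample of a trace (ms)
#' @param trace A [neuro_trace()].
#' @export
trace_end <- function(trace) {
  trace$t0 + (length(trace$values) - 1) * trace$dt
}

#' Duration spanned by a trace (ms)
#' @param trace A [neuro_trace()].
#' @export
trace_duration <- function(trace) {
  (length(trace$values) - 1) * trace$dt
}

#' Ordered train of event (spike) times
#'
#' @param times Strictly increasing numeric vector of event times, ms.
#' @return An object of class `event_train`.
#' @export
event_train <- function(times = numeric(0)) {
  times <- as.numeric(times)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("event times must be strictly increasing", call. = FALSE)
  if (!all(is.finite(times)))
    stop("event times must be finite", call. = FALSE)
  structure(list(times = times), class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %d events\n", length(x$times)))
  invisible(x)
}

#' Read a plain-text trace file
#'
#' Accepts one numeric value per line (samples only; `dt` must be given) or
#' two whitespace-separated columns (time, value), in which case `dt` is
#' inferred from the first two rows and the sampling must be uniform to a
#' relative tolerance of 1e-6. Lines starting with `#` are ignored.
#'
#' @param path File to read.
#' @param dt Sampling interval in ms; required for one-column files,
#'   cross-checked against the time column for two-column files if supplied.
#' @param unit Sample unit, `"mV"` or `"nA"`.
#' @param stimulus Optional [step_stimulus()] to attach.
#' @return A [neuro_trace()].
#' @export
read_trace <- function(path, dt = NULL, unit = c("mV", "nA"), stimulus = NULL) {
  unit <- match.arg(unit)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L)
    stop("trace file must contain at least 2 data rows: ", path, call. = FALSE)
  fields <- strsplit(lines, "[ \t]+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L || !ncol %in% c(1L, 2L))
    stop("trace file must have 1 or 2 whitespace-separated columns: ", path,
         call. = FALSE)
  mat <- suppressWarnings(matrix(as.numeric(unlist(fields)),
                                 ncol = ncol, byrow = TRUE))
  if (anyNA(mat))
    stop("non-numeric content in trace file: ", path, call. = FALSE)
  if (ncol == 1L) {
    if (is.null(dt))
      stop("dt is required for one-column trace files", call. = FALSE)
    return(neuro_trace(mat[, 1], dt = dt, t0 = 0, unit = unit,
                       stimulus = stimulus))
  }
  tcol <- mat[, 1]
  dts <- diff(tcol)
  dt_inferred <- dts[1]
  if (dt_inferred <= 0 ||
      any(abs(dts - dt_inferred) > 1e-6 * abs(dt_inferred)))
    stop("two-column trace file is not uniformly sampled: ", path,
         call. = FALSE)
  if (!is.null(dt) && abs(dt - dt_inferred) > 1e-6 * dt)
    stop(sprintf("dt mismatch: file has %g ms, %g ms requested", dt_inferred,
                 dt), call. = FALSE)
  neuro_trace(mat[, 2], dt = dt_inferred, t0 = tcol[1], unit = unit,
              stimulus = stimulus)
}

#' Write a trace as two-column plain text
#'
#' Writes (time, value) rows at full double precision so that
#' [read_trace()] inverts it bit-exactly.
#'
#' @param trace A [neuro_trace()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "neuro_trace"))
  tt <- trace_times(trace)
  out <- paste(sprintf("%.17g", tt), sprintf("%.17g", trace$values))
  writeLines(out, path)
  invisible(path)
}

#' Align a model trace to a target trace
#'
#' If the two traces share the same grid (equal `dt` to relative 1e-9, equal
#' length, equal `t0`), returns the raw sample vectors. Otherwise the model
#' is linearly interpolated onto the target's time grid, restricted to the
#' overlapping time interval. The target grid always wins: target samples
#' are never resampled.
#'
#' @param model,target [neuro_trace()] objects with the same unit.
#' @return A list with `model`, `target` (paired numeric vectors of equal
#'   length), `dt` and `times` of the paired grid.
#' @export
align_traces <- function(model, target) {
  stopifnot(inherits(model, "neuro_trace"), inherits(target, "neuro_trace"))
  if (model$unit != target$unit)
    stop("cannot align traces with different units", call. = FALSE)
  same_grid <- length(model$values) == length(target$values) &&
    abs(model$dt - target$dt) <= 1e-9 * target$dt &&
    abs(model$t0 - target$t0) <= 1e-9 * max(target$dt, abs(target$t0))
  if (same_grid) {
    return(list(model = model$values, target = target$values,
                dt = target$dt, times = trace_times(target)))
  }
  lo <- max(model$t0, target$t0)
  hi <- min(trace_end(model), trace_end(target))
  if (lo > hi)
    stop("traces have no temporal overlap; cannot align", call. = FALSE)
  tt <- trace_times(target)
  keep <- tt >= lo - 1e-9 * target$dt & tt <= hi + 1e-9 * target$dt
  tt <- tt[keep]
  if (length(tt) < 2L)
    stop("overlap contains fewer than 2 target samples", call. = FALSE)
  m <- stats::approx(trace_times(model), model$values, xout = tt,
                     method = "linear", rule = 1)$y
  list(model = m, target = target$values[keep], dt = target$dt, times = tt)
}
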