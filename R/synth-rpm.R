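# Abdominal-wall respiration-monitoring traces (RPM-like) for one breath-hold.
# The study statistic is the amplitude, defined as max(position) - min(position)
# of the abdominal wall during the hold; the waveform itself is unconstrained,
# so we use a plateau with a slow ripple plus jitter, affinely rescaled so the
# realized amplitude is exact.

#' Simulate an abdominal-wall breath-hold trace
#'
#' Generates a plateau-shaped anterior-posterior abdominal wall position trace
#' for one voluntary breath-hold, as an infrared-marker respiration monitor
#' would record it. The waveform is a slow sinusoidal ripple (0.25 Hz) with a
#' weak second harmonic and Gaussian jitter, rescaled so that
#' `compute_amplitude()` of the result equals `amplitude_mm` exactly.
#' Gating thresholds bracket the plateau.
#'
#' @param duration_s breath-hold duration in seconds (> 0).
#' @param amplitude_mm peak-to-trough excursion of the wall during the hold,
#'   mm (>= 0). Study scale: 1.36 +/- 0.94 mm.
#' @param baseline_mm mean plateau position, mm.
#' @param sample_rate_hz monitor sampling rate (default 25 Hz).
#' @param seed optional integer seed.
#' @return An object of class `"rpm_trace"`: list with `time_s`,
#'   `position_mm`, `gate_lower_mm`, `gate_upper_mm`.
#' @export
#' @examples
#' tr <- simulate_rpm_trace(20.4, amplitude_mm = 1.36, seed = 1)
#' compute_amplitude(tr)
simulate_rpm_trace <- function(duration_s, amplitude_mm, baseline_mm = 0,
                               sample_rate_hz = 25, seed = NULL) {
  .check_scalar(duration_s, "duration_s", min = .Machine$double.eps)
  .check_scalar(amplitude_mm, "amplitude_mm", min = 0)
  .check_scalar(baseline_mm, "baseline_mm")
  .check_scalar(sample_rate_hz, "sample_rate_hz", min = .Machine$double.eps)
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- max(round(duration_s * sample_rate_hz), 1)
  t <- (seq_len(n) - 1L) / sample_rate_hz

  if (amplitude_mm == 0 || n == 1L) {
    pos <- rep(baseline_mm, n)
  } else {
    raw <- sin(2 * pi * 0.25 * t) +
      0.15 * sin(2 * pi * 0.275 * t + 1) +
      rnorm(n, 0, 0.05)
    # rescale so max - min == amplitude exactly, centred on the baseline
    pos <- baseline_mm +
      (raw - min(raw)) / (max(raw) - min(raw)) * amplitude_mm - amplitude_mm / 2
  }

  gate <- amplitude_mm / 2 + 1.0   # 1 mm guard band outside the plateau
  structure(list(
    time_s = t,
    position_mm = pos,
    gate_lower_mm = baseline_mm - gate,
    gate_upper_mm = baseline_mm + gate
  ), class = "rpm_trace")
}

#' Amplitude of a respiration trace
#'
#' The amplitude is the difference between the maxima and minima of the
#' abdominal wall position over the trace.
#'
#' @param trace an `"rpm_trace"` or a numeric vector of positions in mm.
#' @return Amplitude in mm (non-negative scalar).
#' @export
compute_amplitude <- function(trace) {
  pos <- if (inherits(trace, "rpm_trace")) trace$position_mm else trace
  if (!is.numeric(pos) || length(pos) == 0L)
    stop_invalid("trace", "must contain at least one position sample")
  if (any(!is.finite(pos)))
    stop_invalid("trace", "positions must be finite")
  max(pos) - min(pos)
}

#' @export
print.rpm_trace <- function(x, ...) {
  cat(sprintf(
    "Respiration trace: %d samples over %.1f s, amplitude %.2f mm, gates [%.2f, %.2f] mm\n",
    length(x$time_s), max(x$time_s), compute_amplitude(x),
    x$gate_lower_mm, x$gate_upper_mm))
  invisible(x)
}
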