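# Synthetic chest-wall error traces under the nested random-effect model
#
#   y[p,f,k] = M + a[p] + b[p,f] + e[p,f,k]
#   a ~ N(0, sigma_pt^2),  b ~ N(0, sigma_fr^2),  e ~ N(0, sigma_intra^2)
#
# The defaults reproduce the study design this package targets: 25 patients,
# 16 fractions, two tangential fields per fraction, breath-holds of
# 20.4 +/- 1.7 s imaged at 9.5 Hz with two holds per field (~= 310k frames).

#' Specify a synthetic breath-hold error simulation
#'
#' Describes the design (patients, fractions, fields, frames) and the
#' ground-truth parameters of the nested Gaussian error model used by
#' [simulate_errors()]. Defaults are the study-scale values: overall mean
#' 0.30 mm, inter-patient SD 0.82 mm, inter-fraction SD 1.19 mm,
#' intra-fraction SD 1.63 mm, 25 patients x 16 fractions x 2 fields.
#'
#' Frame counts per field are either fixed (`frames_per_field`) or drawn as
#' `round(breath_hold_s * frame_rate_hz)` summed over `breath_holds_per_field`
#' breath-holds, each hold's duration drawn from
#' `Normal(breath_hold_s[1], breath_hold_s[2])` (floored at 5 s).
#'
#' @param n_patients number of patients (>= 1).
#' @param n_fractions treatment fractions per patient (>= 1).
#' @param n_fields imaged fields per fraction (default 2, the tangential pair).
#' @param frames_per_field fixed number of cine frames per field, or `NULL`
#'   to draw counts from the breath-hold model.
#' @param mean_M overall mean error, mm.
#' @param sigma_pt inter-patient SD, mm (>= 0).
#' @param sigma_fr inter-fraction SD, mm (>= 0).
#' @param sigma_intra intra-fraction (residual) SD, mm (>= 0).
#' @param breath_hold_s length-2 numeric, mean and SD of one breath-hold
#'   duration in seconds.
#' @param breath_holds_per_field breath-holds imaged per field.
#' @param frame_rate_hz cine frame rate, frames per second (> 0).
#' @param seed integer seed used by [simulate_errors()]; `NULL` leaves the
#'   RNG state alone.
#' @return An object of class `"simulation_spec"`.
#' @seealso [simulate_errors()]
#' @export
#' @examples
#' spec <- simulation_spec(n_patients = 4, n_fractions = 3,
#'                         frames_per_field = 10, seed = 1)
#' head(simulate_errors(spec))
simulation_spec <- function(n_patients = 25, n_fractions = 16, n_fields = 2,
                            frames_per_field = NULL,
                            mean_M = 0.30, sigma_pt = 0.82, sigma_fr = 1.19,
                            sigma_intra = 1.63,
                            breath_hold_s = c(20.4, 1.7),
                            breath_holds_per_field = 2,
                            frame_rate_hz = 9.5,
                            seed = NULL) {
  .check_scalar(n_patients, "n_patients", min = 1, integer = TRUE)
  .check_scalar(n_fractions, "n_fractions", min = 1, integer = TRUE)
  .check_scalar(n_fields, "n_fields", min = 1, integer = TRUE)
  if (!is.null(frames_per_field))
    .check_scalar(frames_per_field, "frames_per_field", min = 1, integer = TRUE)
  .check_scalar(mean_M, "mean_M")
  .check_scalar(sigma_pt, "sigma_pt", min = 0)
  .check_scalar(sigma_fr, "sigma_fr", min = 0)
  .check_scalar(sigma_intra, "sigma_intra", min = 0)
  if (!is.numeric(breath_hold_s) || length(breath_hold_s) != 2L ||
      any(!is.finite(breath_hold_s)) || breath_hold_s[1] <= 0 ||
      breath_hold_s[2] < 0)
    stop_invalid("breath_hold_s", "must be c(mean > 0, sd >= 0) in seconds")
  .check_scalar(breath_holds_per_field, "breath_holds_per_field",
                min = 1, integer = TRUE)
  .check_scalar(frame_rate_hz, "frame_rate_hz", min = .Machine$double.eps)
  if (!is.null(seed)) .check_scalar(seed, "seed", integer = TRUE)

  structure(list(
    n_patients = as.integer(n_patients),
    n_fractions = as.integer(n_fractions),
    n_fields = as.integer(n_fields),
    frames_per_field = if (is.null(frames_per_field)) NULL
                       else as.integer(frames_per_field),
    mean_M = mean_M, sigma_pt = sigma_pt, sigma_fr = sigma_fr,
    sigma_intra = sigma_intra,
    breath_hold_s = as.numeric(breath_hold_s),
    breath_holds_per_field = as.integer(breath_holds_per_field),
    frame_rate_hz = frame_rate_hz,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("Synthetic DIBH error simulation spec\n")
  cat(sprintf("  design: %d patients x %d fractions x %d fields\n",
              x$n_patients, x$n_fractions, x$n_fields))
  if (is.null(x$frames_per_field))
    cat(sprintf("  frames/field: %d holds x N(%.1f, %.1f) s at %.1f Hz\n",
                x$breath_holds_per_field, x$breath_hold_s[1],
                x$breath_hold_s[2], x$frame_rate_hz))
  else
    cat(sprintf("  frames/field: %d (fixed)\n", x$frames_per_field))
  cat(sprintf("  truth (mm): M=%.3g Sigma_pt=%.3g sigma_fr=%.3g sigma_intra=%.3g\n",
              x$mean_M, x$sigma_pt, x$sigma_fr, x$sigma_intra))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

.field_labels <- function(n) {
  if (n == 2L) c("medial", "lateral") else sprintf("F%02d", seq_len(n))
}

#' Simulate chest-wall positional errors
#'
#' Draws one observation per cine frame from the nested Gaussian model
#' `y = M + a_patient + b_patient:fraction + e`, with independent zero-mean
#' Gaussian effects with SDs `sigma_pt`, `sigma_fr` and `sigma_intra`.
#' Fields are labels only: both tangential fields of a fraction share the
#' fraction effect, matching a model with patient and fraction levels only.
#' Generation is bit-reproducible for a fixed seed.
#'
#' @param spec a [simulation_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return A data frame with columns `patient_id`, `fraction`, `field`,
#'   `frame` (index within field), `time_s` (beam-on time within field) and
#'   `error_mm` (signed displacement; deep inspiration positive).
#' @export
simulate_errors <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "simulation_spec"))
    stop_invalid("spec", "must be a simulation_spec object")
  if (!is.null(seed)) set.seed(as.integer(seed))

  P <- spec$n_patients; FR <- spec$n_fractions; FD <- spec$n_fields
  a <- rnorm(P, 0, spec$sigma_pt)
  b <- rnorm(P * FR, 0, spec$sigma_fr)          # indexed (p-1)*FR + f

  n_units <- P * FR * FD                        # one unit = one field
  unit_p <- rep(seq_len(P), each = FR * FD)
  unit_f <- rep(rep(seq_len(FR), each = FD), times = P)
  unit_d <- rep(seq_len(FD), times = P * FR)

  if (is.null(spec$frames_per_field)) {
    holds <- spec$breath_holds_per_field
    dur <- rnorm(n_units * holds, spec$breath_hold_s[1], spec$breath_hold_s[2])
    dur <- pmax(dur, 5)
    k_hold <- pmax(round(dur * spec$frame_rate_hz), 1L)
    counts <- as.integer(rowSums(matrix(k_hold, nrow = n_units, ncol = holds)))
  } else {
    counts <- rep(spec$frames_per_field, n_units)
  }

  total <- sum(counts)
  e <- rnorm(total, 0, spec$sigma_intra)
  obs_unit <- rep(seq_len(n_units), counts)
  frame <- sequence(counts)

  y <- spec$mean_M + a[unit_p[obs_unit]] +
    b[(unit_p[obs_unit] - 1L) * FR + unit_f[obs_unit]] + e

  data.frame(
    patient_id = sprintf("P%02d", unit_p[obs_unit]),
    fraction = unit_f[obs_unit],
    field = .field_labels(FD)[unit_d[obs_unit]],
    frame = frame,
    time_s = (frame - 1L) / spec$frame_rate_hz,
    error_mm = y,
    stringsAsFactors = FALSE
  )
}
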