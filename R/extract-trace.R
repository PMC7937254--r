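# Frame-stack -> positional-error trace: per-frame edge detection, conversion
# from detector pixels to mm at the isocenter plane, subtraction of the DRR
# reference position, and the sign convention (deep inspiration positive).

#' Convert a detector pixel displacement to mm at the isocenter plane
#'
#' Divergent-beam scaling: `mm = pixels * detector_pitch_mm * 100 / sid_cm`
#' (source-axis distance 100 cm). Linear and sign-preserving.
#'
#' @param pixels pixel displacement(s) at the detector plane.
#' @param detector_pitch_mm detector pixel pitch, mm/pixel (> 0).
#' @param sid_cm source-to-imager distance, cm (> 0).
#' @return Displacement(s) in mm at the isocenter plane.
#' @export
#' @examples
#' pixels_to_isocenter_mm(10, detector_pitch_mm = 0.336, sid_cm = 160) # 2.1
pixels_to_isocenter_mm <- function(pixels, detector_pitch_mm, sid_cm) {
  .check_scalar(detector_pitch_mm, "detector_pitch_mm",
                min = .Machine$double.eps)
  .check_scalar(sid_cm, "sid_cm", min = .Machine$double.eps)
  if (!is.numeric(pixels)) stop_invalid("pixels", "must be numeric")
  pixels * detector_pitch_mm * 100 / sid_cm
}

#' Extract a positional-error trace from a cine frame stack
#'
#' Applies [detect_edge()] to every frame of the stack, converts detected
#' positions to mm at the isocenter plane, subtracts the DRR reference
#' position and applies the sign convention: displacement toward deeper
#' inspiration is positive. Frames where no edge survives are flagged
#' `"no-edge"`, excluded from `error_mm`, and counted in the attached report;
#' if more than `warn_no_edge_frac` of frames fail, the report carries a
#' stack-level warning flag (and a `warning()` is raised).
#'
#' @param stack a [frame_stack()].
#' @param params an [edge_params()] list.
#' @param deep_direction `+1` if increasing measurement coordinate means
#'   deeper inspiration (default), `-1` otherwise.
#' @param warn_no_edge_frac stack-level warning threshold (default 0.5).
#' @return An object of class `"edge_trace"`: a data frame with columns
#'   `frame`, `time_s`, `detected_position_px`, `detected_position_mm`,
#'   `error_mm`, `quality_flag`, with the quality report in
#'   `attr(, "report")` and provenance/geometry attributes.
#' @export
extract_trace <- function(stack, params = edge_params(), deep_direction = 1,
                          warn_no_edge_frac = 0.5) {
  if (!inherits(stack, "frame_stack"))
    stop_invalid("stack", "must be a frame_stack object")
  if (!deep_direction %in% c(-1, 1))
    stop_invalid("deep_direction", "must be +1 or -1")
  .check_scalar(warn_no_edge_frac, "warn_no_edge_frac", min = 0, max = 1)

  iso <- isocenter_pixel_mm(stack)
  nc <- ncol(stack$frames[[1]])
  center <- (nc - 1) / 2
  ref_px <- center + stack$reference_position_mm / iso

  n <- length(stack$frames)
  pos_px <- rep(NA_real_, n)
  flag <- character(n)
  prev <- NA_real_
  for (k in seq_len(n)) {
    det <- detect_edge(stack$frames[[k]], stack$roi, params,
                       angle_deg = stack$field_long_axis_deg,
                       prev_position_px = prev, reference_px = ref_px)
    pos_px[k] <- det$position_px
    flag[k] <- det$quality_flag
    if (is.finite(det$position_px)) prev <- det$position_px
  }

  pos_mm <- (pos_px - center) * iso
  err_mm <- deep_direction * (pos_mm - stack$reference_position_mm)

  out <- data.frame(
    frame = seq_len(n),
    time_s = if (is.null(stack$timestamps)) NA_real_ else stack$timestamps,
    detected_position_px = pos_px,
    detected_position_mm = pos_mm,
    error_mm = err_mm,
    quality_flag = flag,
    stringsAsFactors = FALSE
  )

  n_no_edge <- sum(flag == "no-edge")
  report <- list(
    n_frames = n,
    n_detected = sum(is.finite(pos_px)),
    n_no_edge = n_no_edge,
    n_multi_edge = sum(flag == "multi-edge-resolved"),
    frac_no_edge = n_no_edge / n,
    warning = n_no_edge / n > warn_no_edge_frac,
    units = list(position = "mm at isocenter plane",
                 detected_position_px = "detector pixels (0-based)")
  )
  if (report$warning)
    warning(sprintf("edge not detected in %.0f%% of frames (threshold %.0f%%)",
                    100 * report$frac_no_edge, 100 * warn_no_edge_frac))

  structure(out,
            class = c("edge_trace", "data.frame"),
            report = report,
            patient_id = stack$patient_id,
            fraction = stack$fraction,
            field = stack$field,
            geometry = list(sid_cm = stack$sid_cm,
                            detector_pitch_mm = stack$detector_pitch_mm,
                            isocenter_pixel_mm = iso,
                            reference_position_mm = stack$reference_position_mm,
                            deep_direction = deep_direction))
}

#' @export
print.edge_trace <- function(x, ...) {
  rep <- attr(x, "report")
  cat(sprintf("Edge trace: %d frames, %d detected, %d no-edge, %d multi-edge\n",
              rep$n_frames, rep$n_detected, rep$n_no_edge, rep$n_multi_edge))
  ok <- is.finite(x$error_mm)
  if (any(ok))
    cat(sprintf("  error_mm: mean %.3f, sd %.3f, range [%.3f, %.3f]\n",
                mean(x$error_mm[ok]), sd(x$error_mm[ok]),
                min(x$error_mm[ok]), max(x$error_mm[ok])))
  if (isTRUE(rep$warning)) cat("  WARNING: no-edge fraction above threshold\n")
  invisible(x)
}

#' Quality report of an edge trace
#'
#' @param trace an `"edge_trace"`.
#' @return The per-stack quality report list (frame counts by flag).
#' @export
trace_report <- function(trace) {
  if (!inherits(trace, "edge_trace"))
    stop_invalid("trace", "must be an edge_trace object")
  attr(trace, "report")
}

# --- tidy CSV trace schema (shared with the synthetic generator) ------------

.trace_schema <- c("patient_id", "fraction", "field", "frame", "time_s",
                   "error_mm")

#' Convert an edge trace to the tidy error-trace schema
#'
#' Drops no-edge frames and attaches the stack's provenance labels, producing
#' the shared CSV schema `patient_id, fraction, field, frame, time_s,
#' error_mm`.
#'
#' @param trace an `"edge_trace"`.
#' @return A plain data frame in the tidy trace schema.
#' @export
trace_to_errors <- function(trace) {
  if (!inherits(trace, "edge_trace"))
    stop_invalid("trace", "must be an edge_trace object")
  ok <- is.finite(trace$error_mm)
  data.frame(
    patient_id = as.character(attr(trace, "patient_id")),
    fraction = as.integer(attr(trace, "fraction")),
    field = as.character(attr(trace, "field")),
    frame = trace$frame[ok],
    time_s = trace$time_s[ok],
    error_mm = trace$error_mm[ok],
    stringsAsFactors = FALSE
  )
}

#' Write / read error traces as tidy CSV
#'
#' The schema is `patient_id, fraction, field, frame, time_s, error_mm`
#' (units in the column names: seconds, millimetres). `read_error_csv()`
#' enforces the schema and fails on unknown or missing columns.
#'
#' @param errors a data frame in the tidy trace schema.
#' @param path CSV file path.
#' @return `path` invisibly for the writer; the validated data frame for the
#'   reader.
#' @export
write_error_csv <- function(errors, path) {
  missing_cols <- setdiff(.trace_schema, names(errors))
  if (length(missing_cols))
    stop_invalid("errors", paste("missing columns:",
                                 paste(missing_cols, collapse = ", ")))
  write.csv(errors[, .trace_schema], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_error_csv
#' @export
read_error_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("trace file not found: %s", path))
  d <- read.csv(path, stringsAsFactors = FALSE)
  extra <- setdiff(names(d), .trace_schema)
  missing_cols <- setdiff(.trace_schema, names(d))
  if (length(extra) || length(missing_cols))
    stop_invalid("path", sprintf(
      "trace CSV schema mismatch%s%s",
      if (length(missing_cols)) paste0("; missing: ",
                                       paste(missing_cols, collapse = ", "))
      else "",
      if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", "))
      else ""))
  if (!is.numeric(d$error_mm) || any(!is.finite(d$error_mm)))
    stop_invalid("path", "error_mm must be finite numeric")
  d
}
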