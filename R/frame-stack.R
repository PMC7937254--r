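# FrameStack: an ordered set of 2-D grayscale cine portal frames for one field
# of one fraction, together with the beam geometry needed to map detector
# pixels to millimetres at the isocenter plane.
#
# Conventions (also recorded in the on-disk sidecar):
#   * pixel indices are 0-based, positions are reported at pixel centers;
#   * positions along the measurement axis (perpendicular to the field's
#     long axis) are in detector pixels, with 0 at the first column and
#     (ncol-1)/2 on the central beam axis;
#   * one detector pixel projects to detector_pitch_mm * 100 / sid_cm mm
#     at the isocenter plane.

#' Construct a cine portal frame stack
#'
#' Bundles an ordered list of grayscale frames with acquisition geometry:
#' source-to-imager distance (SID), detector pixel pitch, the analysis region
#' of interest (ROI) at isocenter level, the reference chest-wall position
#' derived from the planning DRR (which defines zero error), and the field's
#' long-axis orientation.
#'
#' @param frames list of numeric matrices, all of identical dimensions.
#' @param sid_cm source-to-imager distance in cm (> 0); 150 or 160 typical.
#' @param detector_pitch_mm detector pixel pitch in mm/pixel (> 0).
#' @param roi integer vector `c(row_min, row_max, col_min, col_max)`,
#'   0-based inclusive pixel indices, inside the frame.
#' @param reference_position_mm chest-wall position from the DRR in mm at the
#'   isocenter plane (along the measurement axis); defines zero error.
#' @param field_long_axis_deg orientation of the field's long axis, degrees
#'   from the detector column axis. The error is measured perpendicular to it.
#' @param timestamps optional per-frame acquisition times, seconds.
#' @param patient_id,fraction,field optional provenance labels.
#' @return An object of class `"frame_stack"`.
#' @export
frame_stack <- function(frames, sid_cm, detector_pitch_mm, roi,
                        reference_position_mm,
                        field_long_axis_deg = 0, timestamps = NULL,
                        patient_id = NA_character_, fraction = NA_integer_,
                        field = NA_character_) {
  if (!is.list(frames) || length(frames) == 0L)
    stop_invalid("frames", "must be a non-empty list of matrices")
  dims <- dim(frames[[1]])
  if (is.null(dims) || any(dims < 2L))
    stop_invalid("frames", "each frame must be a matrix of at least 2x2 pixels")
  same <- vapply(frames, function(f) is.matrix(f) && identical(dim(f), dims),
                 logical(1))
  if (!all(same))
    stop_invalid("frames", "all frames must share one shape")
  .check_scalar(sid_cm, "sid_cm", min = .Machine$double.eps)
  .check_scalar(detector_pitch_mm, "detector_pitch_mm",
                min = .Machine$double.eps)
  roi <- .check_roi(roi, dims)
  .check_scalar(reference_position_mm, "reference_position_mm")
  .check_scalar(field_long_axis_deg, "field_long_axis_deg")
  if (!is.null(timestamps)) {
    if (!is.numeric(timestamps) || length(timestamps) != length(frames))
      stop_invalid("timestamps", "must have one time per frame")
  }

  structure(list(
    frames = frames,
    sid_cm = sid_cm,
    detector_pitch_mm = detector_pitch_mm,
    roi = roi,
    reference_position_mm = reference_position_mm,
    field_long_axis_deg = field_long_axis_deg,
    timestamps = timestamps,
    patient_id = patient_id,
    fraction = fraction,
    field = field
  ), class = "frame_stack")
}

.check_roi <- function(roi, dims) {
  if (!is.numeric(roi) || length(roi) != 4L || any(!is.finite(roi)) ||
      any(roi != round(roi)))
    stop_invalid("roi", "must be 4 integers c(row_min, row_max, col_min, col_max)")
  roi <- as.integer(roi)
  if (roi[1] > roi[2] || roi[3] > roi[4])
    stop_invalid("roi", "must be non-degenerate (min <= max on both axes)")
  if (roi[1] < 0L || roi[3] < 0L || roi[2] >= dims[1] || roi[4] >= dims[2])
    stop_invalid("roi", sprintf("must lie inside the %dx%d frame (0-based)",
                                dims[1], dims[2]))
  roi
}

#' Pixel size at the isocenter plane
#'
#' Divergent-beam scaling of the detector pitch back to the isocenter plane:
#' `detector_pitch_mm * 100 / sid_cm` (the source-axis distance is 100 cm).
#'
#' @param stack a [frame_stack()].
#' @return mm per detector pixel at isocenter.
#' @export
isocenter_pixel_mm <- function(stack) {
  stack$detector_pitch_mm * 100 / stack$sid_cm
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Cine portal frame stack: %d frames of %dx%d px\n",
              length(x$frames), d[1], d[2]))
  cat(sprintf("  SID %.0f cm, pitch %.4g mm/px (%.4g mm/px at isocenter)\n",
              x$sid_cm, x$detector_pitch_mm, isocenter_pixel_mm(x)))
  cat(sprintf("  ROI rows %d..%d, cols %d..%d (0-based); reference %.3g mm; long axis %.1f deg\n",
              x$roi[1], x$roi[2], x$roi[3], x$roi[4],
              x$reference_position_mm, x$field_long_axis_deg))
  if (!is.na(x$patient_id))
    cat(sprintf("  provenance: %s fraction %s field %s\n",
                x$patient_id, x$fraction, x$field))
  invisible(x)
}
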