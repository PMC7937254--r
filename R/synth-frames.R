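# Synthetic portal-image-like frames: one dominant oriented step edge (the
# soft-tissue/lung interface at the chest wall) with Gaussian blur and
# additive detector noise, rendered at a known position so the edge tracker
# has ground truth.

#' Specify a synthetic portal-image render
#'
#' Geometry and appearance of synthetic cine portal frames containing a single
#' oriented step edge. Defaults mirror an amorphous-silicon portal imager:
#' 1280 x 1280 pixels over a 43 x 43 cm detector (pitch 0.336 mm/px) at
#' SID 160 cm. Tests and examples use smaller frames with `detector_size_cm`
#' scaled in proportion so the pitch is unchanged.
#'
#' The edge position is given along the measurement axis (perpendicular to
#' the field long axis), in mm at the isocenter plane, with 0 on the central
#' beam axis. The blurred step is rendered analytically as
#' `base_level + contrast * pnorm(d / max(blur_sigma, 0.35))` where `d` is the
#' signed perpendicular distance (px) from the edge line; detector noise is
#' additive white Gaussian.
#'
#' @param frame_shape c(rows, cols) in pixels.
#' @param detector_size_cm active detector side length, cm (square detector);
#'   pixel pitch is `detector_size_cm * 10 / frame_shape[2]` mm.
#' @param sid_cm source-to-imager distance, cm.
#' @param edge_position_mm true chest-wall position at the isocenter plane, mm.
#' @param edge_angle_deg edge (field long-axis) orientation, degrees from the
#'   column axis; 0 renders a vertical edge.
#' @param contrast intensity step across the edge (16-bit counts).
#' @param noise_sd additive Gaussian detector noise SD (counts).
#' @param blur_sigma Gaussian blur of the step, pixels.
#' @param base_level intensity on the low side of the edge (counts).
#' @param roi analysis ROI, 0-based `c(row_min, row_max, col_min, col_max)`;
#'   default is an 81-row band centred at isocenter level spanning most
#'   columns.
#' @return An object of class `"synthetic_image_spec"`.
#' @export
synthetic_image_spec <- function(frame_shape = c(1280, 1280),
                                 detector_size_cm = 43, sid_cm = 160,
                                 edge_position_mm = 0, edge_angle_deg = 0,
                                 contrast = 8000, noise_sd = 400,
                                 blur_sigma = 1.5, base_level = 22000,
                                 roi = NULL) {
  if (!is.numeric(frame_shape) || length(frame_shape) != 2L ||
      any(!is.finite(frame_shape)) || any(frame_shape < 8) ||
      any(frame_shape != round(frame_shape)))
    stop_invalid("frame_shape", "must be c(rows, cols), both >= 8")
  frame_shape <- as.integer(frame_shape)
  .check_scalar(detector_size_cm, "detector_size_cm",
                min = .Machine$double.eps)
  .check_scalar(sid_cm, "sid_cm", min = .Machine$double.eps)
  .check_scalar(edge_position_mm, "edge_position_mm")
  .check_scalar(edge_angle_deg, "edge_angle_deg", min = -45, max = 45)
  .check_scalar(contrast, "contrast")
  .check_scalar(noise_sd, "noise_sd", min = 0)
  .check_scalar(blur_sigma, "blur_sigma", min = 0)
  .check_scalar(base_level, "base_level", min = 0)

  if (is.null(roi)) {
    rc <- (frame_shape[1] - 1) / 2
    half <- min(40L, frame_shape[1] %/% 3L)
    cm <- min(16L, frame_shape[2] %/% 8L)
    roi <- c(floor(rc) - half, floor(rc) + half, cm, frame_shape[2] - 1L - cm)
  }
  roi <- .check_roi(roi, frame_shape)

  structure(list(
    frame_shape = frame_shape,
    detector_size_cm = detector_size_cm,
    sid_cm = sid_cm,
    edge_position_mm = edge_position_mm,
    edge_angle_deg = edge_angle_deg,
    contrast = contrast, noise_sd = noise_sd, blur_sigma = blur_sigma,
    base_level = base_level,
    roi = roi,
    detector_pitch_mm = detector_size_cm * 10 / frame_shape[2]
  ), class = "synthetic_image_spec")
}

#' Render a synthetic cine frame stack
#'
#' Renders one frame per entry of `per_frame_offsets_mm`, placing the edge at
#' `edge_position_mm + offset` (mm at isocenter, along the measurement axis).
#' The returned [frame_stack()] carries the geometry metadata and uses
#' `spec$edge_position_mm` as the DRR reference position, so a downstream
#' [extract_trace()] should recover the offsets as signed errors.
#'
#' @param spec a [synthetic_image_spec()].
#' @param per_frame_offsets_mm numeric vector of per-frame displacements, mm.
#' @param seed optional integer seed for the detector noise.
#' @param frame_rate_hz frame rate used for the timestamps.
#' @param patient_id,fraction,field provenance labels passed to the stack.
#' @return A [frame_stack()].
#' @export
render_frames <- function(spec, per_frame_offsets_mm, seed = NULL,
                          frame_rate_hz = 9.5,
                          patient_id = NA_character_, fraction = NA_integer_,
                          field = NA_character_) {
  if (!inherits(spec, "synthetic_image_spec"))
    stop_invalid("spec", "must be a synthetic_image_spec object")
  if (!is.numeric(per_frame_offsets_mm) || length(per_frame_offsets_mm) == 0L ||
      any(!is.finite(per_frame_offsets_mm)))
    stop_invalid("per_frame_offsets_mm", "must be a non-empty finite vector")
  if (!is.null(seed)) set.seed(as.integer(seed))

  nr <- spec$frame_shape[1]; nc <- spec$frame_shape[2]
  iso <- spec$detector_pitch_mm * 100 / spec$sid_cm
  theta <- spec$edge_angle_deg * pi / 180
  soft <- max(spec$blur_sigma, 0.35)     # keep the step sub-pixel resolvable

  rows0 <- seq_len(nr) - 1    # 0-based pixel-center coordinates
  cols0 <- seq_len(nc) - 1
  rc <- (nr - 1) / 2; cc <- (nc - 1) / 2

  frames <- lapply(per_frame_offsets_mm, function(off) {
    perp_px <- (spec$edge_position_mm + off) / iso   # perpendicular offset
    # edge line: points with perpendicular coordinate perp_px relative to the
    # detector center; center column of the edge is perp_px / cos(theta)
    c_edge <- cc + perp_px / cos(theta) + (rows0 - rc) * tan(theta)
    d_perp <- outer(-c_edge, cols0, `+`) * cos(theta)   # [row, col]
    img <- spec$base_level + spec$contrast * pnorm(d_perp / soft)
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    img
  })

  frame_stack(
    frames = frames,
    sid_cm = spec$sid_cm,
    detector_pitch_mm = spec$detector_pitch_mm,
    roi = spec$roi,
    reference_position_mm = spec$edge_position_mm,
    field_long_axis_deg = spec$edge_angle_deg,
    timestamps = (seq_along(per_frame_offsets_mm) - 1) / frame_rate_hz,
    patient_id = patient_id, fraction = fraction, field = field
  )
}
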