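# Edge detection, pixel-to-mm geometry, trace extraction, TIFF round trips

test_that("pixel-to-isocenter conversion follows divergent-beam geometry", {
  expect_equal(pixels_to_isocenter_mm(0, 0.336, 160), 0)
  expect_equal(pixels_to_isocenter_mm(10, 0.336, 160), 2.10)
  # linearity and sign preservation
  a <- pixels_to_isocenter_mm(3.2, 0.336, 150)
  b <- pixels_to_isocenter_mm(-1.7, 0.336, 150)
  expect_equal(pixels_to_isocenter_mm(3.2 - 1.7, 0.336, 150), a + b)
  expect_error(pixels_to_isocenter_mm(1, 0.336, 0), "sid_cm",
               class = "dibh_validation_error")
})

test_that("a noiseless vertical step is localized to a quarter pixel", {
  spec0 <- small_step_spec(noise_sd = 0, blur_sigma = 0)
  iso <- spec0$detector_pitch_mm * 100 / spec0$sid_cm
  for (target_col in c(100, 80.5, 45.25)) {
    spec <- small_step_spec(noise_sd = 0, blur_sigma = 0,
                            edge_position_mm = (target_col - 79.5) * iso)
    stk <- render_frames(spec, 0)
    det <- detect_edge(stk$frames[[1]], stk$roi)
    expect_equal(det$quality_flag, "detected")
    expect_lt(abs(det$position_px - target_col), 0.25)
  }
})

test_that("detector agrees with the 1-D smoothed-gradient-profile oracle", {
  spec <- small_step_spec(edge_position_mm = 1.3, noise_sd = 400,
                          blur_sigma = 1.5)
  stk <- render_frames(spec, c(0, -1.1, 0.8), seed = 21)
  for (k in seq_along(stk$frames)) {
    det <- detect_edge(stk$frames[[k]], stk$roi)
    oracle <- gradient_profile_peak(stk$frames[[k]], stk$roi, sigma = 1.5)
    expect_lt(abs(det$position_px - oracle), 0.5)
  }
})

test_that("degenerate frames are flagged no-edge, not errors", {
  expect_equal(detect_edge(matrix(500, 64, 64),
                           c(10, 50, 10, 50))$quality_flag, "no-edge")
  # pure noise, no structure: hysteresis may keep specks but the flat frame
  # case must never throw
  expect_error(detect_edge(matrix(1, 1, 5), c(0, 0, 0, 4)), "frame",
               class = "dibh_validation_error")
})

test_that("render/extract round-trip recovers offsets within sub-pixel RMSE", {
  offs <- c(-2, -0.5, 0, 0.35, 0.7, 2.0)
  for (noise in c(0, 400)) {
    spec <- small_step_spec(edge_position_mm = 0.8, noise_sd = noise)
    stk <- render_frames(spec, offs, seed = 31)
    tr <- extract_trace(stk)
    expect_true(all(tr$quality_flag != "no-edge"))
    iso <- isocenter_pixel_mm(stk)
    rmse <- sqrt(mean((tr$error_mm - offs)^2))
    expect_lt(rmse, iso)        # < 1 isocenter pixel
  }
})

test_that("angled fields are measured perpendicular to the long axis", {
  offs <- c(-1.5, 0, 1.2)
  spec <- small_step_spec(frame_shape = c(128, 160), edge_position_mm = 0.5,
                          edge_angle_deg = 10)
  stk <- render_frames(spec, offs, seed = 7)
  tr <- extract_trace(stk)
  expect_lt(sqrt(mean((tr$error_mm - offs)^2)), isocenter_pixel_mm(stk))
})

test_that("a +2 mm offset at SID 160 shifts the edge ~9.5 detector pixels", {
  spec <- small_step_spec(noise_sd = 0)
  stk <- render_frames(spec, c(0, 2.0))
  p <- vapply(stk$frames, function(f) detect_edge(f, stk$roi)$position_px,
              numeric(1))
  expect_equal(p[2] - p[1], 2.0 / (0.336 * 100 / 160), tolerance = 0.02)
  # and the same number through the geometry op
  expect_equal(pixels_to_isocenter_mm(p[2] - p[1],
                                      stk$detector_pitch_mm, stk$sid_cm),
               2.0, tolerance = 0.01)
})

test_that("shifting the reference shifts every error by exactly that amount", {
  spec <- small_step_spec(edge_position_mm = 0.4)
  stk <- render_frames(spec, c(-0.6, 0, 0.9), seed = 13)
  tr1 <- extract_trace(stk)
  stk2 <- stk
  stk2$reference_position_mm <- stk$reference_position_mm + 1
  tr2 <- extract_trace(stk2)
  expect_equal(tr2$error_mm, tr1$error_mm - 1, tolerance = 1e-12)
  # sign convention flips with deep_direction
  tr3 <- extract_trace(stk, deep_direction = -1)
  expect_equal(tr3$error_mm, -tr1$error_mm, tolerance = 1e-12)
})

test_that("extraction is deterministic and reports no-edge frames", {
  spec <- small_step_spec(edge_position_mm = 0)
  stk <- render_frames(spec, c(0, 0.5), seed = 3)
  stk$frames[[3]] <- matrix(1000, nrow(stk$frames[[1]]),
                            ncol(stk$frames[[1]]))
  stk$timestamps <- c(stk$timestamps, 2)
  tr1 <- extract_trace(stk)
  tr2 <- extract_trace(stk)
  expect_identical(tr1$detected_position_px, tr2$detected_position_px)
  rep <- trace_report(tr1)
  expect_equal(rep$n_no_edge, 1)
  expect_true(is.na(tr1$error_mm[3]))
  expect_false(rep$warning)
  # above the threshold the stack-level warning fires
  stk$frames[[2]] <- stk$frames[[3]]
  expect_warning(extract_trace(stk), "edge not detected")
})

test_that("16-bit multi-page TIFF and sidecar round-trip losslessly", {
  set.seed(5)
  frames <- list(matrix(sample(0:65535, 18 * 25), 18, 25),
                 matrix(sample(0:65535, 18 * 25), 18, 25),
                 matrix(sample(0:65535, 18 * 25), 18, 25))
  stk <- frame_stack(frames, sid_cm = 150, detector_pitch_mm = 0.336,
                     roi = c(2, 15, 3, 20), reference_position_mm = 1.25,
                     field_long_axis_deg = 5, timestamps = c(0, 0.2, 0.4),
                     patient_id = "P07", fraction = 3L, field = "medial")
  prefix <- tempfile()
  write_frame_stack(stk, prefix)
  back <- read_frame_stack(prefix)
  expect_equal(back$frames, frames)
  expect_equal(back$sid_cm, 150)
  expect_equal(back$detector_pitch_mm, 0.336)
  expect_equal(back$roi, stk$roi)
  expect_equal(back$reference_position_mm, 1.25)
  expect_equal(back$field_long_axis_deg, 5)
  expect_equal(back$timestamps, stk$timestamps)
  expect_equal(back$patient_id, "P07")

  file.remove(paste0(prefix, ".json"))
  expect_error(read_frame_stack(prefix), "sidecar",
               class = "dibh_io_error")
})

test_that("frame stacks validate geometry and ROI placement", {
  f <- list(matrix(0, 10, 10))
  expect_error(frame_stack(f, sid_cm = -1, detector_pitch_mm = 0.3,
                           roi = c(1, 5, 1, 5), reference_position_mm = 0),
               "sid_cm", class = "dibh_validation_error")
  expect_error(frame_stack(f, sid_cm = 160, detector_pitch_mm = 0.3,
                           roi = c(1, 12, 1, 5), reference_position_mm = 0),
               "roi", class = "dibh_validation_error")
  expect_error(render_frames(synthetic_image_spec(), c(1, NA)),
               "per_frame_offsets_mm", class = "dibh_validation_error")
  expect_error(synthetic_image_spec(frame_shape = c(0, 10)), "frame_shape",
               class = "dibh_validation_error")
  stk <- frame_stack(f, sid_cm = 160, detector_pitch_mm = 0.336,
                     roi = c(1, 5, 1, 5), reference_position_mm = 0)
  expect_equal(isocenter_pixel_mm(stk), 0.336 * 100 / 160)
})
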