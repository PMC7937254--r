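# Independent oracles used to validate the package's estimators. These are
# deliberately naive re-implementations (loops over means, 1-D profiles,
# closed forms) kept free of any code path they are used to check.

# Expected-mean-squares ANOVA solver for a BALANCED two-level nested design:
# a patients x b fractions x k observations. Solves the EMS equations
#   E[MSW] = ve;  E[MSB] = ve + k vb;  E[MSA] = ve + k vb + b k va
# directly from the sums of squares.
ems_nested_anova <- function(y, patient, fraction) {
  patient <- as.character(patient)
  fraction <- as.character(fraction)
  pats <- unique(patient)
  a <- length(pats)
  cell <- paste(patient, fraction)
  counts <- table(cell)
  k <- unname(counts[1])
  stopifnot(all(counts == k))
  b <- length(unique(cell)) / a
  stopifnot(b == round(b), all(table(patient) == b * k))

  grand <- mean(y)
  ssa <- 0; ssb <- 0; ssw <- 0
  for (p in pats) {
    yp <- y[patient == p]
    ssa <- ssa + b * k * (mean(yp) - grand)^2
    for (f in unique(fraction[patient == p])) {
      ypf <- y[patient == p & fraction == f]
      ssb <- ssb + k * (mean(ypf) - mean(yp))^2
      ssw <- ssw + sum((ypf - mean(ypf))^2)
    }
  }
  msa <- ssa / (a - 1)
  msb <- ssb / (a * (b - 1))
  msw <- ssw / (a * b * (k - 1))
  list(va = (msa - msb) / (b * k), vb = (msb - msw) / k, ve = msw,
       mean = grand,
       interior = (msa - msb) / (b * k) > 0 & (msb - msw) / k > 0 & msw > 0)
}

# Delta-method standard errors of the SD estimates for a balanced
# P x F x K design at the true components (large-sample closed forms).
recovery_se <- function(sigma_pt, sigma_fr, sigma_intra, P, F, K) {
  va <- sigma_pt^2; vb <- sigma_fr^2; ve <- sigma_intra^2
  sd_va <- (va + vb / F + ve / (F * K)) * sqrt(2 / (P - 1))
  sd_vb <- (vb + ve / K) * sqrt(2 / (P * (F - 1)))
  sd_ve <- ve * sqrt(2 / (P * F * (K - 1)))
  c(sigma_pt = sd_va / (2 * sigma_pt),
    sigma_fr = sd_vb / (2 * sigma_fr),
    sigma_intra = sd_ve / (2 * sigma_intra))
}

# 1-D gradient-profile oracle for edge localization, independent of the 2-D
# Canny path: average the ROI rows, smooth with a Gaussian, and take the
# argmax of |d profile / d column|. Returns the 0-based global column.
gradient_profile_peak <- function(frame, roi, sigma = 1.5) {
  sub <- frame[(roi[1] + 1):(roi[2] + 1), (roi[3] + 1):(roi[4] + 1),
               drop = FALSE]
  prof <- colMeans(sub)
  r <- max(1, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  n <- length(prof)
  sm <- vapply(seq_len(n), function(i) {
    idx <- pmin(pmax(i + (-r:r), 1), n)
    sum(k * prof[idx])
  }, numeric(1))
  g <- abs(diff(sm))
  peak_between <- which.max(g)          # gradient lives between columns
  roi[3] + peak_between - 0.5           # 0-based column of the step
}

# Small-frame render spec that preserves the clinical detector pitch
# (43 cm / 1280 px = 0.336 mm/px) so pixel-denominated checks transfer.
small_step_spec <- function(frame_shape = c(96, 160), sid_cm = 160,
                            edge_position_mm = 0, ...) {
  synthetic_image_spec(
    frame_shape = frame_shape,
    detector_size_cm = 43 * frame_shape[2] / 1280,
    sid_cm = sid_cm, edge_position_mm = edge_position_mm, ...)
}

# Simulate + fit shorthand used across tests
fit_sim <- function(spec, ...) {
  varcomp(error_mm ~ patient_id/fraction, simulate_errors(spec), ...)
}
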