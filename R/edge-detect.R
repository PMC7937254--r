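# Chest-wall edge detection in one cine portal frame.
#
# Canny-style pipeline restricted to the ROI: Gaussian smoothing -> gradient
# magnitude/direction -> non-maximum suppression -> hysteresis thresholding.
# Surviving edge pixels are grouped into candidate edges by their coordinate
# along the measurement axis (perpendicular to the field long axis); the
# candidate with the largest integrated gradient magnitude wins, with ties
# broken toward the previous frame's position, else toward the reference.
# Sub-pixel refinement: parabolic fit to the row-averaged gradient-magnitude
# profile around the winning column.

#' Edge-detection parameters
#'
#' @param sigma Gaussian smoothing SD in pixels (default 1.5).
#' @param low_frac,high_frac hysteresis thresholds as fractions of the maximum
#'   gradient magnitude inside the ROI (defaults 0.2 and 0.5).
#' @param max_gap columns further apart than this are split into separate
#'   candidate edges (default 3 px).
#' @param tie_frac candidates whose integrated magnitude is within this
#'   relative fraction of the best are treated as ties (default 0.05).
#' @return A list of class `"edge_params"`.
#' @export
edge_params <- function(sigma = 1.5, low_frac = 0.2, high_frac = 0.5,
                        max_gap = 3, tie_frac = 0.05) {
  .check_scalar(sigma, "sigma", min = 0.3)
  .check_scalar(low_frac, "low_frac", min = 0, max = 1)
  .check_scalar(high_frac, "high_frac", min = 0, max = 1)
  if (low_frac > high_frac)
    stop_invalid("low_frac", "must not exceed high_frac")
  .check_scalar(max_gap, "max_gap", min = 1)
  .check_scalar(tie_frac, "tie_frac", min = 0, max = 1)
  structure(list(sigma = sigma, low_frac = low_frac, high_frac = high_frac,
                 max_gap = max_gap, tie_frac = tie_frac),
            class = "edge_params")
}

# separable Gaussian convolution with replicate padding
.gauss_smooth <- function(A, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  nr <- nrow(A); nc <- ncol(A)
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) {     # rows
    o <- i - r - 1L
    out <- out + k[i] * A[pmin(pmax(seq_len(nr) + o, 1L), nr), , drop = FALSE]
  }
  A2 <- matrix(0, nr, nc)
  for (i in seq_along(k)) {     # cols
    o <- i - r - 1L
    A2 <- A2 + k[i] * out[, pmin(pmax(seq_len(nc) + o, 1L), nc), drop = FALSE]
  }
  A2
}

# central-difference gradients with replicate edges
.gradients <- function(A) {
  nr <- nrow(A); nc <- ncol(A)
  cl <- pmax(seq_len(nc) - 1L, 1L); cr <- pmin(seq_len(nc) + 1L, nc)
  ru <- pmax(seq_len(nr) - 1L, 1L); rd <- pmin(seq_len(nr) + 1L, nr)
  gx <- (A[, cr, drop = FALSE] - A[, cl, drop = FALSE]) / 2   # along columns
  gy <- (A[rd, , drop = FALSE] - A[ru, , drop = FALSE]) / 2   # along rows
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

.shift_mat <- function(A, dr, dc, fill = -Inf) {
  nr <- nrow(A); nc <- ncol(A)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- A[rs[ok_r], cs[ok_c]]
  out
}

# non-maximum suppression with gradient direction quantized to 4 sectors
.nms <- function(mag, gx, gy) {
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  pairs <- list(`0` = list(c(0, 1), c(0, -1)),     # gradient along columns
                `1` = list(c(1, 1), c(-1, -1)),
                `2` = list(c(1, 0), c(-1, 0)),     # gradient along rows
                `3` = list(c(1, -1), c(-1, 1)))
  for (s in 0:3) {
    d <- pairs[[as.character(s)]]
    n1 <- .shift_mat(mag, d[[1]][1], d[[1]][2])
    n2 <- .shift_mat(mag, d[[2]][1], d[[2]][2])
    keep <- keep | (sector == s & mag >= n1 & mag >= n2)
  }
  out <- mag
  out[!keep] <- 0
  out
}

# hysteresis: keep weak pixels 8-connected to strong ones
.hysteresis <- function(nmsmag, low, high) {
  strong <- nmsmag >= high & nmsmag > 0
  weak <- nmsmag >= low & nmsmag > 0
  if (!any(strong)) return(strong)
  repeat {
    nb <- strong
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- nb | .shift_mat(strong, dr, dc, fill = FALSE)
    }
    grown <- nb & weak
    if (identical(grown, strong)) break
    strong <- grown
  }
  strong
}

# bilinear sampling of `frame` rotated by theta about the ROI center, so that
# the measurement axis becomes the column axis of the output
.rectify_roi <- function(frame, roi, theta) {
  nr_out <- roi[2] - roi[1] + 1L
  nc_out <- roi[4] - roi[3] + 1L
  crow <- (roi[1] + roi[2]) / 2    # 0-based ROI center
  ccol <- (roi[3] + roi[4]) / 2
  ci <- (nr_out - 1) / 2; cj <- (nc_out - 1) / 2
  i <- matrix(seq_len(nr_out) - 1, nr_out, nc_out) - ci
  j <- matrix(seq_len(nc_out) - 1, nr_out, nc_out, byrow = TRUE) - cj
  src_r <- crow + i * cos(theta) - j * sin(theta)
  src_c <- ccol + i * sin(theta) + j * cos(theta)
  nr <- nrow(frame); nc <- ncol(frame)
  src_r <- pmin(pmax(src_r, 0), nr - 1)
  src_c <- pmin(pmax(src_c, 0), nc - 1)
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  idx <- function(r, c) frame[cbind(as.vector(r) + 1, as.vector(c) + 1)]
  v <- (1 - fr) * (1 - fc) * idx(r0, c0) + (1 - fr) * fc * idx(r0, c1) +
    fr * (1 - fc) * idx(r1, c0) + fr * fc * idx(r1, c1)
  matrix(v, nr_out, nc_out)
}

#' Detect the chest-wall edge in one frame
#'
#' Runs the Canny-style detector inside the ROI and returns the edge position
#' in detector pixels (0-based, at pixel centers) along the measurement axis,
#' i.e. perpendicular to the field's long axis. When `angle_deg != 0` the ROI
#' is resampled along that direction rather than rotating the whole frame.
#'
#' @param frame numeric matrix (one grayscale cine frame).
#' @param roi 0-based `c(row_min, row_max, col_min, col_max)` inside the frame.
#' @param params an [edge_params()] list.
#' @param angle_deg field long-axis orientation, degrees from the column axis.
#' @param prev_position_px,reference_px optional positions (same coordinate
#'   system as the result) used to break ties between candidate edges.
#' @return A list with `position_px` (`NA` if no edge), `quality_flag`
#'   (`"detected"`, `"no-edge"` or `"multi-edge-resolved"`) and
#'   `n_candidates`.
#' @export
detect_edge <- function(frame, roi, params = edge_params(), angle_deg = 0,
                        prev_position_px = NA_real_,
                        reference_px = NA_real_) {
  if (!is.matrix(frame) || any(dim(frame) < 2L))
    stop_invalid("frame", "must be a numeric matrix of at least 2x2 pixels")
  roi <- .check_roi(roi, dim(frame))
  if (!inherits(params, "edge_params")) params <- do.call(edge_params, params)
  theta <- angle_deg * pi / 180

  A <- if (angle_deg == 0) {
    frame[(roi[1] + 1):(roi[2] + 1), (roi[3] + 1):(roi[4] + 1), drop = FALSE]
  } else {
    .rectify_roi(frame, roi, theta)
  }

  no_edge <- list(position_px = NA_real_, quality_flag = "no-edge",
                  n_candidates = 0L)
  if (max(A) - min(A) < .Machine$double.eps * max(abs(A), 1)) return(no_edge)

  S <- .gauss_smooth(A, params$sigma)
  g <- .gradients(S)
  mmax <- max(g$mag)
  if (mmax <= 0) return(no_edge)
  nmsmag <- .nms(g$mag, g$gx, g$gy)
  edges <- .hysteresis(nmsmag, params$low_frac * mmax, params$high_frac * mmax)
  if (!any(edges)) return(no_edge)

  # integrated gradient magnitude per column of the (rectified) ROI
  w <- colSums(g$mag * edges)
  present <- which(w > 0)
  gaps <- which(diff(present) > params$max_gap)
  starts <- c(1L, gaps + 1L)
  ends <- c(gaps, length(present))
  clusters <- lapply(seq_along(starts),
                     function(k) present[starts[k]:ends[k]])
  wsum <- vapply(clusters, function(cl) sum(w[cl]), numeric(1))

  best <- max(wsum)
  tied <- which(wsum >= best * (1 - params$tie_frac))
  # map local 0-based column -> global measurement coordinate
  nc_frame <- ncol(frame); nr_frame <- nrow(frame)
  roi_ccol <- (roi[3] + roi[4]) / 2; roi_crow <- (roi[1] + roi[2]) / 2
  p_center <- (roi_ccol - (nc_frame - 1) / 2) * cos(theta) -
    (roi_crow - (nr_frame - 1) / 2) * sin(theta)
  to_global <- function(local0)
    (nc_frame - 1) / 2 + p_center + (local0 - (ncol(A) - 1) / 2)

  if (length(tied) > 1L) {
    anchor <- if (is.finite(prev_position_px)) prev_position_px
              else if (is.finite(reference_px)) reference_px else NA_real_
    if (is.finite(anchor)) {
      centers <- vapply(tied, function(k) {
        cl <- clusters[[k]]; to_global(sum(cl * w[cl]) / sum(w[cl]) - 1)
      }, numeric(1))
      pick <- tied[which.min(abs(centers - anchor))]
    } else pick <- tied[which.max(wsum[tied])]
  } else pick <- tied
  cl <- clusters[[pick]]

  # sub-pixel: parabola on the row-averaged gradient magnitude profile
  prof <- colMeans(g$mag)
  peak <- cl[which.max(prof[cl])]
  pos_local <- peak - 1                      # 0-based local column
  if (peak > 1L && peak < ncol(A)) {
    p0 <- prof[peak - 1L]; p1 <- prof[peak]; p2 <- prof[peak + 1L]
    den <- p0 - 2 * p1 + p2
    if (den < 0) {
      delta <- 0.5 * (p0 - p2) / den
      if (abs(delta) <= 1) pos_local <- pos_local + delta
    }
  }

  list(position_px = to_global(pos_local),
       quality_flag = if (length(clusters) > 1L) "multi-edge-resolved"
                      else "detected",
       n_candidates = length(clusters))
}
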