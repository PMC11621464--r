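# local mean over a (2h+1)x(2h+1) box via an integral image (edge-clipped)
.local_mean <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  r1 <- pmax(seq_len(nr) - half, 1L); r2 <- pmin(seq_len(nr) + half, nr)
  c1 <- pmax(seq_len(nc) - half, 1L); c2 <- pmin(seq_len(nc) + half, nc)
  area <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  tot <- S[r2 + 1L, c2 + 1L] - S[r1, c2 + 1L] - S[r2 + 1L, c1] + S[r1, c1]
  tot / area
}

# adaptive (local-mean) binarization of dark foreground: window ~ 1/8 of the
# shorter side, offset scaled by (1 - sensitivity) times the intensity range
.adaptive_binarize <- function(m, sensitivity) {
  rng <- range(m)
  if (rng[2] - rng[1] <= .Machine$double.eps) {
    warning("constant-intensity frame: binarized to background")
    return(matrix(FALSE, nrow(m), ncol(m)))
  }
  half <- max(1L, floor(min(dim(m)) / 16))
  offset <- (1 - sensitivity) * 0.5 * (rng[2] - rng[1])
  m < .local_mean(m, half) - offset
}

#' Colony activity by adaptive-threshold frame differencing
#'
#' Each frame of the region of interest is binarized by local-mean adaptive
#' thresholding (dark ants on a light background), and activity at each frame
#' transition is the proportion of ROI pixels whose binary value changes.
#' This estimates the proportion of individuals that moved within the nest
#' between successive frames.
#'
#' @param stack an `image_stack` (see [simulate_image_stack()],
#'   [read_image_stack()]).
#' @param roi region of interest `c(x0, y0, x1, y1)` in 0-based, half-open
#'   pixel coordinates (x = column, y = row), or `NULL` for the full frame.
#' @param sensitivity adaptive-threshold sensitivity in (0, 1); larger values
#'   classify more pixels as foreground.
#' @param species,colony_id,series_id metadata for the returned series.
#' @return an [activity_series()] of length `n_frames - 1` with values in
#'   \[0, 1\] and `source = "pixel_change"`.
#' @export
pixel_change_activity <- function(stack, roi = NULL, sensitivity = 0.5,
                                  species = NA_character_,
                                  colony_id = NA_character_,
                                  series_id = "pixel_change") {
  stopifnot(inherits(stack, "image_stack"), length(stack$frames) >= 2)
  stopifnot(sensitivity > 0, sensitivity < 1)
  d <- dim(stack$frames[[1]])
  if (is.null(roi)) roi <- c(0L, 0L, d[2], d[1])
  if (roi[3] <= roi[1] || roi[4] <= roi[2])
    stop("empty ROI", call. = FALSE)
  if (roi[1] < 0 || roi[2] < 0 || roi[3] > d[2] || roi[4] > d[1])
    stop("ROI outside frame bounds", call. = FALSE)
  rows <- (roi[2] + 1L):roi[4]
  cols <- (roi[1] + 1L):roi[3]
  bin <- lapply(stack$frames, function(f)
    .adaptive_binarize(f[rows, cols, drop = FALSE], sensitivity))
  n_px <- length(rows) * length(cols)
  vals <- vapply(seq_len(length(bin) - 1L), function(t)
    sum(bin[[t]] != bin[[t + 1L]]) / n_px, numeric(1))
  activity_series(vals, sample_interval_s = stack$frame_interval_s,
                  level = "colony", species = species, colony_id = colony_id,
                  source = "pixel_change", series_id = series_id)
}

# one Horn-Schunck dense-flow estimate between two frames; returns mean
# flow-vector magnitude over the frame
.hs_flow_magnitude <- function(f1, f2, alpha = 1, n_iter = 100L) {
  nr <- nrow(f1); nc <- ncol(f1)
  shift <- function(m, dr, dc) {
    out <- m
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    rs <- pmin(pmax(rs, 1L), nr); cs <- pmin(pmax(cs, 1L), nc)
    m[rs, cs]
  }
  # spatial gradients averaged over the two frames, temporal difference
  Ix <- (shift(f1, 0, 1) - shift(f1, 0, -1) +
         shift(f2, 0, 1) - shift(f2, 0, -1)) / 4
  Iy <- (shift(f1, 1, 0) - shift(f1, -1, 0) +
         shift(f2, 1, 0) - shift(f2, -1, 0)) / 4
  It <- f2 - f1
  u <- matrix(0, nr, nc); v <- matrix(0, nr, nc)
  denom <- alpha^2 + Ix^2 + Iy^2
  avg <- function(m) (shift(m, 1, 0) + shift(m, -1, 0) +
                      shift(m, 0, 1) + shift(m, 0, -1)) / 4
  for (i in seq_len(n_iter)) {
    ub <- avg(u); vb <- avg(v)
    common <- (Ix * ub + Iy * vb + It) / denom
    u <- ub - Ix * common
    v <- vb - Iy * common
  }
  mean(sqrt(u^2 + v^2))
}

#' Colony activity by dense optical flow
#'
#' Estimates a dense displacement field between consecutive frames from the
#' brightness-constancy constraint with a global smoothness regularizer
#' (Horn-Schunck formulation, 100 iterations) and reports the mean
#' flow-vector magnitude over the frame, in pixels per transition. Suited to
#' noisier video frames where thresholding is unreliable.
#'
#' With the truncated relaxation, a small regularization weight lets flow
#' diffuse far into textureless background and inflates the mean magnitude;
#' the default `alpha = 2` keeps the estimated field localized so the mean
#' magnitude tracks the displaced pixel mass of the moving objects.
#'
#' @param stack an `image_stack`.
#' @param alpha smoothness regularization weight (default 2).
#' @param n_iter relaxation iterations (default 100).
#' @param species,colony_id,series_id metadata for the returned series.
#' @return an [activity_series()] of length `n_frames - 1`,
#'   `source = "optical_flow"`.
#' @export
optical_flow_activity <- function(stack, alpha = 2, n_iter = 100L,
                                  species = NA_character_,
                                  colony_id = NA_character_,
                                  series_id = "optical_flow") {
  stopifnot(inherits(stack, "image_stack"), length(stack$frames) >= 2)
  vals <- vapply(seq_len(length(stack$frames) - 1L), function(t)
    .hs_flow_magnitude(stack$frames[[t]], stack$frames[[t + 1L]],
                       alpha = alpha, n_iter = n_iter), numeric(1))
  activity_series(vals, sample_interval_s = stack$frame_interval_s,
                  level = "colony", species = species, colony_id = colony_id,
                  source = "optical_flow", series_id = series_id)
}

#' Mean moving speed in an open-field assay
#'
#' Computes instantaneous speed from consecutive coordinates
#' (`displacement * fps / body_length_px`, in body-lengths per second) and
#' averages it over moving frames only — those whose speed exceeds
#' `moving_threshold_bl_s` (0.5 BL/s by convention). Standardizing by body
#' length removes the tendency of larger ants to walk faster in absolute
#' terms.
#'
#' @param track data.frame or matrix with columns `x`, `y` in pixels (one row
#'   per frame), e.g. from [simulate_open_field_track()].
#' @param body_length_px ant body length in pixels.
#' @param fps frames per second of the track.
#' @param moving_threshold_bl_s speed threshold defining "moving" frames.
#' @return a list of class `open_field_result`: `mean_moving_speed` (BL/s),
#'   `moving_frame_count`, `total_frame_count`, `body_length_px`.
#' @export
open_field_speed <- function(track, body_length_px, fps,
                             moving_threshold_bl_s = 0.5) {
  xy <- as.matrix(as.data.frame(track)[, c("x", "y")])
  if (nrow(xy) < 2) stop("track needs at least 2 coordinates", call. = FALSE)
  stopifnot(body_length_px > 0, fps > 0)
  speed <- sqrt(rowSums(diff(xy)^2)) * fps / body_length_px
  moving <- speed > moving_threshold_bl_s
  if (!any(moving))
    stop("never-moving track: no frame exceeds ", moving_threshold_bl_s,
         " body-lengths/s", call. = FALSE)
  structure(list(mean_moving_speed = mean(speed[moving]),
                 moving_frame_count = sum(moving),
                 total_frame_count = length(speed),
                 body_length_px = body_length_px),
            class = "open_field_result")
}

#' @export
print.open_field_result <- function(x, ...) {
  cat(sprintf(
    "<open_field_result> %.3f BL/s over %d/%d moving frames\n",
    x$mean_moving_speed, x$moving_frame_count, x$total_frame_count))
  invisible(x)
}

#' Individual activity by centroid displacement
#'
#' For recordings of a single isolated ant: each frame is thresholded
#' (midpoint of the intensity range, dark foreground), the largest connected
#' component is taken as the ant (ties broken by lowest row, then column
#' index), and activity is the Euclidean displacement of its centroid between
#' successive frames, in pixels. Frames with no foreground pixels are flagged
#' as detection failures and their centroids linearly interpolated; more than
#' 20% failed frames is an error.
#'
#' @param stack an `image_stack` with exactly one dark object per frame.
#' @param species,colony_id,individual_id,series_id metadata for the series.
#' @return an [activity_series()] of length `n_frames - 1`,
#'   `source = "centroid_displacement"`, with attribute `failed_frames`
#'   (integer vector of flagged frames).
#' @export
centroid_displacement_series <- function(stack, species = NA_character_,
                                         colony_id = NA_character_,
                                         individual_id = NA_character_,
                                         series_id = "centroid") {
  stopifnot(inherits(stack, "image_stack"), length(stack$frames) >= 2)
  n <- length(stack$frames)
  cent <- matrix(NA_real_, n, 2)
  failed <- integer(0)
  for (t in seq_len(n)) {
    f <- stack$frames[[t]]
    fg <- f < mean(range(f))
    if (!any(fg)) { failed <- c(failed, t); next }
    lab <- EBImage::bwlabel(fg)
    sizes <- tabulate(lab[lab > 0])
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      # tie: component containing the lowest (row, col) foreground index
      first_idx <- vapply(best, function(b) which(lab == b)[1], numeric(1))
      best <- best[which.min(first_idx)]
    }
    idx <- which(lab == best, arr.ind = TRUE)
    cent[t, ] <- colMeans(idx)
  }
  if (length(failed) > 0.2 * n)
    stop("object detection failed in ", length(failed), " of ", n,
         " frames (> 20%)", call. = FALSE)
  if (length(failed)) {
    for (j in 1:2)
      cent[, j] <- stats::approx(which(!is.na(cent[, j])),
                                 cent[!is.na(cent[, j]), j],
                                 xout = seq_len(n), rule = 2)$y
  }
  vals <- sqrt(rowSums(diff(cent)^2))
  out <- activity_series(vals, sample_interval_s = stack$frame_interval_s,
                         level = "individual", species = species,
                         colony_id = colony_id, individual_id = individual_id,
                         source = "centroid_displacement",
                         series_id = series_id)
  attr(out, "failed_frames") <- failed
  out
}
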