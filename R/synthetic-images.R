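#' Simulate an image stack of moving blobs
#'
#' Generates a sequence of grayscale frames showing dark, disc-shaped blobs
#' (stand-ins for ants) on a light background. Between consecutive frames,
#' exactly `round(frac_moving_per_frame * n_blobs)` blobs jump to a new
#' location at least `2 * blob_radius_px` away from their previous one, so a
#' moving blob's old and new pixel footprints never overlap. Optional
#' additive Gaussian pixel noise is applied independently per frame.
#'
#' @param n_blobs number of blobs.
#' @param n_frames number of frames (>= 2).
#' @param frac_moving_per_frame proportion of blobs displaced at each frame
#'   transition, in \[0, 1\].
#' @param blob_radius_px blob radius in pixels.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (intensities are on \[0, 1\]; background 0.9, blobs 0.1).
#' @param dim_px frame size `c(rows, cols)` in pixels.
#' @param frame_interval_s seconds between frames (default 30).
#' @param seed integer RNG seed.
#' @return a list of class `image_stack`: `frames` (list of matrices),
#'   `frame_interval_s`, and `truth` (data.frame of blob centers per frame,
#'   with a `moved` flag per transition).
#' @export
simulate_image_stack <- function(n_blobs, n_frames, frac_moving_per_frame,
                                 blob_radius_px = 4, noise_sd = 0,
                                 dim_px = c(120, 160), frame_interval_s = 30,
                                 seed = 1L) {
  stopifnot(n_blobs >= 1, n_frames >= 2,
            frac_moving_per_frame >= 0, frac_moving_per_frame <= 1,
            blob_radius_px >= 1, noise_sd >= 0)
  r <- blob_radius_px
  if (2 * r + 2 >= min(dim_px))
    stop("blobs do not fit in the frame", call. = FALSE)
  # crude density check: non-overlap placement needs head room
  if (n_blobs * (2 * r + 2)^2 > 0.5 * prod(dim_px))
    stop("blob placement impossible at the requested density", call. = FALSE)
  set.seed(seed)
  n_move <- round(frac_moving_per_frame * n_blobs)

  rand_pos <- function() c(stats::runif(1, r + 1, dim_px[1] - r),
                           stats::runif(1, r + 1, dim_px[2] - r))
  ok <- function(p, others, min_d) {
    !length(others) || all(sqrt(colSums((matrix(unlist(others), 2) - p)^2)) >= min_d)
  }
  place <- function(others, away_from = NULL, min_jump = 0) {
    for (i in 1:2000) {
      p <- rand_pos()
      if (!ok(p, others, 2 * r + 2)) next
      if (!is.null(away_from) && sqrt(sum((p - away_from)^2)) < min_jump) next
      return(p)
    }
    stop("blob placement impossible at the requested density", call. = FALSE)
  }

  centers <- list()
  for (b in seq_len(n_blobs)) centers[[b]] <- place(centers[seq_len(b - 1)])

  disc <- function(frame, center) {
    rows <- max(1, floor(center[1] - r)):min(dim_px[1], ceiling(center[1] + r))
    cols <- max(1, floor(center[2] - r)):min(dim_px[2], ceiling(center[2] + r))
    d2 <- outer((rows - center[1])^2, (cols - center[2])^2, "+")
    frame[rows, cols][d2 <= r^2] <- 0.1
    frame
  }
  render <- function(cs) {
    f <- matrix(0.9, dim_px[1], dim_px[2])
    for (p in cs) f <- disc(f, p)
    if (noise_sd > 0)
      f <- f + matrix(stats::rnorm(prod(dim_px), 0, noise_sd),
                      dim_px[1], dim_px[2])
    f
  }

  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  frames[[1]] <- render(centers)
  truth[[1]] <- data.frame(frame = 1L, blob = seq_len(n_blobs),
                           row = vapply(centers, `[`, 0, 1),
                           col = vapply(centers, `[`, 0, 2), moved = FALSE)
  for (t in 2:n_frames) {
    movers <- if (n_move > 0) sample.int(n_blobs, n_move) else integer(0)
    for (b in movers)
      centers[[b]] <- place(centers[-b], away_from = centers[[b]],
                            min_jump = 2 * r)
    frames[[t]] <- render(centers)
    truth[[t]] <- data.frame(frame = t, blob = seq_len(n_blobs),
                             row = vapply(centers, `[`, 0, 1),
                             col = vapply(centers, `[`, 0, 2),
                             moved = seq_len(n_blobs) %in% movers)
  }
  structure(list(frames = frames, frame_interval_s = frame_interval_s,
                 truth = do.call(rbind, truth)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %dx%d px @ %gs\n",
              length(x$frames), d[1], d[2], x$frame_interval_s))
  invisible(x)
}

#' Read an image stack from TIFF or PNG files
#'
#' Frames are taken either from a multi-page TIFF or from a directory of
#' single-frame TIFF/PNG files in lexicographic filename order. Color images
#' are converted to grayscale by channel averaging.
#'
#' @param path a multi-page TIFF file or a directory of image files.
#' @param frame_interval_s seconds between frames (default 30).
#' @return an `image_stack` (see [simulate_image_stack()]).
#' @export
read_image_stack <- function(path, frame_interval_s = 30) {
  # EBImage stores images as width x height; transpose to R's row = y
  to_gray <- function(a) {
    if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
    t(a)
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tiff?|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L)
      stop("need at least 2 image files in ", path, call. = FALSE)
    frames <- lapply(files, function(f) {
      img <- EBImage::readImage(f)
      to_gray(EBImage::imageData(img))
    })
  } else {
    img <- EBImage::readImage(path, all = TRUE)
    a <- EBImage::imageData(img)
    if (length(dim(a)) == 2L) stop("multi-page TIFF has a single frame",
                                   call. = FALSE)
    frames <- lapply(seq_len(dim(a)[3]), function(i) t(a[, , i]))
  }
  structure(list(frames = frames, frame_interval_s = frame_interval_s,
                 truth = NULL),
            class = "image_stack")
}

#' Simulate an open-field walking track
#'
#' Generates a 2-D pixel-coordinate track alternating moving bouts (constant
#' speed, random heading per bout) with stationary bouts, such that the
#' requested fraction of frame transitions are moving. Displacement per
#' moving transition is `speed_bl_s * body_length_px / fps` pixels.
#'
#' @param speed_bl_s walking speed during moving bouts, in body-lengths per
#'   second.
#' @param body_length_px body length in pixels.
#' @param fps frames per second (5 in the open-field assay design).
#' @param duration_s track duration in seconds.
#' @param moving_fraction fraction of frame transitions that are moving.
#' @param bout_len_frames mean bout length in frames (bouts are drawn
#'   geometrically and then trimmed to the exact moving fraction).
#' @param seed integer RNG seed.
#' @return data.frame with columns `x`, `y` (pixels) and `moving` (logical,
#'   per transition into each frame; first frame `NA`).
#' @export
simulate_open_field_track <- function(speed_bl_s, body_length_px, fps,
                                      duration_s, moving_fraction = 0.6,
                                      bout_len_frames = 10, seed = 1L) {
  stopifnot(fps > 0, speed_bl_s >= 0, body_length_px > 0,
            moving_fraction >= 0, moving_fraction <= 1)
  set.seed(seed)
  n <- max(2L, floor(duration_s * fps) + 1L)
  n_trans <- n - 1L
  n_moving <- round(moving_fraction * n_trans)
  # contiguous bouts: alternate moving/stationary runs of ~bout_len frames
  state <- logical(0)
  cur <- n_moving > 0
  while (length(state) < n_trans) {
    len <- max(1L, stats::rgeom(1, 1 / bout_len_frames) + 1L)
    state <- c(state, rep(cur, len))
    cur <- !cur
  }
  state <- state[seq_len(n_trans)]
  # trim to the exact count by flipping excess transitions
  excess <- sum(state) - n_moving
  if (excess > 0) state[utils::tail(which(state), excess)] <- FALSE
  if (excess < 0) state[utils::tail(which(!state), -excess)] <- TRUE
  step <- speed_bl_s * body_length_px / fps
  xy <- matrix(0, n, 2)
  xy[1, ] <- c(500, 500)
  heading <- stats::runif(1, 0, 2 * pi)
  for (t in seq_len(n_trans)) {
    if (t > 1 && state[t] && !state[t - 1]) heading <- stats::runif(1, 0, 2 * pi)
    d <- if (state[t]) step * c(cos(heading), sin(heading)) else c(0, 0)
    xy[t + 1, ] <- xy[t, ] + d
  }
  data.frame(x = xy[, 1], y = xy[, 2], moving = c(NA, state))
}
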