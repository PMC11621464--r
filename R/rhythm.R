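#' Rescale an activity series to the unit interval
#'
#' Applies `(x - min) / (max - min)` so the series spans exactly \[0, 1\].
#' All downstream rhythm metrics are computed on rescaled series, which makes
#' the coherence factor invariant to the amplitude (and units) of the raw
#' activity signal.
#'
#' @param series an [activity_series()].
#' @return the rescaled [activity_series()].
#' @export
rescale_unit <- function(series) {
  stopifnot(inherits(series, "activity_series"))
  x <- series$values
  rng <- range(x)
  if (rng[2] - rng[1] <= 0)
    stop("cannot rescale constant series '", series$series_id, "'",
         call. = FALSE)
  series$values <- (x - rng[1]) / (rng[2] - rng[1])
  series
}

# Gaussian kernel on a centered window of `window` points, MATLAB gausswin
# convention (alpha = 2.5, i.e. sd = (window - 1) / 5).
.gauss_kernel <- function(window) {
  if (window == 1L) return(1)
  half <- (window - 1L) / 2L
  sd <- (window - 1) / 5
  k <- exp(-0.5 * ((-half:half) / sd)^2)
  k / sum(k)
}

#' Gaussian-weighted moving average
#'
#' Smooths a series with a Gaussian-weighted moving average over a centered
#' `window`-point window (default 15, the smoothing the rhythm metrics
#' require: unsmoothed series let high-frequency noise distort the wavelet
#' periodogram). At the series edges the kernel is truncated to the available
#' points and renormalized, so the output has the same length as the input.
#'
#' @param series an [activity_series()].
#' @param window odd window length in points (default 15).
#' @return the smoothed [activity_series()].
#' @export
smooth_series <- function(series, window = 15L) {
  stopifnot(inherits(series, "activity_series"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be odd and >= 1", call. = FALSE)
  n <- length(series$values)
  if (window > n) stop("window longer than series", call. = FALSE)
  if (window == 1L) return(series)
  k <- .gauss_kernel(window)
  half <- (window - 1L) %/% 2L
  num <- stats::convolve(c(rep(0, half), series$values, rep(0, half)),
                         rev(k), type = "filter")
  den <- stats::convolve(c(rep(0, half), rep(1, n), rep(0, half)),
                         rev(k), type = "filter")
  series$values <- num / den
  series
}

#' Continuous wavelet periodogram of an activity series
#'
#' Computes a continuous wavelet transform with an analytic Morlet mother
#' wavelet (center frequency `omega0 = 6`) on a logarithmic scale grid with
#' `voices` voices per octave, then sums the absolute wavelet magnitudes over
#' time at each scale. Scales are converted to oscillation periods in
#' minutes, spanning two sampling intervals up to half the record length.
#' Edge effects are mitigated by reflection padding; no cone-of-influence
#' exclusion is applied (all magnitudes contribute to the sum).
#'
#' The caller is expected to rescale and smooth the series first (see
#' [rhythm_metrics()] which enforces the rescale -> smooth -> transform
#' order).
#'
#' @param series an [activity_series()] with at least 64 points.
#' @param voices voices per octave of the scale grid (default 12).
#' @param omega0 Morlet center frequency (default 6).
#' @return a list of class `wavelet_periodogram` with elements `periods_min`
#'   (strictly increasing) and `power` (summed magnitudes, >= 0).
#' @export
wavelet_periodogram <- function(series, voices = 12L, omega0 = 6) {
  stopifnot(inherits(series, "activity_series"))
  x <- series$values
  n <- length(x)
  if (n < 64L)
    stop("series too short for wavelet analysis (need >= 64 points, got ",
         n, ")", call. = FALSE)
  dt <- series$sample_interval_s / 60  # minutes
  # Morlet: scale <-> period conversion (Fourier factor)
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  s0 <- 2 * dt / fourier_factor
  n_octaves <- log2(n / 4)  # largest period = n*dt/2
  if (n_octaves < 2)
    stop("series spans fewer than two octaves of periods", call. = FALSE)
  j <- seq(0, floor(n_octaves * voices)) / voices
  scales <- s0 * 2^j
  # reflection padding to 2n, then FFT-based transform (analytic wavelet:
  # only positive frequencies contribute)
  xp <- c(x, rev(x))
  np <- length(xp)
  xh <- stats::fft(xp)
  omega <- 2 * pi * c(seq(0, floor(np / 2)),
                      seq(floor(np / 2) + 1, np - 1) - np) / (np * dt)
  pos <- omega > 0
  power <- vapply(scales, function(s) {
    psi <- numeric(np)
    psi[pos] <- pi^(-0.25) * sqrt(2 * pi * s / dt) *
      exp(-0.5 * (s * omega[pos] - omega0)^2)
    w <- stats::fft(xh * psi, inverse = TRUE) / np
    sum(Mod(w[seq_len(n)]))
  }, numeric(1))
  structure(list(periods_min = scales * fourier_factor, power = power),
            class = "wavelet_periodogram")
}

#' @export
print.wavelet_periodogram <- function(x, ...) {
  cat(sprintf("<wavelet_periodogram> %d periods in [%.2f, %.2f] min\n",
              length(x$periods_min), min(x$periods_min), max(x$periods_min)))
  invisible(x)
}

#' Dominant oscillation period of a periodogram
#'
#' The period at the global maximum of the summed wavelet power — the typical
#' interval between activity bursts. Ties are broken toward the shorter
#' period.
#'
#' @param pg a [wavelet_periodogram()].
#' @return dominant period in minutes.
#' @export
dominant_period <- function(pg) {
  stopifnot(inherits(pg, "wavelet_periodogram"), length(pg$power) > 0)
  pg$periods_min[which.max(pg$power)]  # which.max takes the first (shortest)
}

#' Rhythmicity (coherence factor) of a periodogram
#'
#' The coherence factor is a signal-to-noise-style measure of rhythm
#' regularity: the ratio of the periodogram's tallest peak height to the mean
#' wavelet magnitude, \eqn{\beta = H_{dp} / W_m}. A flat periodogram gives
#' exactly 1; sharper, more regular oscillations give larger values.
#'
#' @param pg a [wavelet_periodogram()].
#' @return a list of class `rhythm_metrics` with `dominant_period_min`,
#'   `rhythmicity_beta`, `peak_height` and `mean_power`.
#' @export
rhythmicity <- function(pg) {
  stopifnot(inherits(pg, "wavelet_periodogram"), length(pg$power) > 0)
  h <- max(pg$power)
  wm <- mean(pg$power)
  if (wm == 0)
    stop("periodogram has zero mean power (identically zero series)",
         call. = FALSE)
  structure(list(dominant_period_min = dominant_period(pg),
                 rhythmicity_beta = h / wm,
                 peak_height = h, mean_power = wm),
            class = "rhythm_metrics")
}

#' @export
print.rhythm_metrics <- function(x, ...) {
  cat(sprintf("<rhythm_metrics> dominant period %.2f min, beta %.3f\n",
              x$dominant_period_min, x$rhythmicity_beta))
  invisible(x)
}

#' Truncate a colony series to match a target length
#'
#' Colony recordings are longer than individual recordings; comparative
#' analyses use colony series truncated to the individual length so series of
#' equal length are compared. The first `target_len` frames are retained
#' (recordings start in the morning, so the head of the series is the
#' common window).
#'
#' @param series an [activity_series()].
#' @param target_len number of frames to keep (<= series length).
#' @return the truncated [activity_series()].
#' @export
truncate_to_match <- function(series, target_len) {
  stopifnot(inherits(series, "activity_series"))
  n <- length(series$values)
  if (target_len > n)
    stop("target_len (", target_len, ") exceeds series length (", n, ")",
         call. = FALSE)
  series$values <- series$values[seq_len(target_len)]
  series
}

#' Rhythm metrics for one activity series
#'
#' Runs the fixed processing order rescale -> Gaussian smooth -> wavelet
#' periodogram and extracts the dominant period and coherence factor.
#'
#' @param series an [activity_series()].
#' @param window smoothing window (default 15 points).
#' @param truncate_frames optional length to truncate to before processing
#'   (used on colony series to match the individual recording length).
#' @inheritParams wavelet_periodogram
#' @return a `rhythm_metrics` list (see [rhythmicity()]).
#' @export
rhythm_metrics <- function(series, window = 15L, truncate_frames = NULL,
                           voices = 12L, omega0 = 6) {
  if (!is.null(truncate_frames))
    series <- truncate_to_match(series, truncate_frames)
  s <- smooth_series(rescale_unit(series), window = window)
  rhythmicity(wavelet_periodogram(s, voices = voices, omega0 = omega0))
}

#' Rhythm metrics for a collection of series
#'
#' Applies [rhythm_metrics()] to every series and assembles the long metric
#' table used by the comparative module. Colony-level series are truncated to
#' `truncate_frames` (typically the individual recording length) before
#' processing.
#'
#' @param series list of [activity_series()] objects.
#' @param truncate_frames length colony series are truncated to, or `NULL`
#'   to disable truncation.
#' @inheritParams rhythm_metrics
#' @return data.frame with one row per series: series_id, species, colony_id,
#'   individual_id, level, dominant_period_min, beta.
#' @export
rhythm_metrics_table <- function(series, truncate_frames = NULL,
                                 window = 15L, voices = 12L, omega0 = 6) {
  rows <- lapply(series, function(s) {
    tf <- if (identical(s$level, "colony")) truncate_frames else NULL
    if (!is.null(tf)) tf <- min(tf, length(s$values))
    m <- rhythm_metrics(s, window = window, truncate_frames = tf,
                        voices = voices, omega0 = omega0)
    data.frame(series_id = s$series_id, species = s$species,
               colony_id = s$colony_id, individual_id = s$individual_id,
               level = s$level, dominant_period_min = m$dominant_period_min,
               beta = m$rhythmicity_beta, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
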