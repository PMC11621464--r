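# shared fixtures, all built in code

# sine activity series: period in minutes, sampled every 30 s
make_sine <- function(period_min, n = 1020L, noise_sd = 0, seed = NULL,
                      dt_s = 30) {
  if (!is.null(seed)) set.seed(seed)
  x <- sin(2 * pi * (seq_len(n) - 1L) * (dt_s / 60) / period_min)
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  activity_series(x - min(x), sample_interval_s = dt_s, series_id = "sine")
}

# peak period (minutes) of the plain FFT periodogram — the independent
# oracle for dominant-period checks
fft_peak_period <- function(values, dt_min = 0.5) {
  x <- values - mean(values)
  n <- length(x)
  p <- Mod(fft(x))[2:floor(n / 2)]^2
  k <- which.max(p)  # frequency index k / (n * dt)
  n * dt_min / k
}

# per-recording metric table built directly (no simulation): `colony` and
# `individual` are lists mapping species -> matrix/vector of unit values;
# colony units may have several recordings (matrix rows = recordings)
make_metrics <- function(colony, individual, period = 40) {
  rows <- list()
  for (sp in names(colony)) {
    vals <- colony[[sp]]
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
    for (u in seq_len(ncol(vals))) for (r in seq_len(nrow(vals))) {
      rows[[length(rows) + 1L]] <- data.frame(
        series_id = sprintf("%s_c%d_r%d", sp, u, r), species = sp,
        colony_id = sprintf("%s_c%d", sp, u), individual_id = NA_character_,
        level = "colony", dominant_period_min = period,
        beta = vals[r, u], stringsAsFactors = FALSE)
    }
    iv <- individual[[sp]]
    for (u in seq_along(iv)) {
      rows[[length(rows) + 1L]] <- data.frame(
        series_id = sprintf("%s_i%d", sp, u), species = sp,
        colony_id = sprintf("%s_c%d", sp, 1L + (u - 1L) %% ncol(vals)),
        individual_id = sprintf("%s_i%d", sp, u), level = "individual",
        dominant_period_min = period, beta = iv[u], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# small balanced 4-species tree
tree4 <- function() ape::read.tree(
  text = "((a:0.5,b:0.5):0.5,(c:0.5,d:0.5):0.5);")

# star tree with equal branch lengths
star_tree <- function(n, bl = 1) {
  tr <- ape::stree(n, type = "star")
  tr$tip.label <- paste0("t", seq_len(n))
  tr$edge.length <- rep(bl, n)
  tr
}

# two-frame-alternating stripe stack: consecutive frames have opposite
# 1-px-wide stripe phase, so adaptive binarization flips every pixel
stripe_stack <- function(n_frames = 3L, dim_px = 40L) {
  mk <- function(phase) {
    m <- matrix(0.9, dim_px, dim_px)
    m[, seq(1L + phase, dim_px, by = 2L)] <- 0.1
    m
  }
  structure(list(frames = lapply(seq_len(n_frames) %% 2L, mk),
                 frame_interval_s = 30, truth = NULL),
            class = "image_stack")
}

# scaled-down synthetic study (kept small so test time stays bounded)
small_study <- function(seed, n_species = 8L) {
  study_config(n_species = n_species, colonies_per_species = 2L,
               recordings_per_colony = 2L, individuals_per_species = 2L,
               colony_series_len = 300L, individual_series_len = 256L,
               seed = seed)
}
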