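test_that("unit rescaling is exact, affine-invariant and idempotent", {
  s <- activity_series(c(0, 5, 10), series_id = "r")
  expect_equal(rescale_unit(s)$values, c(0, 0.5, 1))
  set.seed(1)
  x <- activity_series(runif(50) + 1, series_id = "x")
  y <- x
  y$values <- 3.7 * x$values + 11
  expect_equal(rescale_unit(x)$values, rescale_unit(y)$values)
  expect_equal(rescale_unit(rescale_unit(x))$values, rescale_unit(x)$values)
  flat <- activity_series(rep(2, 10), series_id = "flat-series")
  expect_error(rescale_unit(flat), "flat-series")
})

test_that("Gaussian smoothing matches an explicit kernel convolution", {
  const <- activity_series(rep(0.4, 40), series_id = "c")
  expect_equal(smooth_series(const)$values, rep(0.4, 40))
  set.seed(2)
  s <- activity_series(runif(200), series_id = "n")
  expect_equal(smooth_series(s, window = 1)$values, s$values)
  expect_error(smooth_series(s, window = 6), "odd")
  # oracle: direct loop over the truncated, renormalized kernel
  w <- 15L; half <- 7L
  sd <- (w - 1) / 5
  k <- exp(-0.5 * ((-half:half) / sd)^2)
  oracle <- vapply(seq_along(s$values), function(i) {
    idx <- (i - half):(i + half)
    ok <- idx >= 1 & idx <= length(s$values)
    sum(s$values[idx[ok]] * k[ok]) / sum(k[ok])
  }, numeric(1))
  expect_lt(max(abs(smooth_series(s, w)$values - oracle)), 1e-10)
})

test_that("the periodogram peak sits at the oracle frequency", {
  for (P in c(10, 20, 40, 80)) {
    s <- smooth_series(rescale_unit(make_sine(P)))
    dp <- dominant_period(wavelet_periodogram(s))
    oracle <- fft_peak_period(s$values)
    expect_lt(abs(log(dp / oracle)), log(2) / 12 + 1e-9,
              label = sprintf("period %d: %.2f vs oracle %.2f", P, dp, oracle))
  }
})

test_that("the stronger of two components dominates", {
  x <- 3 * sin(2 * pi * (0:1019) * 0.5 / 20) +
    sin(2 * pi * (0:1019) * 0.5 / 60)
  s <- smooth_series(rescale_unit(
    activity_series(x - min(x), series_id = "two")))
  dp <- dominant_period(wavelet_periodogram(s))
  expect_lt(abs(log(dp / 20)), 2 * log(2) / 12)
  expect_lt(abs(log(dp / fft_peak_period(s$values))), log(2) / 12 + 1e-9)
})

test_that("periodogram power is nonnegative and needs two octaves", {
  set.seed(4)
  pg <- wavelet_periodogram(activity_series(runif(128), series_id = "w"))
  expect_true(all(pg$power >= 0))
  expect_true(all(diff(pg$periods_min) > 0))
  expect_error(wavelet_periodogram(activity_series(runif(32),
                                                   series_id = "short")),
               "64")
})

test_that("rhythmicity is the peak-to-mean ratio with its exact edge cases", {
  flat <- structure(list(periods_min = 1:5, power = rep(2, 5)),
                    class = "wavelet_periodogram")
  m <- rhythmicity(flat)
  expect_identical(m$rhythmicity_beta, 1)
  expect_identical(m$dominant_period_min, 1L)  # tie broken to shortest
  spiky <- structure(list(periods_min = 1:5, power = c(1, 1, 8, 1, 1)),
                     class = "wavelet_periodogram")
  expect_equal(rhythmicity(spiky)$rhythmicity_beta, 10 / 3)
  zero <- structure(list(periods_min = 1:3, power = rep(0, 3)),
                    class = "wavelet_periodogram")
  expect_error(rhythmicity(zero), "zero")
})

test_that("noise degrades rhythmicity, never below the floor", {
  clean <- rhythm_metrics(make_sine(40))$rhythmicity_beta
  noisy <- vapply(1:20, function(s)
    rhythm_metrics(make_sine(40, noise_sd = 2, seed = s))$rhythmicity_beta,
    numeric(1))
  expect_true(all(clean > noisy))
  expect_true(all(noisy >= 1))
})

test_that("dominant period is invariant to amplitude scaling", {
  s <- make_sine(35, noise_sd = 0.3, seed = 9)
  big <- s
  big$values <- 100 * s$values
  expect_equal(rhythm_metrics(s)$dominant_period_min,
               rhythm_metrics(big)$dominant_period_min)
  expect_equal(rhythm_metrics(s)$rhythmicity_beta,
               rhythm_metrics(big)$rhythmicity_beta)
})

test_that("smoothing keeps a noisy sine's dominant period on its grid point", {
  for (s in 1:5) {
    noisy <- make_sine(40, noise_sd = 0.8, seed = 20 + s)
    dp <- rhythm_metrics(noisy)$dominant_period_min
    clean <- rhythm_metrics(make_sine(40))$dominant_period_min
    expect_lt(abs(log(dp / clean)), log(2) / 12 + 1e-9)
  }
})

test_that("truncation keeps the head of the series", {
  s <- activity_series(seq_len(1740), series_id = "t")
  expect_equal(truncate_to_match(s, 1020)$values, as.numeric(1:1020))
  expect_equal(truncate_to_match(s, 1740)$values, s$values)
  expect_error(truncate_to_match(s, 2000), "exceeds")
})

test_that("metrics are stable under truncation of stationary series", {
  rel <- vapply(1:25, function(s) {
    full <- simulate_fhn_series(fhn_params(noise_sd = 0.3),
                                duration_s = 1740 * 30, seed = 300 + s)
    b_full <- rhythm_metrics(full)$rhythmicity_beta
    b_trunc <- rhythm_metrics(full,
                              truncate_frames = 1020)$rhythmicity_beta
    abs(b_trunc - b_full) / b_full
  }, numeric(1))
  expect_lt(mean(rel), 0.1)
})

test_that("the metric table carries one labelled row per series", {
  ds <- simulate_study_dataset(study_config(
    n_species = 3, colonies_per_species = 1, recordings_per_colony = 2,
    individuals_per_species = 1, colony_series_len = 140,
    individual_series_len = 100, seed = 5))
  tab <- rhythm_metrics_table(ds$series, truncate_frames = 100)
  expect_equal(nrow(tab), length(ds$series))
  expect_setequal(tab$series_id, names(ds$series))
  expect_true(all(tab$beta >= 1))
  expect_true(all(tab$dominant_period_min > 0))
})
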