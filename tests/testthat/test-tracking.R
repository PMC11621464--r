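test_that("pixel-change activity spans its trivial extremes", {
  st0 <- simulate_image_stack(8, 4, 0, noise_sd = 0, seed = 1)
  a0 <- pixel_change_activity(st0)
  expect_identical(unique(a0$values), 0)
  # alternating fine stripes flip every pixel's binary class
  a1 <- pixel_change_activity(stripe_stack())
  expect_identical(unique(a1$values), 1)
  expect_s3_class(a0, "activity_series")
  expect_identical(a0$source, "pixel_change")
})

test_that("pixel-change activity scales with the moving fraction", {
  s5 <- pixel_change_activity(simulate_image_stack(10, 20, 0.5, seed = 11))
  s1 <- pixel_change_activity(simulate_image_stack(10, 20, 0.1, seed = 11))
  ratio <- mean(s5$values) / mean(s1$values)
  expect_lt(abs(ratio - 5) / 5, 0.15)
  # oracle: count displaced blob-pixel mass directly from the truth table
  st <- simulate_image_stack(10, 20, 0.5, seed = 11)
  n_px <- prod(dim(st$frames[[1]]))
  changed <- vapply(2:20, function(t)
    sum(st$frames[[t]] != st$frames[[t - 1]]) / n_px, numeric(1))
  a <- pixel_change_activity(st)
  expect_lt(abs(mean(a$values) - mean(changed)) / mean(changed), 0.25)
})

test_that("pixel-change and flow tolerate a global brightness shift", {
  st <- simulate_image_stack(8, 6, 0.4, seed = 7)
  brighter <- st
  brighter$frames <- lapply(st$frames, function(f) f + 0.1)
  a <- pixel_change_activity(st)
  b <- pixel_change_activity(brighter)
  expect_lt(max(abs(a$values - b$values)) / max(mean(a$values), 1e-9), 0.05)
  fa <- optical_flow_activity(st, n_iter = 40)
  fb <- optical_flow_activity(brighter, n_iter = 40)
  expect_lt(mean(abs(fa$values - fb$values)) / mean(fa$values), 0.05)
})

test_that("optical flow is zero for static scenes and orders speeds", {
  st0 <- simulate_image_stack(6, 4, 0, noise_sd = 0, seed = 2)
  f0 <- optical_flow_activity(st0)
  expect_lt(max(f0$values), 1e-6)
  translate <- function(step) {
    frames <- lapply(0:4, function(t) {
      m <- matrix(0.9, 60, 80)
      m[25:33, (10 + t * step):(18 + t * step)] <- 0.1
      m
    })
    structure(list(frames = frames, frame_interval_s = 30, truth = NULL),
              class = "image_stack")
  }
  slow <- optical_flow_activity(translate(1))
  fast <- optical_flow_activity(translate(3))
  expect_gt(mean(fast$values), mean(slow$values))
  # displaced-mass oracle: mean flow ~ step * blob mass / frame area
  blob_mass <- 9 * 9
  expected <- 2 * blob_mass / (60 * 80)
  expect_lt(abs(mean(optical_flow_activity(translate(2))$values) - expected) /
              expected, 0.3)
  expect_lt(abs(mean(optical_flow_activity(translate(1))$values) -
                  blob_mass / (60 * 80)) / (blob_mass / (60 * 80)), 0.5)
})

test_that("open-field speed follows the body-length normalization exactly", {
  n <- 51
  track <- data.frame(x = seq(0, by = 12, length.out = n), y = 0)
  res <- open_field_speed(track, body_length_px = 20, fps = 5)
  expect_equal(res$mean_moving_speed, 3)  # 12 px/frame * 5 fps / 20 px
  expect_equal(res$moving_frame_count, n - 1L)
  # stationary track is a distinct never-moving error
  still <- data.frame(x = rep(1, 10), y = rep(2, 10))
  expect_error(open_field_speed(still, 20, 5), "never-moving")
  expect_error(open_field_speed(still[1, ], 20, 5), "at least 2")
})

test_that("open-field speed excludes sub-threshold frames and ignores rotation", {
  trk <- simulate_open_field_track(2, 20, 5, 120, moving_fraction = 0.5,
                                   seed = 3)
  res <- open_field_speed(trk, 20, 5)
  expect_lt(abs(res$mean_moving_speed - 2) / 2, 0.02)
  expect_equal(res$moving_frame_count, sum(trk$moving[-1]))
  th <- 0.7
  rot <- data.frame(x = cos(th) * trk$x - sin(th) * trk$y,
                    y = sin(th) * trk$x + cos(th) * trk$y)
  expect_equal(open_field_speed(rot, 20, 5)$mean_moving_speed,
               res$mean_moving_speed)
})

test_that("centroid tracking recovers the generator's step lengths", {
  st <- simulate_image_stack(1, 12, 1, blob_radius_px = 4, seed = 5)
  cd <- centroid_displacement_series(st, series_id = "one")
  tru <- st$truth
  d_true <- vapply(2:12, function(t)
    sqrt(sum((tru[tru$frame == t, c("row", "col")] -
                tru[tru$frame == t - 1, c("row", "col")])^2)), numeric(1))
  expect_lt(sqrt(mean((cd$values - d_true)^2)), 0.5)
  expect_identical(cd$level, "individual")
  # fixed blob: all displacements zero
  st0 <- simulate_image_stack(1, 6, 0, noise_sd = 0, seed = 6)
  expect_equal(max(centroid_displacement_series(st0)$values), 0)
})

test_that("image stacks survive a TIFF round trip", {
  st <- simulate_image_stack(4, 5, 0.5, noise_sd = 0, seed = 12)
  dir <- withr::local_tempdir()
  for (t in seq_along(st$frames))
    tiff::writeTIFF(st$frames[[t]],
                    file.path(dir, sprintf("frame_%03d.tif", t)),
                    bits.per.sample = 16L)
  back <- read_image_stack(dir)
  expect_length(back$frames, 5)
  expect_lt(max(abs(back$frames[[3]] - st$frames[[3]])), 1e-3)
  a <- pixel_change_activity(back)
  b <- pixel_change_activity(st)
  expect_lt(max(abs(a$values - b$values)), 0.02)
})
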