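test_that("image stacks respect the moving-fraction contract", {
  # no movers and no noise: all frames identical
  st0 <- simulate_image_stack(10, 5, 0, noise_sd = 0, seed = 4)
  for (t in 2:5) expect_identical(st0$frames[[t]], st0$frames[[1]])
  # exactly round(frac * n) blobs displaced per transition
  st <- simulate_image_stack(10, 8, 0.3, seed = 3)
  moved <- tapply(st$truth$moved, st$truth$frame, sum)
  expect_true(all(moved[-1] == 3))
  # impossible densities are refused
  expect_error(simulate_image_stack(200, 3, 0.5, blob_radius_px = 8,
                                    dim_px = c(60, 60)),
               "impossible|fit")
})

test_that("open-field tracks realize the requested speed and bout structure", {
  trk0 <- simulate_open_field_track(3, 20, 5, 60, moving_fraction = 0,
                                    seed = 1)
  expect_true(all(diff(trk0$x) == 0 & diff(trk0$y) == 0))
  trk <- simulate_open_field_track(3, 20, 5, 60, moving_fraction = 0.6,
                                   seed = 2)
  d <- sqrt(diff(trk$x)^2 + diff(trk$y)^2)
  expect_equal(sort(unique(round(d, 9))), c(0, 12))  # 3 BL/s * 20 px / 5 fps
  expect_equal(sum(d > 0), round(0.6 * (nrow(trk) - 1)))
})

test_that("chronograms are ultrametric with the requested height and floor", {
  tr <- simulate_chronogram(22, height = 3, seed = 9)
  depths <- ape::node.depth.edgelength(tr)[1:22]
  expect_lt(diff(range(depths)), 1e-9)
  expect_equal(max(depths), 3)
  term <- tr$edge.length[tr$edge[, 2] <= 22]
  expect_gte(min(term), 0.04 * 3)
})

test_that("BM trait simulation matches its analytic covariance", {
  tr <- simulate_chronogram(6, seed = 2)
  # sigma2 = 0 pins every tip at the root state
  expect_equal(unname(simulate_bm_traits(tr, 0, root_state = 1.5, seed = 1)),
               rep(1.5, 6))
  # two-tip star: Var(x1 - x2) = 2 sigma2 t over many draws
  star <- star_tree(2, bl = 0.7)
  d <- vapply(1:10000, function(s) {
    x <- simulate_bm_traits(star, sigma2 = 2, seed = s)
    x[1] - x[2]
  }, numeric(1))
  expect_lt(abs(var(d) - 2 * 2 * 0.7) / (2 * 2 * 0.7), 0.05)
  # empirical tip covariance matches sigma2 * C entrywise
  C <- ape::vcv(tr)
  draws <- t(vapply(1:5000, function(s)
    simulate_bm_traits(tr, sigma2 = 1.3, seed = 10000 + s),
    numeric(6)))
  emp <- cov(draws)
  expect_lt(max(abs(emp - 1.3 * C[colnames(draws), colnames(draws)])) /
              max(1.3 * C), 0.1)
})

test_that("study datasets have the configured shape and full provenance", {
  cfg <- study_config(n_species = 5, colonies_per_species = 1,
                      recordings_per_colony = 2, individuals_per_species = 1,
                      colony_series_len = 128, individual_series_len = 100,
                      seed = 3)
  ds <- simulate_study_dataset(cfg)
  expect_length(ds$series, 5 * (2 + 1))
  expect_equal(nrow(ds$provenance), 15)
  expect_setequal(ds$tree$tip.label, unique(ds$provenance$species))
  lens <- vapply(ds$series, length, 0L)
  lvls <- vapply(ds$series, `[[`, "", "level")
  expect_true(all(lens[lvls == "colony"] == 128))
  expect_true(all(lens[lvls == "individual"] == 100))
  # recordings of the same colony share latent parameters; colonies differ
  pc <- ds$provenance[ds$provenance$level == "colony", ]
  expect_true(all(tapply(pc$noise_sd, pc$colony_id,
                         function(v) diff(range(v)) == 0)))
  # bit-identical rerun
  ds2 <- simulate_study_dataset(cfg)
  expect_identical(ds$provenance, ds2$provenance)
  expect_identical(lapply(ds$series, `[[`, "values"),
                   lapply(ds2$series, `[[`, "values"))
})

test_that("a 3:1 rhythm-strength SD ratio surfaces as a higher colony rate", {
  hits <- vapply(1:10, function(s) {
    cfg <- study_config(n_species = 12L, colonies_per_species = 2L,
                        recordings_per_colony = 2L,
                        individuals_per_species = 4L,
                        colony_series_len = 768L,
                        individual_series_len = 768L, seed = s)
    ds <- simulate_study_dataset(cfg)
    met <- rhythm_metrics_table(ds$series, truncate_frames = 768)
    rc <- bootstrap_rate_comparison(met, ds$tree, "rhythmicity",
                                    n_boot = 100, seed = s + 500)
    rc$sigma2_colony > rc$sigma2_individual
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("series CSV round trip preserves values and metadata", {
  ds <- simulate_study_dataset(study_config(
    n_species = 3, colonies_per_species = 1, recordings_per_colony = 1,
    individuals_per_species = 1, colony_series_len = 80,
    individual_series_len = 70, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(ds$series, path)
  back <- read_series_csv(path)
  expect_setequal(names(back), names(ds$series))
  for (id in names(back)) {
    expect_equal(back[[id]]$values, ds$series[[id]]$values)
    expect_identical(back[[id]]$species, ds$series[[id]]$species)
    expect_identical(back[[id]]$level, ds$series[[id]]$level)
  }
})
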