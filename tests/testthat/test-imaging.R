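# small synthetic state with a production ring at a chosen radius
ring_state <- function(r_ring, R0 = 1.5, n = 151) {
  r <- seq(0, R0, length.out = n)
  z <- rep(0, n)
  ba <- z; ba[which.min(abs(r - r_ring))] <- 1
  structure(list(time = 0, r = r, m = 1L, R0 = R0,
                 rho_poly = rep(1, n), rho_ba = ba, rho_cross = z, kappa = z),
            class = "field_state")
}

test_that("noiseless render puts the brightest ring at the front radius", {
  p <- model_parameters()
  st <- ring_state(1.0)
  fr <- render_frame(st, p, pixel_size_um = 10,
                     noise = imaging_noise_model(sigma = 0, vignetting = 0))
  ctr <- attr(fr, "center")
  prof <- radial_profile(fr, ctr)
  pk <- prof$radius_px[which.max(prof$intensity)]
  expect_lte(abs(pk - 100), 1)
  expect_error(render_frame(st, p, pixel_size_um = 0), "positive")
})

test_that("rendering is deterministic under a fixed seed", {
  p <- model_parameters()
  st <- ring_state(0.8)
  nm <- imaging_noise_model(sigma = 0.08, seed = 99)
  f1 <- render_frame(st, p, noise = nm)
  f2 <- render_frame(st, p, noise = nm)
  expect_identical(f1, f2)
  f3 <- render_frame(st, p, noise = imaging_noise_model(sigma = 0.08, seed = 100))
  expect_false(identical(f1, f3))
  # rendering must not disturb the caller's RNG stream
  set.seed(5); a <- runif(1)
  set.seed(5); invisible(render_frame(st, p, noise = nm)); b <- runif(1)
  expect_identical(a, b)
})

test_that("bandpass filter removes flats and impulses but keeps rings", {
  expect_error(bandpass_filter(matrix(0, 32, 32)), "64 x 64")
  expect_error(bandpass_filter(matrix(0, 128, 128), large_px = 3, small_px = 3),
               "exceed")
  # constant frame: pure large-scale structure, removed entirely
  flat <- bandpass_filter(matrix(5, 128, 128))
  expect_lt(max(abs(flat)), 1e-10)
  # single-pixel impulse: below 10 % of input amplitude
  imp <- matrix(0, 128, 128); imp[64, 64] <- 1
  expect_lt(max(abs(bandpass_filter(imp))), 0.1)
  expect_equal(mean(bandpass_filter(imp)), 0)
  # ring of width ~10 px survives with at least half its amplitude
  ax <- seq_len(256) - 128.5
  rr <- sqrt(outer(ax^2, ax^2, "+"))
  ring <- exp(-((rr - 60) / 5)^2)
  filt <- bandpass_filter(ring)
  expect_gte(max(filt), 0.5 * max(ring))
})

test_that("front diameter detection is accurate and rejects flat frames", {
  p <- model_parameters()
  st <- ring_state(1.2)
  fr <- render_frame(st, p, pixel_size_um = 10,
                     noise = imaging_noise_model(sigma = 0, vignetting = 0))
  det <- detect_front_diameter(fr)
  expect_equal(det$diameter_um, 2400, tolerance = 20 / 2400)
  # flat frame: not found
  flat <- matrix(0.3, 301, 301)
  det0 <- detect_front_diameter(flat, pixel_size_um = 10)
  expect_true(is.na(det0$diameter_um))
  # noisy ring: within 2 px of truth after bandpass
  frn <- render_frame(st, p, pixel_size_um = 10,
                      noise = imaging_noise_model(sigma = 0.1, seed = 3))
  detn <- detect_front_diameter(bandpass_filter(frn))
  expect_lte(abs(detn$radius_px - 120), 2)
  expect_error(detect_front_diameter(fr, center = c(-5, 10)), "outside")
})

test_that("series tracking round-trips a simulation and drops bad frames", {
  sim <- simulate_scenario(
    make_disc_scenario(40, n_nodes = 120, horizon = 2e4, cadence = 250))
  ftr <- build_front_trajectory(sim)
  idx <- seq(1, length(sim$times), by = 4)
  ser <- render_series(sim, pixel_size_um = 25,
                       noise = imaging_noise_model(sigma = 0.05, seed = 21),
                       idx = idx)
  itr <- track_image_series(ser)
  both <- is.finite(itr$radius_mm) & is.finite(ftr$radius_mm[idx])
  expect_gt(mean(both), 0.8)
  # image-based radii within 5 % of the field-level radii at matched times
  expect_lt(max(abs(itr$radius_mm[both] - ftr$radius_mm[idx][both]) /
                  ftr$radius_mm[idx][both]), 0.05)
  # corrupting one mid-series frame only removes that detection
  ser2 <- ser
  ser2$frames[[5]] <- matrix(0.5, nrow(ser$frames[[5]]), ncol(ser$frames[[5]]))
  itr2 <- track_image_series(ser2)
  expect_true(is.na(itr2$radius_mm[5]))
  expect_equal(sum(is.finite(itr2$radius_mm)),
               sum(is.finite(itr$radius_mm)) - 1)
  expect_error(image_series(list(), numeric(0), 10), "empty")
  expect_error(track_image_series(ser$frames), "image_series")
})

test_that("identical seeds give byte-identical synthetic stacks", {
  sim <- simulate_scenario(
    make_disc_scenario(40, n_nodes = 80, horizon = 3000, cadence = 500))
  nm <- imaging_noise_model(sigma = 0.1, seed = 17)
  s1 <- render_series(sim, pixel_size_um = 30, noise = nm)
  s2 <- render_series(sim, pixel_size_um = 30, noise = nm)
  expect_identical(s1, s2)
})

test_that("PGM round trip preserves frames up to quantisation", {
  sim <- simulate_scenario(
    make_disc_scenario(40, n_nodes = 80, horizon = 2000, cadence = 500))
  ser <- render_series(sim, pixel_size_um = 40,
                       noise = imaging_noise_model(sigma = 0.05, seed = 3))
  dir <- withr::local_tempdir()
  meta <- write_image_series(ser, dir, prefix = "t")
  back <- read_image_series(meta)
  expect_equal(back$timestamps, ser$timestamps)
  expect_equal(back$pixel_size_um, ser$pixel_size_um)
  rng <- max(vapply(ser$frames, max, 0)) - min(vapply(ser$frames, min, 0))
  err <- max(mapply(function(a, b) max(abs(a - b)), ser$frames, back$frames))
  expect_lt(err, rng / 65535)
})

test_that("centre estimation lands near the true disc centre", {
  p <- model_parameters()
  st <- ring_state(1.0)
  fr <- render_frame(st, p, pixel_size_um = 10,
                     noise = imaging_noise_model(sigma = 0.05, seed = 8))
  ser <- image_series(list(fr, fr, fr, fr, fr), 0:4, 10)
  est <- estimate_center(ser)
  expect_lt(max(abs(est - attr(fr, "center"))), 2)
})
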