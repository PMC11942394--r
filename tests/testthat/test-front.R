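# assemble a field_state by hand (bypassing the solver)
mk_state <- function(r, poly, ba, cross, kap, time = 0, m = 1L) {
  structure(list(time = time, r = r, m = m, R0 = max(r),
                 rho_poly = poly, rho_ba = ba, rho_cross = cross,
                 kappa = kap),
            class = "field_state")
}

test_that("production profile mirrors the cross-link source term", {
  p <- model_parameters()
  r <- seq(0, 2, length.out = 21)
  z <- rep(0, 21)
  # no barium anywhere: nothing reacts
  st <- mk_state(r, rep(1, 21), z, z, z)
  expect_identical(production_profile(st, p), z)
  # single active node reproduces the pointwise arithmetic (0.25)
  ba <- z; ba[13] <- 1
  cross <- z; cross[13] <- 0.5
  kap <- z; kap[13] <- 0.2
  st2 <- mk_state(r, rep(1, 21), ba, cross, kap)
  pr <- production_profile(st2, p)
  expect_equal(pr[13], 0.25)
  expect_identical(pr[-13], z[-13])
  # fully gelled: no polymer left, occupancy saturated
  st3 <- mk_state(r, z, rep(2, 21), rep(2.5, 21), rep(1, 21))
  expect_equal(production_profile(st3, p), z)
})

test_that("front extraction takes the production argmax, outermost on ties", {
  p <- model_parameters()
  r <- seq(0, 2, length.out = 41)
  z <- rep(0, 41)
  ba <- z; ba[which.min(abs(r - 1.2))] <- 1
  st <- mk_state(r, rep(1, 41), ba, z, z)
  expect_equal(extract_front_radius(st, p)$radius, 1.2, tolerance = 0.03)
  # two equal peaks: outermost wins
  ba2 <- z; ba2[c(11, 31)] <- 1
  st2 <- mk_state(r, rep(1, 41), ba2, z, z)
  expect_equal(extract_front_radius(st2, p)$radius, r[31])
  # all-zero production: not found
  st3 <- mk_state(r, rep(1, 41), z, z, z)
  expect_true(is.na(extract_front_radius(st3, p)$radius))
  # detection floor
  expect_true(is.na(extract_front_radius(st, p, min_peak = 1)$radius))
})

test_that("trajectory bookkeeping finds the gelation time", {
  tr <- front_trajectory(times = c(0, 60, 120, 180, 240),
                         radius_mm = c(2.5, 2.0, 1.5, 1.0, 0.0))
  expect_equal(tr$gelation_time_s, 240)
  # constant front: gelation never reached, reason reported
  tr2 <- front_trajectory(times = seq(0, 240, 60), radius_mm = rep(2, 5))
  expect_true(is.na(tr2$gelation_time_s))
  expect_match(tr2$reason, "persisted")
  # a single isolated dropout is detector noise, not completion
  tr3 <- front_trajectory(times = seq(0, 300, 50),
                          radius_mm = c(2.5, 2.0, NA, 1.6, 1.4, 1.2, 1.0))
  expect_true(is.na(tr3$gelation_time_s))
  # two consecutive misses mean the front is gone
  tr4 <- front_trajectory(times = seq(0, 300, 50),
                          radius_mm = c(2.5, 2.0, 1.5, 1.2, 1.1, NA, NA))
  expect_equal(tr4$gelation_time_s, 250)
})

test_that("simulated disc trajectory shrinks monotonically", {
  sim <- simulate_scenario(
    make_disc_scenario(40, n_nodes = 150, horizon = 2e4, cadence = 200))
  tr <- build_front_trajectory(sim)
  r <- tr$radius_mm[is.finite(tr$radius_mm)]
  expect_gte(length(r), 50)
  # non-increasing within one (graded) grid cell of tolerance
  cell <- max(diff(sim$grid$r))
  expect_true(all(diff(r) <= cell))
  # strictly decreasing once thinned so the front moves >= 1 cell per sample
  thin <- r[seq(1, length(r), by = 8)]
  expect_true(all(diff(thin) < 0))
})

test_that("piecewise-linear segmentation recovers generating velocities", {
  t <- seq(0, 100, by = 5)
  r <- ifelse(t < 50, 2.5 - 0.02 * t, 1.5 - 0.005 * (t - 50))
  fit <- segment_and_fit_velocities(front_trajectory(t, r, R0 = 2.5))
  expect_equal(fit$breakpoint_s, 50)
  expect_equal(fit$v_early, -0.02, tolerance = 1e-8)
  expect_equal(fit$v_late, -0.005, tolerance = 1e-8)
  expect_identical(fit$flag, "ok")
  # pure linear data: slopes agree and the breakpoint is flagged
  rl <- 2.5 - 0.01 * t
  fl <- segment_and_fit_velocities(front_trajectory(t, rl, R0 = 2.5))
  expect_identical(fl$flag, "unidentifiable")
  expect_equal(fl$v_early, fl$v_late, tolerance = 1e-6)
  expect_equal(fl$v_early, -0.01, tolerance = 1e-8)
  # noisy piecewise data: slopes within 10 % of the generating values
  set.seed(11)
  rn <- r + rnorm(length(t), 0, 0.01)
  fn <- segment_and_fit_velocities(front_trajectory(t, rn, R0 = 2.5))
  expect_equal(fn$v_early, -0.02, tolerance = 0.1)
  expect_equal(fn$v_late, -0.005, tolerance = 0.1)
  # degenerate and undersized inputs
  expect_warning(
    fd <- segment_and_fit_velocities(front_trajectory(t, rep(1, 21), R0 = 1)),
    "constant")
  expect_identical(fd$v_early, 0)
  expect_error(
    segment_and_fit_velocities(front_trajectory(1:5, c(5:2, NA), R0 = 5)),
    "at least 8")
})
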