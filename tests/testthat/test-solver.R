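# near-zero rate constants: positivity invariants require strictly positive
# parameters, so "reaction off" is represented by negligibly small ones
inert_params <- function() {
  model_parameters(K_poly = 1e-30, K_ba = 1e-30, C_poly = 1e-30,
                   C_ba = 1e-30, C_kba = 1e-30, C_k = 1e-30)
}

test_that("with no barium and no reaction all fields stay constant", {
  sc <- make_slab_scenario(2, bath_mM = 1e-9, n_nodes = 80,
                           horizon = 100, cadence = 20)
  sim <- simulate_scenario(sc, inert_params())
  for (f in c("rho_poly", "rho_cross", "kappa")) {
    expect_equal(max(abs(sweep(sim$fields[[f]], 2, sim$fields[[f]][1, ]))), 0,
                 tolerance = 1e-12)
  }
  expect_lt(max(sim$fields$rho_ba), 1e-9)
})

test_that("reaction-free slab matches the erfc closed form within 1%", {
  # semi-infinite approximation: domain 4 mm >> diffusion length ~0.9 mm
  p <- inert_params()
  sc <- make_slab_scenario(4, bath_mM = 10, n_nodes = 400,
                           refinement = "uniform", horizon = 120, cadence = 30)
  sim <- simulate_scenario(sc, p)
  i <- which(sim$times == 120)
  x_depth <- 4 - sim$grid$r                  # depth below the bath face
  probe <- which(x_depth > 0.1 & x_depth < 1.6)
  num <- sim$fields$rho_ba[i, probe]
  ref <- analytic_slab_diffusion(x_depth[probe], t = 120, D = p$D0_ba, c0 = 1)
  expect_true(all(abs(num - ref) / ref < 0.01))
})

test_that("single-node reaction integration matches the RK45 oracle to 1e-6", {
  p <- model_parameters()
  times <- seq(0, 200, by = 25)
  tight <- solver_options(rtol = 1e-9, atol = 1e-12)
  for (y0 in list(c(1, 4, 0, 0), c(1, 1, 0.5, 0.2), c(0.3, 2, 1.5, 0.7))) {
    mine <- integrate_local(local_state(y0[1], y0[2], y0[3], y0[4]), p,
                            times, tight)
    ref <- oracle_rk45(y0, p, times)
    expect_equal(mine, ref, tolerance = 1e-6)
  }
})

test_that("analytic slab profile has the documented limits", {
  expect_equal(analytic_slab_diffusion(0, 10, 1e-3, c0 = 2), 2)
  expect_lt(analytic_slab_diffusion(100, 1, 1e-3, c0 = 2), 1e-12)
  x <- 0.5 * 2 * sqrt(1e-3 * 50)             # x/(2 sqrt(D t)) = 0.5
  expect_equal(analytic_slab_diffusion(x, 50, 1e-3), 0.4795, tolerance = 1e-3)
  expect_error(analytic_slab_diffusion(1, 0, 1e-3), "t must be positive")
})

test_that("cross-link density and occupancy are monotone; fields stay bounded", {
  sc <- make_disc_scenario(40, n_nodes = 120, horizon = 4000, cadence = 200)
  sim <- simulate_scenario(sc)
  expect_true(all(apply(sim$fields$rho_cross, 2, diff) >= -1e-9))
  expect_true(all(apply(sim$fields$kappa, 2, diff) >= -1e-9))
  expect_true(all(sim$fields$kappa >= 0 & sim$fields$kappa <= 1))
  expect_true(all(sim$fields$rho_poly >= 0))
  expect_true(all(sim$fields$rho_ba >= 0))
  # polymer never exceeds its initial density (it only degrades and diffuses)
  expect_lt(max(sim$fields$rho_poly), 1 + 1e-6)
})

test_that("integrator failures surface as errors with the last accepted time", {
  sc <- make_disc_scenario(40, n_nodes = 100, horizon = 2000, cadence = 100)
  expect_error(
    simulate_scenario(sc, options = solver_options(max_steps = 10)),
    "max step count")
  expect_error(solver_options(rtol = 2), "rtol")
  expect_error(solver_options(atol = -1), "atol")
})

test_that("explicit output times override the cadence grid", {
  sc <- make_disc_scenario(40, n_nodes = 80, horizon = 100, cadence = 50)
  tt <- c(0, 0.5, 1, 5, 20, 60)
  sim <- simulate_scenario(sc, out_times = tt)
  expect_equal(sim$times, tt)
  expect_error(simulate_scenario(sc, out_times = c(1, 2)), "start at 0")
})
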