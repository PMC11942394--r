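write_cfg <- function(lines) {
  path <- withr::local_tempfile(fileext = ".cfg",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a minimal config is completed with the published defaults", {
  cfg <- load_config(write_cfg(c("geometry: disc", "bath_mM: 20")))
  expect_equal(attr(cfg$params, "D0_ba_m2s"), 6.78e-9)
  expect_equal(attr(cfg$params, "D0_poly_m2s"), 6.78e-12)
  expect_equal(cfg$params$C_poly, 0.16)
  expect_equal(cfg$scenario$bath_ba, 2.0)
  expect_equal(cfg$scenario$R0, 2.523, tolerance = 1e-3)
  expect_equal(cfg$options$rtol, 1e-6)
})

test_that("config validation is aggregated and names unknown keys", {
  expect_error(load_config(write_cfg("wibble: 3")), "wibble")
  # an inverted diffusivity gap violates the ion >> polymer requirement
  expect_error(
    load_config(write_cfg(c("geometry: disc", "bath_mM: 20",
                            "D0_ba: 1e-13"))),
    "10x")
  # several problems are reported together
  err <- tryCatch(
    load_config(write_cfg(c("geometry: tube", "bath_mM: -1"))),
    error = conditionMessage)
  expect_match(err, "geometry")
  expect_match(err, "bath_mM")
  expect_error(load_config("/nonexistent/path.cfg"), "not found")
})

test_that("save -> load round trip reproduces the configuration", {
  cfg <- load_config(write_cfg(c("geometry: sphere", "bath_mM: 40",
                                 "diameter_um: 1705", "n_nodes: 80",
                                 "horizon: 5000", "cadence: 50",
                                 "C_poly: 0.2", "seed: 9")))
  path <- withr::local_tempfile(fileext = ".cfg")
  save_config(cfg, path)
  cfg2 <- load_config(path)
  expect_equal(cfg2$scenario$R0, cfg$scenario$R0)
  expect_equal(cfg2$scenario$horizon, cfg$scenario$horizon)
  expect_equal(cfg2$params$C_poly, 0.2)
  expect_equal(cfg2$seed, 9L)
})

test_that("run_simulate writes trajectory, fields and summary artifacts", {
  # sphere gels quickly enough for a full-run smoke test
  cfg <- load_config(write_cfg(c("geometry: sphere", "diameter_um: 1500",
                                 "bath_mM: 40", "n_nodes: 120",
                                 "horizon: 6000", "cadence: 60")))
  out <- withr::local_tempdir()
  res <- run_simulate(cfg, out)
  expect_true(all(file.exists(file.path(out, c("trajectory.csv", "fields.csv",
                                               "summary.json")))))
  summ <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_gt(summ$gelation_time_s, 0)
  expect_lt(summ$v_early_mm_per_s, 0)
  expect_lt(summ$v_late_mm_per_s, 0)
  expect_identical(summ$units$velocity, "mm/s")
  tr <- read.csv(file.path(out, "trajectory.csv"))
  expect_identical(names(tr), c("time_s", "front_radius_mm",
                                "front_diameter_mm"))
  expect_equal(tr$front_diameter_mm, 2 * tr$front_radius_mm)
  fields <- read.csv(file.path(out, "fields.csv"))
  expect_true(all(c("time_s", "radius_mm", "rho_poly", "rho_ba", "rho_cross",
                    "kappa") %in% names(fields)))
})

test_that("two runs from the same config produce identical trajectories", {
  cfg <- load_config(write_cfg(c("geometry: disc", "bath_mM: 40",
                                 "n_nodes: 80", "horizon: 4000",
                                 "cadence: 200", "seed: 4")))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_simulate(cfg, d1)
  run_simulate(cfg, d2)
  expect_identical(readLines(file.path(d1, "trajectory.csv")),
                   readLines(file.path(d2, "trajectory.csv")))
})

test_that("a failing run leaves no partial field artifacts behind", {
  cfg <- load_config(write_cfg(c("geometry: disc", "bath_mM: 40",
                                 "n_nodes: 80", "horizon: 4000",
                                 "cadence: 200")))
  cfg$options <- solver_options(max_steps = 5)
  out <- file.path(withr::local_tempdir(), "run")
  expect_error(run_simulate(cfg, out), "max step")
  expect_false(file.exists(file.path(out, "fields.csv")))
  expect_false(file.exists(file.path(out, "summary.json")))
})

test_that("summary JSON honours the negative-velocity convention and nulls", {
  path <- withr::local_tempfile(fileext = ".json")
  write_summary(list(gelation_time_s = NA_real_, reason = "front persisted",
                     breakpoint_s = 120, v_early_mm_per_s = -0.02,
                     v_late_mm_per_s = -0.005, fit_flag = "ok", R0_mm = 2.5),
                path)
  doc <- jsonlite::read_json(path)
  expect_null(doc$gelation_time_s)
  expect_identical(doc$gelation_not_reached_reason, "front persisted")
  expect_identical(doc$v_late_mm_per_s, -0.005)
  expect_identical(doc$units$length, "mm")
})
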