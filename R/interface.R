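#' Load a run configuration
#'
#' Reads a flat `key: value` configuration file (a YAML subset: one scalar
#' per line, `#` comments, blank lines ignored), fills every omitted model
#' parameter with its published default, builds the scenario and solver
#' options, and validates. Validation reports every violation at once, not
#' just the first; unknown keys are an error naming them.
#'
#' Recognised keys: `geometry` (disc | sphere), `bath_mM`, `diameter_um`
#' (sphere), `volume_uL`, `height_um` (disc), `n_nodes`, `refinement`,
#' `horizon`, `cadence`, `rtol`, `atol`, `seed`, `label`, and the eight
#' parameters `D0_poly`, `D0_ba` (m^2/s), `K_poly`, `K_ba`, `C_poly`,
#' `C_ba`, `C_kba`, `C_k`.
#'
#' @param path config file path.
#' @return Object of class `run_config`: list with `scenario`, `params`,
#'   `options`, `seed`, `label`, `raw` (the parsed key/value list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  kv <- .parse_flat_config(path)
  config_from_list(kv)
}

#' @rdname load_config
#' @param kv named list of configuration values (as parsed from a file).
#' @export
config_from_list <- function(kv) {
  scen_keys <- c("geometry", "bath_mM", "diameter_um", "volume_uL",
                 "height_um", "n_nodes", "refinement", "horizon", "cadence")
  par_keys <- c("D0_poly", "D0_ba", "K_poly", "K_ba",
                "C_poly", "C_ba", "C_kba", "C_k")
  misc_keys <- c("rtol", "atol", "seed", "label")
  unknown <- setdiff(names(kv), c(scen_keys, par_keys, misc_keys))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  geometry <- kv$geometry %||% "disc"
  if (!geometry %in% c("disc", "sphere")) {
    note(sprintf("geometry must be 'disc' or 'sphere', got '%s'", geometry))
  }
  num <- function(key, default) {
    v <- kv[[key]] %||% default
    v <- suppressWarnings(as.numeric(v))
    if (length(v) != 1 || is.na(v)) note(sprintf("key '%s' is not numeric", key))
    v
  }
  bath_mM <- num("bath_mM", 20)
  if (!is.na(bath_mM) && bath_mM <= 0) note("bath_mM must be positive")

  params <- tryCatch({
    args <- lapply(par_keys, function(k) {
      if (is.null(kv[[k]])) NULL else suppressWarnings(as.numeric(kv[[k]]))
    })
    names(args) <- par_keys
    do.call(model_parameters, args[!vapply(args, is.null, TRUE)])
  }, error = function(e) { note(conditionMessage(e)); NULL })

  options <- tryCatch(
    solver_options(rtol = num("rtol", 1e-6), atol = num("atol", 1e-9)),
    error = function(e) { note(conditionMessage(e)); NULL })

  scenario <- NULL
  if (!length(problems)) {
    scenario <- tryCatch({
      common <- list(n_nodes = as.integer(num("n_nodes", 600)),
                     refinement = kv$refinement %||% "graded",
                     label = kv$label %||% NULL)
      if (geometry == "disc") {
        do.call(make_disc_scenario, c(
          list(bath_mM = bath_mM, volume_uL = num("volume_uL", 4),
               height_um = num("height_um", 200),
               horizon = num("horizon", 4e5), cadence = num("cadence", 120)),
          common))
      } else {
        do.call(make_sphere_scenario, c(
          list(diameter_um = num("diameter_um", 1500), bath_mM = bath_mM,
               horizon = num("horizon", 1.2e5), cadence = num("cadence", 60)),
          common))
      }
    }, error = function(e) { note(conditionMessage(e)); NULL })
  }
  if (length(problems)) {
    stop("invalid configuration (", length(problems), " problem(s)):\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(list(scenario = scenario, params = params, options = options,
                 seed = as.integer(num("seed", 1)),
                 label = scenario$label, raw = kv),
            class = "run_config")
}

.parse_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln)[[1]]
    if (m[1] == -1) stop("cannot parse config line: '", ln, "'")
    key <- substring(ln, m[2], m[2] + attr(m, "match.length")[2] - 1)
    val <- substring(ln, m[3], m[3] + attr(m, "match.length")[3] - 1)
    kv[[key]] <- trimws(val)
  }
  kv
}

#' Save a run configuration
#'
#' Writes the flat key/value form; [load_config()] of the result reproduces
#' the configuration (round trip).
#'
#' @param config a `run_config`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  sc <- config$scenario
  p <- config$params
  kv <- c(
    geometry = sc$geometry, bath_mM = sc$bath_mM,
    if (sc$geometry == "sphere") c(diameter_um = format(sc$R0 * 2000)),
    n_nodes = length(sc$grid$r), refinement = sc$grid$refinement,
    horizon = sc$horizon, cadence = sc$cadence,
    D0_poly = format(attr(p, "D0_poly_m2s")), D0_ba = format(attr(p, "D0_ba_m2s")),
    K_poly = p$K_poly, K_ba = p$K_ba, C_poly = p$C_poly, C_ba = p$C_ba,
    C_kba = p$C_kba, C_k = p$C_k,
    rtol = format(config$options$rtol), atol = format(config$options$atol),
    seed = config$seed, label = sc$label)
  writeLines(paste0(names(kv), ": ", unname(kv)), path)
  invisible(path)
}

#' Run a configured simulation and write its artifacts
#'
#' Executes the forward model, the front extraction and the two-phase fit,
#' and writes: `fields.csv` (long table: time_s, radius_mm, the four
#' fields), `trajectory.csv` (time_s, front_radius_mm, front_diameter_mm)
#' and `summary.json`. Artifacts appear only on success: everything is
#' staged to a temporary directory and moved into place at the end, so a
#' failing run leaves no partial field files behind.
#'
#' @param config a `run_config` (see [load_config()]).
#' @param out_dir output directory.
#' @param fields_every thin the fields CSV to every n-th stored state
#'   (default 10; the trajectory always uses every state).
#' @return List with `summary` and the written `paths`, invisibly.
#' @export
run_simulate <- function(config, out_dir, fields_every = 10) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  sim <- simulate_scenario(config$scenario, config$params, config$options)
  traj <- build_front_trajectory(sim)
  summ <- front_summary(traj)
  stage <- tempfile("gelfront_stage_")
  dir.create(stage, recursive = TRUE)
  write_trajectory_csv(traj, file.path(stage, "trajectory.csv"))
  write_fields_csv(sim, file.path(stage, "fields.csv"), every = fields_every)
  write_summary(summ, file.path(stage, "summary.json"),
                extra = list(label = config$label,
                             solver_stats = sim$stats))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (f in list.files(stage)) {
    dest <- file.path(out_dir, f)
    file.copy(file.path(stage, f), dest, overwrite = TRUE)
    paths[f] <- dest
  }
  unlink(stage, recursive = TRUE)
  invisible(list(summary = summ, paths = paths, sim = sim, trajectory = traj))
}

#' @rdname run_simulate
#' @param traj a [front_trajectory()].
#' @param path destination CSV.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "front_trajectory"))
  utils::write.csv(
    data.frame(time_s = traj$times, front_radius_mm = traj$radius_mm,
               front_diameter_mm = 2 * traj$radius_mm),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname run_simulate
#' @param sim a `gel_sim`.
#' @param every keep every n-th state.
#' @export
write_fields_csv <- function(sim, path, every = 1) {
  stopifnot(inherits(sim, "gel_sim"))
  idx <- seq(1, length(sim$times), by = every)
  n <- length(sim$grid$r)
  df <- do.call(rbind, lapply(idx, function(i) {
    data.frame(time_s = sim$times[i], radius_mm = sim$grid$r,
               rho_poly = sim$fields$rho_poly[i, ],
               rho_ba = sim$fields$rho_ba[i, ],
               rho_cross = sim$fields$rho_cross[i, ],
               kappa = sim$fields$kappa[i, ])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run summary as JSON
#'
#' Velocities keep the field's sign convention: the front speed is the rate
#' of change of the ungelled core radius and is negative. A run whose front
#' never dissipated reports `gelation_time_s: null` plus a reason string.
#'
#' @param summary a [front_summary()] list.
#' @param path destination JSON file.
#' @param extra optional named list merged into the document.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, extra = NULL) {
  doc <- list(
    gelation_time_s = if (is.na(summary$gelation_time_s)) NULL else summary$gelation_time_s,
    gelation_not_reached_reason = summary$reason,
    breakpoint_s = if (is.na(summary$breakpoint_s)) NULL else summary$breakpoint_s,
    v_early_mm_per_s = summary$v_early_mm_per_s,
    v_late_mm_per_s = summary$v_late_mm_per_s,
    fit_flag = summary$fit_flag,
    R0_mm = summary$R0_mm,
    units = list(time = "s", length = "mm", velocity = "mm/s"))
  doc <- c(doc, extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
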