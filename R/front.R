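#' Instantaneous cross-linking production profile
#'
#' Per-node source rate of cross-linked polymer,
#' `(C_poly + C_ba) rho_poly rho_ba + C_kba rho_ba (1-kappa) rho_cross`.
#' This is the quantity the microscope "sees": brighter areas in the
#' time-lapse correspond to more ongoing gelling reaction, so the travelling
#' front is the ring where this production peaks.
#'
#' @param state a `field_state` (see [sim_state()]).
#' @param p model parameters.
#' @return Nonnegative per-node production rates.
#' @export
production_profile <- function(state, p) {
  stopifnot(inherits(state, "field_state"))
  .assert_params(p)
  rr <- reaction_rates(
    structure(list(rho_poly = state$rho_poly, rho_ba = state$rho_ba,
                   rho_cross = state$rho_cross, kappa = state$kappa),
              class = "local_state"), p)
  rr$rate_cross
}

#' Front radius of a single field state
#'
#' The front is the radius of maximum instantaneous cross-linking production
#' ([production_profile()]). Ties break to the outermost radius (the front
#' travels inward; the outer peak is the advancing interface). The peak
#' position is refined to sub-cell precision by a parabola through the peak
#' node and its neighbours (supporting nonuniform grids), so the reported
#' radius varies smoothly in time instead of jumping cell by cell — this
#' matters when trajectories feed a least-squares calibration. The front is
#' reported as not found (`NA`) when the peak production does not exceed
#' `min_peak` — callers tracking a whole run pass 1 % of the recent
#' historical peak so that a dissipated front is not chased into noise.
#'
#' @param state a `field_state`.
#' @param p model parameters.
#' @param min_peak detection floor for the production peak (default 0: any
#'   strictly positive production counts).
#' @return List with `radius` (mm, or `NA_real_` if not found) and `peak`
#'   (the peak production value).
#' @export
extract_front_radius <- function(state, p, min_peak = 0) {
  prod <- production_profile(state, p)
  peak <- max(prod)
  if (peak <= 0 || peak < min_peak) {
    return(list(radius = NA_real_, peak = peak))
  }
  i <- max(which(prod == peak))
  radius <- state$r[i]
  if (i > 1 && i < length(prod)) {
    # quadratic through the three points around the peak (nonuniform grid)
    x <- state$r[(i - 1):(i + 1)] - state$r[i]
    y <- prod[(i - 1):(i + 1)]
    a <- (x[3] * (y[1] - y[2]) + x[1] * (y[2] - y[3])) / (x[1] * x[3] * (x[1] - x[3]))
    b <- (x[3]^2 * (y[1] - y[2]) + x[1]^2 * (y[2] - y[3])) /
      (x[1] * x[3] * (x[3] - x[1]))
    if (is.finite(a) && a < 0) {
      vert <- -b / (2 * a)
      # trust the refinement only within the bracketing cells
      if (vert > x[1] && vert < x[3]) radius <- state$r[i] + vert
    }
  }
  list(radius = radius, peak = peak)
}

#' Front trajectory container
#'
#' @param times times, s (strictly increasing).
#' @param radius_mm front radius per time, mm; `NA` where not detected.
#' @param R0 initial domain radius, mm (defaults to the first finite radius).
#' @param source free-text provenance label.
#' @return Object of class `front_trajectory` with `gelation_time_s` set to
#'   the first time the front is missing or has shrunk below 2 % of `R0`
#'   (`NA` plus a `reason` if that never happens).
#' @export
front_trajectory <- function(times, radius_mm, R0 = NULL, source = "unknown") {
  stopifnot(length(times) == length(radius_mm), !is.unsorted(times))
  if (is.null(R0)) {
    fin <- radius_mm[is.finite(radius_mm)]
    if (!length(fin)) stop("trajectory has no detected front at all")
    R0 <- fin[1]
  }
  # gelled when the front radius falls within 2 % of R0, or when detection
  # fails persistently (>= 2 consecutive misses, or a miss on the final
  # state). A single isolated miss is detector noise, not completion.
  small_idx <- which(is.finite(radius_mm) & radius_mm <= 0.02 * R0)
  miss <- !is.finite(radius_mm)
  miss_idx <- integer(0)
  if (any(miss)) {
    runs <- rle(miss)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    persistent <- runs$values & (runs$lengths >= 2 | ends == length(miss))
    miss_idx <- starts[persistent]
  }
  gel_idx <- c(small_idx, miss_idx)
  gel_idx <- gel_idx[gel_idx > 1]   # ignore a missing front at t = 0
  gelation_time <- if (length(gel_idx)) times[min(gel_idx)] else NA_real_
  reason <- if (is.na(gelation_time)) "front persisted to the last state" else NULL
  radius_out <- radius_mm
  if (!is.na(gelation_time)) {
    radius_out[times > gelation_time] <- NA_real_
  }
  structure(list(times = times, radius_mm = radius_out, R0 = R0,
                 gelation_time_s = gelation_time, reason = reason,
                 source = source),
            class = "front_trajectory")
}

#' @export
print.front_trajectory <- function(x, ...) {
  cat(sprintf("front_trajectory (%s): %d points, R0 = %.4g mm, ", x$source,
              length(x$times), x$R0))
  if (is.na(x$gelation_time_s)) {
    cat("gelation not reached (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("gelation at %g s\n", x$gelation_time_s))
  }
  invisible(x)
}

#' Build a front trajectory from a simulation
#'
#' Applies [extract_front_radius()] to every stored state and derives the
#' total gelation time (first state with no front or with the front within
#' 2 % of the initial radius).
#'
#' The front counts as dissipated when its production peak falls below 1 %
#' of the recent historical maximum — the maximum over the trailing
#' `window` detected states, excluding the t = 0 state. The t = 0 state is
#' excluded because the instant the bath touches the rim the production
#' spikes to its global maximum (full polymer meeting full bath
#' concentration), hundreds of times the quasi-steady front production;
#' referencing that spike would declare the front dead while it is still
#' travelling. Against the trailing window the peak decays by far less than
#' 100x during propagation, while at completion it collapses by orders of
#' magnitude within a few frames, so the rule fires exactly once.
#'
#' @param sim a `gel_sim` with at least 5 stored states.
#' @param p model parameters (defaults to those of the run).
#' @param window trailing window (number of states) for the dissipation
#'   reference (default 20).
#' @return A [front_trajectory()].
#' @export
build_front_trajectory <- function(sim, p = NULL, window = 20) {
  stopifnot(inherits(sim, "gel_sim"))
  p <- p %||% sim$params
  nt <- length(sim$times)
  if (nt < 5) stop("need at least 5 states to build a trajectory")
  radius <- rep(NA_real_, nt)
  peaks <- numeric(0)              # trailing detected peaks (post-IC states)
  for (i in seq_len(nt)) {
    st <- sim_state(sim, i)
    ref <- if (length(peaks)) max(utils::tail(peaks, window)) else 0
    fr <- extract_front_radius(st, p, min_peak = 0.01 * ref)
    if (i > 1 && is.finite(fr$radius)) peaks <- c(peaks, fr$peak)
    radius[i] <- fr$radius
  }
  front_trajectory(sim$times, radius, R0 = sim$grid$R,
                   source = sim$scenario$label)
}

#' Two-phase piecewise-linear fit of a front trajectory
#'
#' The observed front kinetics show two regimes: an initial fast, nearly
#' linear shrinkage followed by a slower but still linear phase. This fits a
#' continuous single-breakpoint piecewise-linear model
#' `r(t) = b0 + v_early * t + (v_late - v_early) * max(t - tb, 0)` by
#' ordinary least squares, scanning every interior observed time as the
#' candidate breakpoint and keeping the minimum-SSE fit (deterministic
#' exhaustive search).
#'
#' As the front converges on the core it accelerates sharply (geometric
#' focusing plus front dissipation — a terminal artifact, not one of the two
#' kinetic phases), so points with radius below `core_cutoff * R0` are
#' excluded from the fit; otherwise the single breakpoint can lock onto the
#' terminal dive instead of the early/late transition.
#'
#' @param traj a [front_trajectory()].
#' @param min_points minimum detected points required (default 8).
#' @param core_cutoff fraction of `R0` below which points are excluded from
#'   the fit (default 0.1).
#' @return List with `breakpoint_s`, `v_early`, `v_late` (mm/s, negative for
#'   a shrinking front), `sse`, and `flag`: `"ok"`, `"unidentifiable"` (a
#'   single line fits as well as two; slopes then agree) or `"degenerate"`
#'   (constant trajectory; zero slopes, with a warning).
#' @export
segment_and_fit_velocities <- function(traj, min_points = 8,
                                       core_cutoff = 0.1) {
  stopifnot(inherits(traj, "front_trajectory"))
  keep <- is.finite(traj$radius_mm) &
    traj$radius_mm >= core_cutoff * traj$R0
  t <- traj$times[keep]
  r <- traj$radius_mm[keep]
  n <- length(t)
  if (n < min_points) {
    stop("need at least ", min_points, " detected front points, got ", n)
  }
  if (stats::sd(r) == 0) {
    warning("constant front trajectory; slopes set to zero")
    return(list(breakpoint_s = NA_real_, v_early = 0, v_late = 0,
                sse = 0, flag = "degenerate"))
  }
  lin <- stats::lm.fit(cbind(1, t), r)
  sse_lin <- sum(lin$residuals^2)
  best <- list(sse = Inf)
  for (j in 3:(n - 2)) {            # >= 2 interior points on each side
    tb <- t[j]
    X <- cbind(1, t, pmax(t - tb, 0))
    fit <- stats::lm.fit(X, r)
    sse <- sum(fit$residuals^2)
    if (sse < best$sse) {
      best <- list(sse = sse, tb = tb, beta = fit$coefficients)
    }
  }
  v_early <- unname(best$beta[2])
  v_late <- unname(best$beta[2] + best$beta[3])
  flag <- "ok"
  # a single line explaining the data as well as two => breakpoint meaningless
  if (sse_lin <= best$sse * (1 + 1e-6) + 1e-12) {
    flag <- "unidentifiable"
    v_early <- v_late <- unname(lin$coefficients[2])
    best$tb <- NA_real_
  }
  list(breakpoint_s = best$tb, v_early = v_early, v_late = v_late,
       sse = best$sse, flag = flag)
}

#' Summarise a run: gelation time and two-phase velocities
#'
#' @param traj a [front_trajectory()].
#' @return List combining the trajectory's gelation time with the
#'   [segment_and_fit_velocities()] fit.
#' @export
front_summary <- function(traj) {
  fit <- segment_and_fit_velocities(traj)
  list(gelation_time_s = traj$gelation_time_s,
       reason = traj$reason,
       breakpoint_s = fit$breakpoint_s,
       v_early_mm_per_s = fit$v_early,
       v_late_mm_per_s = fit$v_late,
       fit_flag = fit$flag,
       R0_mm = traj$R0)
}
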