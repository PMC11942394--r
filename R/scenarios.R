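#' Disc gelation scenario
#'
#' Builds the thin-disc setup used for the time-lapse gelation experiments:
#' a small droplet of alginate sol squeezed under a spacer of fixed height
#' forms a disc; the cross-linker bath floods the chamber and barium diffuses
#' in radially. The disc radius follows from the droplet volume and chamber
#' height, `R0 = sqrt(V / (pi h))`; with the default 4 uL and 200 um this is
#' 2.523 mm. The vertical dimension is ignored (thin-film assumption: the
#' front is observed in-plane), so the symmetry exponent is 1.
#'
#' The bath is treated as an unlimited reservoir: barium is held at the bath
#' concentration at the outer rim for the whole run (Dirichlet), while
#' polymer cannot leave (zero flux; the gelled rim traps it). Initially the
#' body holds polymer at its reference density with no barium, no cross-links
#' and zero occupancy.
#'
#' @param bath_mM bath BaCl2 concentration in mM (experiments: 10, 20, 40).
#' @param p model parameters (accepted for interface symmetry; scenarios are
#'   parameter-free).
#' @param volume_uL droplet volume (default 4 uL = 4 mm^3).
#' @param height_um chamber height (default 200 um).
#' @param n_nodes grid nodes (default 600, graded toward the rim).
#' @param refinement `"graded"` or `"uniform"` (see [radial_grid()]).
#' @param horizon simulated time span, s.
#' @param cadence output interval, s.
#' @param label optional run label.
#' @return Object of class `gel_scenario`.
#' @examples
#' sc <- make_disc_scenario(40)
#' sc$R0   # 2.523 mm
#' @export
make_disc_scenario <- function(bath_mM, p = model_parameters(),
                               volume_uL = 4, height_um = 200,
                               n_nodes = 600,
                               refinement = c("graded", "uniform"),
                               horizon = 4e5, cadence = 120,
                               label = NULL) {
  refinement <- match.arg(refinement)
  if (!is.numeric(bath_mM) || bath_mM <= 0) stop("bath_mM must be positive")
  if (volume_uL <= 0) stop("volume_uL must be positive")
  if (height_um <= 0) stop("height_um must be positive")
  h_mm <- to_model_units(height_um, "um")
  R0 <- sqrt(volume_uL / (pi * h_mm))     # 1 uL = 1 mm^3
  grid <- radial_grid(R0, n_nodes, m = 1, refinement = refinement)
  .new_scenario(grid, bath_mM, horizon, cadence,
                label %||% sprintf("disc_%gmM", bath_mM),
                geometry = "disc")
}

#' Sphere gelation scenario
#'
#' A droplet of alginate pipetted into the cross-linker bath gels as a
#' free-floating sphere; barium diffuses in from the whole surface
#' (symmetry exponent 2). Observed sphere diameters span roughly
#' 1.1-1.9 mm depending on bath concentration.
#'
#' @param diameter_um sphere diameter in um, sanity-bounded to \[500, 3000\].
#' @inheritParams make_disc_scenario
#' @return Object of class `gel_scenario`.
#' @examples
#' make_sphere_scenario(1705, 10)$R0  # 0.8525 mm
#' @export
make_sphere_scenario <- function(diameter_um, bath_mM, p = model_parameters(),
                                 n_nodes = 600,
                                 refinement = c("graded", "uniform"),
                                 horizon = 1.2e5, cadence = 60,
                                 label = NULL) {
  refinement <- match.arg(refinement)
  if (!is.numeric(diameter_um) || diameter_um < 500 || diameter_um > 3000) {
    stop("diameter_um must lie in [500, 3000] um")
  }
  if (!is.numeric(bath_mM) || bath_mM <= 0) stop("bath_mM must be positive")
  R0 <- to_model_units(diameter_um, "um") / 2
  grid <- radial_grid(R0, n_nodes, m = 2, refinement = refinement)
  .new_scenario(grid, bath_mM, horizon, cadence,
                label %||% sprintf("sphere_%gum_%gmM", diameter_um, bath_mM),
                geometry = "sphere")
}

#' Slab (planar) gelation scenario
#'
#' A planar layer of alginate sol of given thickness with the bath on one
#' face (symmetry exponent 0, Dirichlet barium at `x = L`, zero flux at
#' `x = 0`). Not an experimental geometry here, but the configuration in
#' which the transport discretisation can be checked against the classical
#' semi-infinite-slab closed form ([analytic_slab_diffusion()]).
#'
#' @param thickness_mm slab thickness, mm.
#' @inheritParams make_disc_scenario
#' @return Object of class `gel_scenario`.
#' @export
make_slab_scenario <- function(thickness_mm, bath_mM, p = model_parameters(),
                               n_nodes = 600,
                               refinement = c("graded", "uniform"),
                               horizon = 600, cadence = 5,
                               label = NULL) {
  refinement <- match.arg(refinement)
  if (!is.numeric(thickness_mm) || thickness_mm <= 0) {
    stop("thickness_mm must be positive")
  }
  if (!is.numeric(bath_mM) || bath_mM <= 0) stop("bath_mM must be positive")
  grid <- radial_grid(thickness_mm, n_nodes, m = 0, refinement = refinement)
  .new_scenario(grid, bath_mM, horizon, cadence,
                label %||% sprintf("slab_%gmM", bath_mM),
                geometry = "slab")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.new_scenario <- function(grid, bath_mM, horizon, cadence, label, geometry) {
  if (horizon <= 0 || cadence <= 0 || cadence > horizon) {
    stop("need 0 < cadence <= horizon")
  }
  n <- length(grid$r)
  bath_ba <- to_model_units(bath_mM, "mM")
  init <- list(
    rho_poly = rep(1, n),                      # sol at reference density
    rho_ba = c(rep(0, n - 1), bath_ba),        # bath value at the rim only
    rho_cross = rep(0, n),
    kappa = rep(0, n)
  )
  sc <- structure(
    list(grid = grid, R0 = grid$R, geometry = geometry,
         bath_mM = bath_mM, bath_ba = bath_ba, init = init,
         horizon = horizon, cadence = cadence, label = label),
    class = "gel_scenario")
  validate_scenario(sc)
  sc
}

#' @export
print.gel_scenario <- function(x, ...) {
  cat(sprintf("gel_scenario '%s': %s, R0 = %.4g mm, bath %g mM (%.3g model units)\n",
              x$label, x$geometry, x$R0, x$bath_mM, x$bath_ba))
  cat(sprintf("  horizon %g s, output every %g s, %d nodes\n",
              x$horizon, x$cadence, length(x$grid$r)))
  invisible(x)
}

#' Validate a scenario's initial state and geometry
#'
#' @param sc a `gel_scenario`.
#' @return The scenario, invisibly; stops on violation.
#' @export
validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "gel_scenario"))
  n <- length(sc$grid$r)
  init <- sc$init
  if (!all(lengths(init) == n)) stop("initial fields must match the grid")
  validate_local_state(structure(init, class = "local_state"))
  if (any(init$kappa != 0) || any(init$rho_cross != 0)) {
    stop("initial kappa and rho_cross must be zero everywhere")
  }
  if (any(init$rho_ba[-n] != 0)) {
    stop("initial rho_ba must be zero inside the body")
  }
  invisible(sc)
}
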