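#' Model parameters of the gelation kinetics
#'
#' Bundles the eight constants of the barium-alginate cross-linking model:
#' base diffusivities of free polymer and free barium, the exponential
#' hindrance coefficients that shrink those diffusivities as cross-link
#' density builds up, and the four reaction-rate coefficients (primary
#' polymer attachment, barium consumption by primary attachment, secondary
#' ion absorption into the existing network, and the evolution of the binding
#' occupancy fraction).
#'
#' Defaults are the published best-fit values for ultra-high-viscosity
#' alginate discs gelled in 10-40 mM BaCl2 baths. Diffusivities are supplied
#' in m^2/s and stored internally in mm^2/s (model units); the dimensionless
#' rate/hindrance constants act on model-unit densities (see [unit_system()]).
#'
#' @param D0_poly base free-polymer diffusivity, m^2/s.
#' @param D0_ba base free-barium diffusivity, m^2/s. Ions are much smaller
#'   than polymer chains, so `D0_ba` must exceed `D0_poly` by at least a
#'   factor of 10 (the physical separation is ~3 orders of magnitude).
#' @param K_poly,K_ba hindrance exponents: D = D0 * exp(-K * rho_cross),
#'   per unit cross-link density (model units).
#' @param C_poly primary attachment rate coefficient (1/(barium density * s)).
#' @param C_ba barium consumption coefficient for primary attachment.
#' @param C_kba secondary ion-absorption coefficient.
#' @param C_k occupancy evolution coefficient. `C_kba` and `C_k` share the
#'   published default value but are independent parameters.
#' @return Object of class `gel_params`: named list with `D0_poly`, `D0_ba`
#'   in mm^2/s, the six rate/hindrance constants, and the physical
#'   diffusivities as attributes.
#' @examples
#' p <- model_parameters()
#' p$D0_ba            # 6.78e-3 mm^2/s
#' reaction_rates(local_state(1, 1, 0.5, 0.2), p)
#' @export
model_parameters <- function(D0_poly = 6.78e-12,
                             D0_ba = 6.78e-9,
                             K_poly = 2.5,
                             K_ba = 2.3,
                             C_poly = 1.6e-1,
                             C_ba = 8.0e-2,
                             C_kba = 2.5e-2,
                             C_k = 2.5e-2) {
  vals <- c(D0_poly = D0_poly, D0_ba = D0_ba, K_poly = K_poly, K_ba = K_ba,
            C_poly = C_poly, C_ba = C_ba, C_kba = C_kba, C_k = C_k)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad)) {
    stop("model parameters must be strictly positive and finite; offending: ",
         paste(bad, collapse = ", "))
  }
  if (D0_ba / D0_poly < 10) {
    stop("D0_ba must be at least 10x D0_poly (ion diffusivity far exceeds ",
         "polymer diffusivity); got ratio ", format(D0_ba / D0_poly))
  }
  p <- list(
    D0_poly = to_model_units(D0_poly, "m2_per_s"),
    D0_ba = to_model_units(D0_ba, "m2_per_s"),
    K_poly = K_poly, K_ba = K_ba,
    C_poly = C_poly, C_ba = C_ba, C_kba = C_kba, C_k = C_k
  )
  attr(p, "D0_poly_m2s") <- D0_poly
  attr(p, "D0_ba_m2s") <- D0_ba
  class(p) <- "gel_params"
  p
}

#' @export
print.gel_params <- function(x, ...) {
  cat("Gelation model parameters (model units: mm, s, reference densities):\n")
  cat(sprintf("  D0_poly %.4g mm^2/s (%.4g m^2/s)   D0_ba %.4g mm^2/s (%.4g m^2/s)\n",
              x$D0_poly, attr(x, "D0_poly_m2s"), x$D0_ba, attr(x, "D0_ba_m2s")))
  cat(sprintf("  K_poly %.4g  K_ba %.4g\n", x$K_poly, x$K_ba))
  cat(sprintf("  C_poly %.4g  C_ba %.4g  C_kba %.4g  C_k %.4g\n",
              x$C_poly, x$C_ba, x$C_kba, x$C_k))
  invisible(x)
}

#' Modify a parameter set
#'
#' @param p a `gel_params` object.
#' @param ... named replacements among the eight parameter names; `D0_poly`
#'   and `D0_ba` are interpreted in m^2/s as in [model_parameters()].
#' @return A validated `gel_params`.
#' @export
update_parameters <- function(p, ...) {
  stopifnot(inherits(p, "gel_params"))
  repl <- list(...)
  if (!length(repl)) return(p)
  known <- c("D0_poly", "D0_ba", "K_poly", "K_ba",
             "C_poly", "C_ba", "C_kba", "C_k")
  unknown <- setdiff(names(repl), known)
  if (length(unknown) || is.null(names(repl)) || any(names(repl) == "")) {
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  }
  args <- list(D0_poly = attr(p, "D0_poly_m2s"), D0_ba = attr(p, "D0_ba_m2s"),
               K_poly = p$K_poly, K_ba = p$K_ba, C_poly = p$C_poly,
               C_ba = p$C_ba, C_kba = p$C_kba, C_k = p$C_k)
  args[names(repl)] <- repl
  do.call(model_parameters, args)
}

.assert_params <- function(p) {
  if (!inherits(p, "gel_params")) stop("'p' must be a gel_params object")
  invisible(p)
}
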