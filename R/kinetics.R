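#' Local chemical state of the gelling mixture
#'
#' A pointwise snapshot of the four state variables: free-polymer density,
#' free-barium density, cross-linked-polymer density (all nonnegative, model
#' units) and the binding occupancy fraction kappa in \[0, 1\], the ratio of
#' occupied to possible cation-binding positions in the network. All four
#' arguments may be equal-length vectors (per-node states).
#'
#' @param rho_poly,rho_ba,rho_cross nonnegative densities.
#' @param kappa occupancy fraction in \[0, 1\].
#' @return Object of class `local_state`.
#' @export
local_state <- function(rho_poly, rho_ba, rho_cross, kappa) {
  s <- list(rho_poly = as.numeric(rho_poly), rho_ba = as.numeric(rho_ba),
            rho_cross = as.numeric(rho_cross), kappa = as.numeric(kappa))
  n <- lengths(s)
  if (length(unique(n)) != 1L) stop("state components must have equal length")
  class(s) <- "local_state"
  validate_local_state(s)
  s
}

#' @rdname local_state
#' @param s a `local_state`.
#' @param tol negative values above `-tol` are tolerated (solver round-off).
#' @export
validate_local_state <- function(s, tol = 0) {
  for (f in c("rho_poly", "rho_ba", "rho_cross")) {
    v <- s[[f]]
    if (any(!is.finite(v))) stop("non-finite value in field '", f, "'")
    if (any(v < -tol)) stop("negative density in field '", f, "': min ",
                            format(min(v)))
  }
  k <- s$kappa
  if (any(!is.finite(k))) stop("non-finite value in field 'kappa'")
  if (any(k < -tol) || any(k > 1 + tol)) {
    stop("field 'kappa' outside [0, 1]: range ",
         format(min(k)), " .. ", format(max(k)))
  }
  invisible(s)
}

#' Pointwise reaction source terms of the cross-linking kinetics
#'
#' Evaluates the mass-exchange terms of the four-field gelation model:
#' \deqn{\dot\rho_{poly}  = -C_{poly}\,\rho_{poly}\rho_{ba}}
#' \deqn{\dot\rho_{ba}    = -C_{ba}\,\rho_{poly}\rho_{ba}
#'       - C_{\kappa ba}\,\rho_{ba}(1-\kappa)\rho_{cross}}
#' \deqn{\dot\rho_{cross} = (C_{poly}+C_{ba})\,\rho_{poly}\rho_{ba}
#'       + C_{\kappa ba}\,\rho_{ba}(1-\kappa)\rho_{cross}}
#' \deqn{\dot\kappa       = C_{\kappa}\,\rho_{ba}(1-\kappa)\rho_{cross}}
#'
#' The first term is the primary attachment of a free polymer chain to the
#' network (consuming one barium per attachment event at rate `C_ba`); the
#' second is secondary absorption of further ions onto free binding sites of
#' chains already in the network, `(1-kappa)*rho_cross` measuring free sites.
#' By construction the first three rates sum to zero exactly: cross-linked
#' mass grows by precisely what the free phases lose.
#'
#' @param s a [local_state()] (vector components allowed).
#' @param p a [model_parameters()].
#' @return List with components `rate_poly`, `rate_ba`, `rate_cross`,
#'   `rate_kappa` (model units per second).
#' @examples
#' p <- model_parameters()
#' reaction_rates(local_state(1, 1, 0.5, 0.2), p)
#' @export
reaction_rates <- function(s, p) {
  .assert_params(p)
  if (!inherits(s, "local_state")) stop("'s' must be a local_state")
  validate_local_state(s)
  pb <- s$rho_poly * s$rho_ba
  sec <- s$rho_ba * (1 - s$kappa) * s$rho_cross
  list(
    rate_poly = -p$C_poly * pb,
    rate_ba = -p$C_ba * pb - p$C_kba * sec,
    rate_cross = (p$C_poly + p$C_ba) * pb + p$C_kba * sec,
    rate_kappa = p$C_k * sec
  )
}

#' Cross-link-hindered effective diffusivity
#'
#' As the network tightens, the mesh size shrinks and transport of both free
#' polymer and barium ions slows down exponentially:
#' \deqn{D = D_0 \exp(-K\,\rho_{cross}).}
#'
#' @param rho_cross cross-linked polymer density (nonnegative, model units).
#' @param D0 base diffusivity at zero cross-link density.
#' @param K hindrance exponent (per unit cross-link density).
#' @return Diffusivity, same units as `D0`; in (0, D0], strictly decreasing
#'   in `rho_cross`.
#' @examples
#' effective_diffusivity(1, D0 = 6.78e-9, K = 2.3)  # ~6.8e-10
#' @export
effective_diffusivity <- function(rho_cross, D0, K) {
  if (any(!is.finite(rho_cross)) || any(rho_cross < 0)) {
    stop("rho_cross must be finite and nonnegative")
  }
  if (any(D0 <= 0)) stop("D0 must be positive")
  if (any(K < 0)) stop("K must be nonnegative")
  D0 * exp(-K * rho_cross)
}
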