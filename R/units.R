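#' Model unit conventions
#'
#' The simulator works in nondimensionalised "model units" chosen so that the
#' rate and hindrance constants of the kinetic system act on O(1) densities:
#'
#' * length: millimetre; time: second;
#' * free-barium density: referenced to a 10 mM BaCl2 bath, so baths of
#'   10/20/40 mM map to boundary values 1.0/2.0/4.0;
#' * free-polymer density: referenced to the initial alginate sol
#'   (1:1 mixture of 0.65 % w/v solutions), which maps to 1.0;
#' * cross-linked polymer density: expressed in the same polymer reference
#'   units (it accumulates mass from both polymer and barium).
#'
#' Diffusivities quoted in m^2/s convert to mm^2/s (factor 1e6).
#'
#' @return An object of class `unit_system`: a list with the reference
#'   quantities `ba_ref_mM`, `poly_ref_wv`, `length_unit`, `time_unit`.
#' @examples
#' us <- unit_system()
#' to_model_units(20, "mM")          # 2.0
#' to_model_units(0.65, "percent_wv") # 1.0
#' @export
unit_system <- function() {
  structure(
    list(ba_ref_mM = 10, poly_ref_wv = 0.65,
         length_unit = "mm", time_unit = "s"),
    class = "unit_system"
  )
}

.unit_factors <- function(us = unit_system()) {
  c(mM = 1 / us$ba_ref_mM,
    percent_wv = 1 / us$poly_ref_wv,
    mm = 1,
    um = 1e-3,
    m2_per_s = 1e6,   # -> mm^2/s
    s = 1,
    min = 60)
}

#' Convert physical quantities to model units (and back)
#'
#' Linear, invertible mappings per [unit_system()]. `"%w/v"` is accepted as an
#' alias for `"percent_wv"`, `"µm"` for `"um"`.
#'
#' @param value numeric vector in physical units.
#' @param unit one of `"mM"`, `"percent_wv"` (`"%w/v"`), `"mm"`, `"um"`
#'   (`"µm"`), `"m2_per_s"`, `"s"`, `"min"`.
#' @param us a [unit_system()].
#' @return numeric vector in model units (resp. physical units).
#' @export
to_model_units <- function(value, unit, us = unit_system()) {
  f <- .unit_factors(us)
  unit <- .canon_unit(unit)
  if (!unit %in% names(f)) {
    stop("unknown unit: '", unit, "' (known: ", paste(names(f), collapse = ", "), ")")
  }
  value * f[[unit]]
}

#' @rdname to_model_units
#' @export
from_model_units <- function(value, unit, us = unit_system()) {
  f <- .unit_factors(us)
  unit <- .canon_unit(unit)
  if (!unit %in% names(f)) {
    stop("unknown unit: '", unit, "' (known: ", paste(names(f), collapse = ", "), ")")
  }
  value / f[[unit]]
}

.canon_unit <- function(unit) {
  stopifnot(is.character(unit), length(unit) == 1)
  switch(unit,
         "%w/v" = "percent_wv",
         "µm" = "um",
         "m^2/s" = "m2_per_s",
         unit)
}

#' @export
print.unit_system <- function(x, ...) {
  cat("Model unit system: length mm, time s;",
      sprintf("barium ref %g mM -> 1.0;", x$ba_ref_mM),
      sprintf("polymer ref %g %%w/v -> 1.0\n", x$poly_ref_wv))
  invisible(x)
}
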