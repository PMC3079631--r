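#' Oocyte geometry from the apparent diameter
#'
#' Builds the spherical geometry used by all permeability calculations.
#' The oocyte is treated as a sphere of the measured (apparent) diameter;
#' the effective membrane area `S` multiplies the apparent sphere area by
#' the folding factor to account for plasma-membrane microvilli.
#'
#' @param apparent_diameter Apparent oocyte diameter, cm (a stage V/VI
#'   Xenopus oocyte is about 0.12 cm).
#' @param constants A [physical_constants()] object; supplies
#'   `area_fold_factor`.
#'
#' @return An object of class `oocyte_geometry` with fields
#'   `apparent_diameter` (cm), `V0` (initial volume, cm^3), `A_apparent`
#'   (sphere surface, cm^2) and `S` (folded membrane area, cm^2).
#' @examples
#' geom <- oocyte_geometry(0.12)
#' geom$V0          # ~9.05e-4 cm^3
#' geom$S / geom$A_apparent  # 9
#' @export
oocyte_geometry <- function(apparent_diameter,
                            constants = physical_constants()) {
  stopifnot(inherits(constants, "physical_constants"))
  if (!is.numeric(apparent_diameter) || length(apparent_diameter) != 1 ||
      !is.finite(apparent_diameter) || apparent_diameter <= 0)
    stop("apparent_diameter must be a single positive number (cm)")
  d <- apparent_diameter
  A <- pi * d^2
  structure(list(apparent_diameter = d,
                 V0 = pi / 6 * d^3,
                 A_apparent = A,
                 S = constants$area_fold_factor * A),
            class = "oocyte_geometry")
}

#' @export
print.oocyte_geometry <- function(x, ...) {
  cat(sprintf(
    "Oocyte geometry: d = %.4g cm, V0 = %.4g cm^3, A = %.4g cm^2, S = %.4g cm^2\n",
    x$apparent_diameter, x$V0, x$A_apparent, x$S))
  invisible(x)
}

# area used by the K-K flux equations; the folded area stays available for
# the slope-based Pf/Ps formulas where the 9x convention is standard
kk_area <- function(geom, area_basis = c("apparent", "folded")) {
  area_basis <- match.arg(area_basis)
  if (area_basis == "apparent") geom$A_apparent else geom$S
}
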