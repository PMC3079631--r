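#' Physical constants for oocyte transport calculations
#'
#' Bundles the constants used throughout the Kedem-Katchalsky model and the
#' slope-based permeability formulas. Defaults correspond to room-temperature
#' (20 degrees C) experiments with ethylene glycol as the permeant.
#'
#' @param Vw Partial molar volume of water, cm^3/mol.
#' @param vs_EG Partial molar volume of the permeant (ethylene glycol),
#'   cm^3/mol.
#' @param R Gas constant, cm^3.atm/(mol.K).
#' @param T Absolute temperature, K.
#' @param area_fold_factor Dimensionless factor by which membrane folding
#'   multiplies the apparent (sphere) surface area; applied in the Pf/Ps
#'   slope formulas.
#'
#' @return An object of class `physical_constants`.
#' @examples
#' physical_constants()
#' physical_constants(T = 298.15)
#' @export
physical_constants <- function(Vw = 18, vs_EG = 54, R = 82.3, T = 293.15,
                               area_fold_factor = 9) {
  vals <- c(Vw = Vw, vs_EG = vs_EG, R = R, T = T,
            area_fold_factor = area_fold_factor)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all physical constants must be finite and strictly positive")
  if (area_fold_factor < 1)
    stop("area_fold_factor must be >= 1")
  structure(list(Vw = Vw, vs_EG = vs_EG, R = R, T = T,
                 area_fold_factor = area_fold_factor),
            class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants:\n")
  cat(sprintf("  Vw   = %g cm^3/mol   vs_EG = %g cm^3/mol\n", x$Vw, x$vs_EG))
  cat(sprintf("  R    = %g cm^3.atm/(mol.K)   T = %g K  (RT = %g)\n",
              x$R, x$T, x$R * x$T))
  cat(sprintf("  area fold factor = %g\n", x$area_fold_factor))
  invisible(x)
}

# unit helpers: canonical internal units are cm, cm3, min, mol, atm
mosm_to_osm_cm3 <- function(mosm) mosm * 1e-6   # mOsm (mosmol/l) -> osmol/cm3
molar_to_mol_cm3 <- function(m) m * 1e-3        # mol/l -> mol/cm3
lp_um_to_cm <- function(lp_um) lp_um * 1e-4     # um/(min atm) -> cm/(min atm)
lp_cm_to_um <- function(lp_cm) lp_cm * 1e4
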