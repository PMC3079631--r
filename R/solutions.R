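#' Bath solution description
#'
#' Describes the extracellular medium as an impermeant osmolarity plus at
#' most one permeant solute. Solutions are treated as ideal: 1 mOsm
#' contributes 1e-6 osmol/cm^3 of osmotic driving force. Molarity/osmolarity
#' pairs quoted for real solutions (e.g. 0.9 M sucrose ~ 1450-1460 mOsm) are
#' taken as user-supplied values, never recomputed.
#'
#' @param osm_impermeant Osmolarity of all impermeant species, mOsm.
#' @param conc_permeant Permeant concentration, mol/l.
#' @param permeant_id One of `"none"`, `"ethylene_glycol"`, `"glycerol"`,
#'   `"propylene_glycol"`.
#' @param pH_label Optional label carried as metadata (the model itself is
#'   pH-agnostic; pH acts only through the fitted permeabilities).
#'
#' @return An object of class `bath_solution`.
#' @examples
#' bath_solution(1460)                              # 0.9 M sucrose in MBS
#' bath_solution(200, 1.3, "ethylene_glycol")       # 1.3 M EG + MBS
#' @export
bath_solution <- function(osm_impermeant, conc_permeant = 0,
                          permeant_id = c("none", "ethylene_glycol",
                                          "glycerol", "propylene_glycol"),
                          pH_label = NA_character_) {
  permeant_id <- match.arg(permeant_id)
  if (!is.numeric(osm_impermeant) || osm_impermeant < 0)
    stop("osm_impermeant must be >= 0 (mOsm)")
  if (!is.numeric(conc_permeant) || conc_permeant < 0)
    stop("conc_permeant must be >= 0 (mol/l)")
  if ((permeant_id == "none") != (conc_permeant == 0))
    stop("permeant_id = 'none' if and only if conc_permeant = 0")
  structure(list(osm_impermeant = osm_impermeant,
                 conc_permeant = conc_permeant,
                 permeant_id = permeant_id,
                 pH_label = pH_label),
            class = "bath_solution")
}

#' @export
print.bath_solution <- function(x, ...) {
  cat(sprintf("Bath: %g mOsm impermeant", x$osm_impermeant))
  if (x$permeant_id != "none")
    cat(sprintf(" + %g M %s", x$conc_permeant, x$permeant_id))
  if (!is.na(x$pH_label)) cat(sprintf(" (pH %s)", x$pH_label))
  cat("\n")
  invisible(x)
}
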