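#' Scintillation measurement of hypertonic cryoprotectant uptake
#'
#' Holds the counts and calibration constants of the hypertonic
#' radiolabeled-uptake assay: oocytes bathed in labeled cryoprotectant,
#' counted at time zero (externally bound background) and after exposure.
#'
#' @param cpm_t Counts per minute in the oocyte after exposure.
#' @param cpm_t0 Counts per minute at time zero.
#' @param cpm_per_ul Calibration: cpm per microlitre of labeled bath
#'   (default 73000).
#' @param bath_conc Bath cryoprotectant concentration, mol/l (default 1.3).
#' @param V_final Final oocyte volume, microlitres (computed upstream from
#'   the observed or simulated volume change under the hypertonic bath).
#' @return An object of class `uptake_measurement`.
#' @export
uptake_measurement <- function(cpm_t, cpm_t0, cpm_per_ul = 73000,
                               bath_conc = 1.3, V_final) {
  if (any(c(cpm_t, cpm_t0) < 0)) stop("cpm values must be >= 0")
  if (cpm_per_ul <= 0) stop("cpm_per_ul must be > 0")
  if (missing(V_final) || V_final <= 0)
    stop("V_final must be > 0 (microlitres)")
  structure(list(cpm_t = cpm_t, cpm_t0 = cpm_t0, cpm_per_ul = cpm_per_ul,
                 bath_conc = bath_conc, V_final = V_final),
            class = "uptake_measurement")
}

#' Intracellular cryoprotectant concentration from counts
#'
#' `conc = ((cpm_t - cpm_t0) / cpm_per_ul) * bath_conc / V_final`: net
#' counts over the bath calibration give the microlitres of bath solution
#' equivalent taken up; times the bath molarity this is micromoles of
#' solute, and divided by the final volume in microlitres it is mol/l.
#' Negative net counts (background exceeding signal) clamp to zero with a
#' warning.
#'
#' @param m An [uptake_measurement()].
#' @return Intracellular concentration, mol/l.
#' @examples
#' intracellular_concentration(
#'   uptake_measurement(cpm_t = 6050, cpm_t0 = 0, V_final = 0.98))  # ~0.11
#' @export
intracellular_concentration <- function(m) {
  stopifnot(inherits(m, "uptake_measurement"))
  net <- m$cpm_t - m$cpm_t0
  if (net < 0) {
    warning("net counts negative (background exceeds signal); clamping to 0")
    net <- 0
  }
  (net / m$cpm_per_ul) * m$bath_conc / m$V_final
}

#' Isotonic tracer-uptake assay specification
#'
#' @param hot_conc Labeled ("hot") solute concentration, micromolar.
#' @param total_conc Total (hot + cold) solute concentration, millimolar.
#' @param specific_activity Tracer specific activity, Ci/mmol.
#' @param incubation Incubation time, min.
#' @param counting_efficiency Fraction of disintegrations registered as
#'   counts (default 1, i.e. cpm taken as dpm).
#' @return An object of class `isotonic_uptake_spec`.
#' @export
isotonic_uptake_spec <- function(hot_conc = 5, total_conc = 1,
                                 specific_activity = 20, incubation = 1,
                                 counting_efficiency = 1) {
  vals <- c(hot_conc, total_conc, specific_activity, incubation,
            counting_efficiency)
  if (any(vals <= 0)) stop("all spec fields must be positive")
  if (total_conc * 1e3 < hot_conc)
    stop("total_conc (mM) must be >= hot_conc (uM)")
  structure(list(hot_conc = hot_conc, total_conc = total_conc,
                 specific_activity = specific_activity,
                 incubation = incubation,
                 counting_efficiency = counting_efficiency),
            class = "isotonic_uptake_spec")
}

#' Isotonic solute uptake rate from net counts
#'
#' Converts net cpm to total solute uptake: counts -> microcuries
#' (2.22e6 dpm/uCi, scaled by the counting efficiency) -> micromoles of hot
#' tracer (via the specific activity) -> total solute via the cold-dilution
#' factor `total_conc / hot_conc` -> rate over the incubation time.
#'
#' @param net_cpm Background-subtracted counts per minute per oocyte.
#' @param spec An [isotonic_uptake_spec()].
#' @return Uptake rate, pmol of total solute per oocyte per min.
#' @examples
#' isotonic_uptake_rate(44400, isotonic_uptake_spec())  # 200 pmol/min
#' @export
isotonic_uptake_rate <- function(net_cpm, spec = isotonic_uptake_spec()) {
  stopifnot(inherits(spec, "isotonic_uptake_spec"))
  if (net_cpm < 0) {
    warning("net counts negative; clamping to 0")
    net_cpm <- 0
  }
  uCi <- net_cpm / (spec$counting_efficiency * 2.22e6)
  hot_umol <- uCi * 1e-6 / spec$specific_activity * 1e3  # Ci/(Ci/mmol)->umol
  dilution <- spec$total_conc * 1e3 / spec$hot_conc      # mM -> uM ratio
  total_umol <- hot_umol * dilution
  total_umol / spec$incubation * 1e6                     # umol -> pmol
}

#' Model-predicted intracellular cryoprotectant concentration
#'
#' Bridges the K-K simulator and the uptake assay: simulates the hypertonic
#' protocol and returns `Ns(t)/V(t)` in mol/l, the same total-volume basis
#' as [intracellular_concentration()]. Note the asymptote: at long times
#' the free-water concentration reaches the bath concentration, but on the
#' total-volume basis the value plateaus near
#' `bath_conc * free-water fraction`, well below the bath concentration.
#'
#' @inheritParams kk_simulate
#' @param t Exposure time, min.
#' @return Predicted concentration at `t`, mol/l.
#' @export
predicted_concentration_from_kk <- function(params, geom, bath,
                                            vb_fraction = 0.75, t = 10,
                                            osm_iso = 200,
                                            constants = physical_constants(),
                                            area_basis = c("apparent",
                                                           "folded"),
                                            drag = TRUE) {
  area_basis <- match.arg(area_basis)
  tr <- kk_simulate(params, geom, bath, vb_fraction = vb_fraction,
                    osm_iso = osm_iso, times = c(0, t),
                    constants = constants, area_basis = area_basis,
                    drag = drag)
  n <- nrow(tr)
  tr$ns_mol[n] / tr$volume_cm3[n] * 1e3  # mol/cm3 -> mol/l
}
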