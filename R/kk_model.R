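#' Kedem-Katchalsky membrane parameter triple
#'
#' The three phenomenological coefficients of the Kedem-Katchalsky (K-K)
#' description of coupled water and solute transport across the oolemma.
#'
#' @param Lp Hydraulic conductivity, um/(min.atm) (the unit convention used
#'   for oocyte work; converted to cm/(min.atm) internally).
#' @param Ps Permeant solute permeability, cm/min.
#' @param sigma Reflection coefficient, dimensionless in `[0, 1]`; 1 means
#'   the solute is fully reflected (impermeant), 0 fully coupled to the
#'   volume flux.
#' @return An object of class `kk_parameters`.
#' @examples
#' kk_parameters(Lp = 2.64, Ps = 25.49e-3, sigma = 0.8)
#' @export
kk_parameters <- function(Lp, Ps = 0, sigma = 1) {
  if (!is.numeric(Lp) || Lp < 0) stop("Lp must be >= 0 (um/min/atm)")
  if (!is.numeric(Ps) || Ps < 0) stop("Ps must be >= 0 (cm/min)")
  if (!is.numeric(sigma) || sigma < 0 || sigma > 1)
    stop("sigma must lie in [0, 1]")
  structure(list(Lp = Lp, Ps = Ps, sigma = sigma), class = "kk_parameters")
}

#' @export
print.kk_parameters <- function(x, ...) {
  cat(sprintf("K-K parameters: Lp = %.4g um/(min.atm), Ps = %.4g cm/min, sigma = %.4g\n",
              x$Lp, x$Ps, x$sigma))
  invisible(x)
}

#' Instantaneous oocyte compartment state
#'
#' @param V Total oocyte volume, cm^3.
#' @param Ns Internal permeant amount, mol.
#' @param N_imp_osm Internal impermeant osmoles, osmol (conserved).
#' @param Vb Osmotically inactive volume, cm^3.
#' @param vs Partial molar volume of the permeant, cm^3/mol (used only to
#'   validate the free-water constraint).
#' @return An object of class `oocyte_state`.
#' @export
oocyte_state <- function(V, Ns = 0, N_imp_osm = 0, Vb = 0, vs = 54) {
  if (Ns < 0) stop("Ns must be >= 0")
  if (V - Vb - Ns * vs <= 0)
    stop("invalid state: free water volume V - Vb - Ns*vs must be > 0")
  structure(list(V = V, Ns = Ns, N_imp_osm = N_imp_osm, Vb = Vb),
            class = "oocyte_state")
}

# assemble the parameter list consumed by the C++ right-hand side
kk_pars_list <- function(params, geom, bath, N_imp_osm, Vb,
                         constants, area_basis, drag) {
  list(Lp = lp_um_to_cm(params$Lp), Ps = params$Ps, sigma = params$sigma,
       S = kk_area(geom, area_basis), Vb = Vb, Nimp = N_imp_osm,
       vs = constants$vs_EG, RT = constants$R * constants$T,
       osm_out = mosm_to_osm_cm3(bath$osm_impermeant),
       Cs_out = molar_to_mol_cm3(bath$conc_permeant),
       drag = isTRUE(drag))
}

#' Instantaneous Kedem-Katchalsky fluxes
#'
#' Reference (pure R) implementation of the model right-hand side. The
#' volume flux is
#' `Jv = Lp * RT * [(Cimp_in - Cimp_out) + sigma * (Cs_in - Cs_out)]`
#' (positive = influx) and the permeant flux
#' `dNs/dt = Ps * S * (Cs_out - Cs_in) + (1 - sigma) * Cbar * Jv * S`,
#' with internal concentrations on the free-water basis
#' (`Vfree = V - Vb - Ns*vs`) and `Cbar` the arithmetic mean of the internal
#' and external permeant concentrations. Setting `drag = FALSE` drops the
#' solvent-drag term (two-parameter form, for sensitivity checks).
#'
#' The compiled integrator used by [kk_simulate()] implements the same
#' equations; this function doubles as the independent oracle in the test
#' suite.
#'
#' @param state An [oocyte_state()].
#' @param bath A [bath_solution()].
#' @param params A [kk_parameters()].
#' @param geom An [oocyte_geometry()].
#' @param constants A [physical_constants()].
#' @param area_basis `"apparent"` (default, geometric sphere area) or
#'   `"folded"` (9x apparent).
#' @param drag Include the solvent-drag coupling term (default TRUE).
#' @return Named numeric vector `c(dV, dNs)` in cm^3/min and mol/min.
#' @examples
#' st <- oocyte_state(V = 9e-4, Vb = 6.75e-4, N_imp_osm = 4.5e-8)
#' kk_derivatives(st, bath_solution(1460), kk_parameters(2.57),
#'                oocyte_geometry(0.12))
#' @export
kk_derivatives <- function(state, bath, params, geom,
                           constants = physical_constants(),
                           area_basis = c("apparent", "folded"),
                           drag = TRUE) {
  area_basis <- match.arg(area_basis)
  p <- kk_pars_list(params, geom, bath, state$N_imp_osm, state$Vb,
                    constants, area_basis, drag)
  Ns <- max(state$Ns, 0)
  Vfree <- state$V - p$Vb - Ns * p$vs
  if (Vfree <= 0)
    stop("free water volume exhausted: V - Vb - Ns*vs <= 0")
  Cs_in <- Ns / Vfree
  Cimp_in <- p$Nimp / Vfree
  Jv <- p$Lp * (p$RT * (Cimp_in - p$osm_out) +
                p$sigma * p$RT * (Cs_in - p$Cs_out))
  dV <- Jv * p$S
  dNs <- p$Ps * p$S * (p$Cs_out - Cs_in)
  if (p$drag) dNs <- dNs + (1 - p$sigma) * 0.5 * (Cs_in + p$Cs_out) * Jv * p$S
  c(dV = dV, dNs = dNs)
}

#' Simulate an oocyte volume trajectory under a bath step change
#'
#' Integrates the K-K model from an isotonic resting state (`V = V0`, no
#' internal permeant, internal impermeant osmoles set so that the oocyte is
#' at equilibrium with `osm_iso`) after an instantaneous step to the given
#' bath. With an impermeant-only hypertonic bath the oocyte shrinks
#' monotonically to the Boyle-van't Hoff equilibrium; with a permeant
#' present it shrinks and then re-swells as the solute equilibrates.
#'
#' @inheritParams kk_derivatives
#' @param vb_fraction Osmotically inactive fraction of the initial volume
#'   (default 0.75 for Xenopus oocytes).
#' @param osm_iso Isotonic (resting) osmolarity, mOsm (default 200, MBS).
#' @param duration Simulated time, min.
#' @param sample_interval Output sampling interval, min (default 1/6 min =
#'   10 s, the standard hypertonic recording interval).
#' @param times Optional explicit sample times (min, increasing, starting
#'   at 0); overrides `duration`/`sample_interval`.
#' @param rtol,atol Solver relative/absolute tolerances.
#' @return A [volume_trajectory()] with per-sample internal permeant
#'   amounts.
#' @examples
#' geom <- oocyte_geometry(0.12)
#' tr <- kk_simulate(kk_parameters(2.57), geom, bath_solution(1460),
#'                   duration = 10)
#' min(tr$rel_volume)  # approaches 0.75 + 0.25 * 200/1460
#' @export
kk_simulate <- function(params, geom, bath, vb_fraction = 0.75,
                        osm_iso = 200, duration = 10,
                        sample_interval = 1 / 6, times = NULL,
                        constants = physical_constants(),
                        area_basis = c("apparent", "folded"),
                        drag = TRUE, rtol = 1e-8, atol = 1e-12) {
  area_basis <- match.arg(area_basis)
  stopifnot(inherits(params, "kk_parameters"),
            inherits(geom, "oocyte_geometry"),
            inherits(bath, "bath_solution"))
  if (vb_fraction < 0 || vb_fraction >= 1)
    stop("vb_fraction must lie in [0, 1)")
  if (is.null(times)) {
    if (duration <= 0 || sample_interval <= 0)
      stop("duration and sample_interval must be positive")
    times <- seq(0, duration, by = sample_interval)
  }
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing and start at 0")
  V0 <- geom$V0
  Vb <- vb_fraction * V0
  N_imp <- mosm_to_osm_cm3(osm_iso) * (V0 - Vb)
  p <- kk_pars_list(params, geom, bath, N_imp, Vb, constants,
                    area_basis, drag)
  y <- kk_integrate_cpp(times, V0, 0, p, rtol = rtol, atol = atol)
  volume_trajectory(times = times, rel_volumes = y[, 1] / V0, V0 = V0,
                    ns_mol = y[, 2],
                    meta = list(params = params, bath = bath,
                                vb_fraction = vb_fraction,
                                osm_iso = osm_iso, N_imp_osm = N_imp,
                                area_basis = area_basis, drag = drag))
}

#' Observed or simulated relative-volume time series
#'
#' @param times Sample times, min; strictly increasing, first entry 0.
#' @param rel_volumes Relative volumes V/V0; first entry 1 within 1e-6.
#' @param V0 Initial total volume, cm^3.
#' @param ns_mol Optional per-sample internal permeant amounts (simulator
#'   output).
#' @param meta Optional list of provenance metadata.
#' @return A data frame of class `volume_trajectory` with columns
#'   `time_min`, `rel_volume`, `volume_cm3` and (if supplied) `ns_mol`;
#'   `V0` is carried as an attribute.
#' @export
volume_trajectory <- function(times, rel_volumes, V0, ns_mol = NULL,
                              meta = NULL) {
  if (length(times) != length(rel_volumes))
    stop("times and rel_volumes must have equal length")
  if (length(times) < 1 || times[1] != 0)
    stop("trajectory must start at time 0")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (any(rel_volumes <= 0)) stop("all relative volumes must be > 0")
  if (abs(rel_volumes[1] - 1) > 1e-6)
    stop("rel_volumes[1] must equal 1 (relative-volume convention)")
  if (!is.numeric(V0) || V0 <= 0) stop("V0 must be positive (cm^3)")
  df <- data.frame(time_min = times, rel_volume = rel_volumes,
                   volume_cm3 = rel_volumes * V0)
  if (!is.null(ns_mol)) df$ns_mol <- ns_mol
  structure(df, V0 = V0, meta = meta,
            class = c("volume_trajectory", "data.frame"))
}

#' @export
print.volume_trajectory <- function(x, ...) {
  cat(sprintf("Volume trajectory: %d samples over %.3g min, V0 = %.4g cm^3\n",
              nrow(x), x$time_min[nrow(x)], attr(x, "V0")))
  cat(sprintf("  rel volume range [%.4f, %.4f]\n",
              min(x$rel_volume), max(x$rel_volume)))
  invisible(x)
}

#' Boyle-van't Hoff equilibrium volume
#'
#' Closed-form equilibrium relative volume of a two-compartment osmometer
#' with inactive fraction `vb_fraction` stepped from `osm_iso` into an
#' impermeant bath of `osm_hyper`:
#' `V_eq/V0 = vb + (1 - vb) * osm_iso / osm_hyper`. With vb = 0.75 the
#' oocyte can never lose more than 25% of its volume, its free water
#' content.
#'
#' @param vb_fraction Osmotically inactive fraction, in `[0, 1)`.
#' @param osm_iso Isotonic osmolarity, mOsm.
#' @param osm_hyper Bath osmolarity, mOsm (>= `osm_iso`).
#' @return Equilibrium V/V0.
#' @examples
#' bvh_equilibrium(0.75, 200, 1460)  # 0.7842
#' @export
bvh_equilibrium <- function(vb_fraction, osm_iso, osm_hyper) {
  if (!(osm_iso > 0) || osm_hyper < osm_iso)
    stop("require osm_hyper >= osm_iso > 0")
  if (vb_fraction < 0 || vb_fraction >= 1)
    stop("vb_fraction must lie in [0, 1)")
  vb_fraction + (1 - vb_fraction) * osm_iso / osm_hyper
}

#' Convert hydraulic conductivity to osmotic water permeability
#'
#' `Pf = Lp * R * T / Vw`, with Lp given in um/(min.atm) and Pf returned in
#' cm/min.
#'
#' @param Lp Hydraulic conductivity, um/(min.atm).
#' @param constants A [physical_constants()].
#' @return Pf in cm/min.
#' @examples
#' pf_from_lp(2.57)  # ~0.344 cm/min
#' @export
pf_from_lp <- function(Lp, constants = physical_constants()) {
  if (any(Lp < 0)) stop("Lp must be >= 0")
  lp_um_to_cm(Lp) * constants$R * constants$T / constants$Vw
}
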