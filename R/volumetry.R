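#' Time window for slope-based permeability estimation
#'
#' @param t_start,t_end Window bounds, min; `t_end > t_start >= 0`.
#' @return An object of class `slope_window`.
#' @export
slope_window <- function(t_start, t_end) {
  if (!(t_end > t_start) || t_start < 0)
    stop("require t_end > t_start >= 0")
  structure(list(t_start = t_start, t_end = t_end), class = "slope_window")
}

# OLS slope of rel_volume (or volume) vs time over a window; two-point mode
# is the oracle used in tests
window_slope <- function(traj, window, column = "rel_volume",
                         method = c("ols", "two_point")) {
  method <- match.arg(method)
  sel <- traj$time_min >= window$t_start - 1e-12 &
         traj$time_min <= window$t_end + 1e-12
  if (sum(sel) < 2)
    stop(sprintf("window [%g, %g] min contains fewer than 2 samples",
                 window$t_start, window$t_end))
  t <- traj$time_min[sel]
  v <- traj[[column]][sel]
  if (method == "two_point") {
    slope <- (v[length(v)] - v[1]) / (t[length(t)] - t[1])
    return(list(slope = slope, r_squared = NA_real_, n = length(t)))
  }
  fit <- lm(v ~ t)
  ssr <- sum(fit$residuals^2)
  sst <- sum((v - mean(v))^2)
  list(slope = unname(coef(fit)[2]),
       r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
       n = length(t))
}

permeability_result <- function(value, kind, window, slope, r_squared,
                                n_samples, units, solute_id = NA_character_) {
  structure(list(value = value, kind = kind, window = window, slope = slope,
                 r_squared = r_squared, n_samples = n_samples, units = units,
                 solute_id = solute_id),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("%s = %.4g %s  (slope %.4g /min, n = %d, R^2 = %.4f)\n",
              x$kind, x$value, x$units, x$slope, x$n_samples,
              if (is.na(x$r_squared)) NaN else x$r_squared))
  invisible(x)
}

#' Osmotic water permeability from an oocyte swelling trajectory
#'
#' `Pf = V0 * d(V/V0)/dt / (S * Vw * (Osm_in - Osm_out))`, the standard
#' initial-slope estimator for the hypotonic oocyte swelling assay. The
#' slope is an ordinary least-squares fit of relative volume against time
#' over the window (default: the first 20 s, recorded at 2-s intervals in
#' the assay this mirrors). Swelling under a hypotonic bath
#' (`osm_out < osm_in`) yields a positive Pf. The geometry's folded area
#' `S` (9x apparent) is used, the convention for this formula.
#'
#' @param traj A [volume_trajectory()].
#' @param geom An [oocyte_geometry()].
#' @param osm_in Internal (resting) osmolarity, mOsm.
#' @param osm_out Bath osmolarity, mOsm.
#' @param window A [slope_window()]; default `[0, 1/3]` min.
#' @param constants A [physical_constants()].
#' @param slope_method `"ols"` (default) or `"two_point"`.
#' @return A `permeability_result` with `value` in cm/min.
#' @export
compute_pf <- function(traj, geom, osm_in, osm_out,
                       window = slope_window(0, 1 / 3),
                       constants = physical_constants(),
                       slope_method = "ols") {
  if (osm_in == osm_out) stop("zero osmotic gradient: osm_in == osm_out")
  s <- window_slope(traj, window, "rel_volume", slope_method)
  d_osm <- mosm_to_osm_cm3(osm_in - osm_out)
  pf <- attr(traj, "V0") * s$slope / (geom$S * constants$Vw * d_osm)
  if (pf < 0)
    warning("negative Pf estimate: trajectory slope opposes the osmotic gradient")
  permeability_result(pf, "Pf", window, s$slope, s$r_squared, s$n,
                      "cm/min")
}

#' Cryoprotectant permeability from isotonic solute-substitution swelling
#'
#' `Ps = d(V/V0)/dt / (S/V0)`: the swelling-rate estimator used when an
#' impermeant fraction of the isotonic bath is replaced by the permeant
#' solute. Default window: the first minute (5-s sampling in the assay this
#' mirrors). Uses the folded area `S`.
#'
#' @inheritParams compute_pf
#' @param solute_id Optional permeant label carried into the result.
#' @return A `permeability_result` with `value` in cm/min (multiply by 1e3
#'   for the conventional x10^-3 cm/min reporting).
#' @export
compute_ps <- function(traj, geom, window = slope_window(0, 1),
                       solute_id = NA_character_, slope_method = "ols") {
  s <- window_slope(traj, window, "rel_volume", slope_method)
  ps <- s$slope / (geom$S / attr(traj, "V0"))
  permeability_result(ps, "Ps", window, s$slope, s$r_squared, s$n,
                      "cm/min", solute_id)
}

#' Linear (secant) hydraulic conductivity from hypertonic shrinkage
#'
#' Estimates Lp from the initial linear portion of an impermeant-bath
#' shrinkage curve: the OLS slope of absolute volume over `[0, t_cutoff]`
#' divided by the membrane area, RT and the initial osmotic gradient.
#' Because the true volume decay is convex, the secant slope underestimates
#' the tangent Lp more strongly the longer the cutoff: the 10-min estimate
#' is systematically below the 2-min one. The model-based refit
#' ([fit_kk()] restricted to the same window) is the bias-free alternative.
#'
#' @inheritParams compute_pf
#' @param bath A [bath_solution()]; must be impermeant-only.
#' @param t_cutoff Window end, min (2 and 10 are the conventional choices).
#' @param osm_iso Internal isotonic osmolarity, mOsm.
#' @param area_basis Membrane area entering the flux normalisation;
#'   `"apparent"` to match [kk_simulate()]'s default, `"folded"` for the
#'   9x convention.
#' @return A `permeability_result` with `value` in um/(min.atm).
#' @export
estimate_lp_linear <- function(traj, geom, bath, t_cutoff = 2,
                               osm_iso = 200,
                               constants = physical_constants(),
                               area_basis = c("apparent", "folded"),
                               slope_method = "ols") {
  area_basis <- match.arg(area_basis)
  if (bath$permeant_id != "none")
    stop("estimate_lp_linear requires an impermeant-only bath")
  if (t_cutoff > max(traj$time_min))
    stop("t_cutoff lies beyond the trajectory")
  s <- window_slope(traj, slope_window(0, t_cutoff), "volume_cm3",
                    slope_method)
  d_osm <- mosm_to_osm_cm3(bath$osm_impermeant - osm_iso)
  if (d_osm <= 0) stop("bath must be hypertonic relative to osm_iso")
  lp_cm <- -s$slope / (kk_area(geom, area_basis) *
                         constants$R * constants$T * d_osm)
  permeability_result(lp_cm_to_um(lp_cm), "Lp",
                      slope_window(0, t_cutoff), s$slope, s$r_squared, s$n,
                      "um/(min.atm)")
}

#' Summarise a batch of permeability results against a control group
#'
#' @param results Numeric vector or list of `permeability_result`s.
#' @param control_results Control group in the same form.
#' @return A list with per-group `mean`, `sem` (NA for n = 1) and `fold`
#'   change versus the control mean.
#' @examples
#' summarize_batch(c(2, 4, 6), c(1, 1, 1))
#' @export
summarize_batch <- function(results, control_results) {
  vals <- function(x) {
    if (is.list(x)) vapply(x, function(r) r$value, numeric(1))
    else as.numeric(x)
  }
  v <- vals(results); cv <- vals(control_results)
  if (length(v) == 0 || length(cv) == 0) stop("empty input")
  if (mean(cv) == 0) stop("zero control mean: fold change undefined")
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  list(n = length(v), mean = mean(v), sem = sem(v),
       control_n = length(cv), control_mean = mean(cv),
       control_sem = sem(cv), fold = mean(v) / mean(cv))
}
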