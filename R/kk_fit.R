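#' Specification of a Kedem-Katchalsky fit
#'
#' Controls which of (Lp, Ps, sigma) are estimated, their bounds and the
#' multistart grid. Internally the optimiser works on the scaled triple
#' (Lp in um/(min.atm), Ps in 1e-3 cm/min, sigma) so that all free
#' parameters are O(1)-O(100).
#'
#' @param free Character subset of `c("Lp", "Ps", "sigma")` to estimate.
#' @param fixed Named list of values for the non-free parameters (defaults:
#'   Ps = 0, sigma = 1 - the impermeant-bath convention).
#' @param lower,upper Named bounds on the natural scale (Lp um/(min.atm),
#'   Ps cm/min, sigma dimensionless).
#' @param starts Optional matrix of start points (columns Lp, Ps_mcm,
#'   sigma, on the scaled basis); defaults to a fixed 8-point grid, making
#'   the fit fully deterministic.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(free = c("Lp", "Ps", "sigma"),
                     fixed = list(),
                     lower = c(Lp = 0, Ps = 0, sigma = 0),
                     upper = c(Lp = 100, Ps = 1, sigma = 1),
                     starts = NULL) {
  if (length(free) == 0) stop("at least one free parameter is required")
  free <- match.arg(free, c("Lp", "Ps", "sigma"), several.ok = TRUE)
  defaults <- list(Lp = 1, Ps = 0, sigma = 1)
  fixed <- modifyList(defaults[setdiff(names(defaults), free)], fixed)
  if (any(names(fixed) %in% free))
    stop("a parameter cannot be both free and fixed")
  if (is.null(starts)) {
    # fixed Latin-style grid over (Lp um, Ps 1e-3 cm/min, sigma)
    starts <- rbind(c(1, 1, 0.5), c(5, 50, 0.7), c(0.5, 10, 0.9),
                    c(10, 100, 0.3), c(2, 5, 0.95), c(20, 300, 0.6),
                    c(0.1, 0.5, 0.8), c(50, 30, 0.2))
    colnames(starts) <- c("Lp", "Ps", "sigma")
  }
  structure(list(free = free, fixed = fixed, lower = lower, upper = upper,
                 starts = starts),
            class = "fit_spec")
}

# scaled basis: Lp as-is (um), Ps in 1e-3 cm/min, sigma as-is
to_scaled <- function(p) c(Lp = p[["Lp"]], Ps = p[["Ps"]] * 1e3,
                           sigma = p[["sigma"]])
from_scaled <- function(s) list(Lp = s[["Lp"]], Ps = s[["Ps"]] / 1e3,
                                sigma = s[["sigma"]])

#' Fit Kedem-Katchalsky parameters to an observed trajectory
#'
#' Bounded nonlinear least squares of the K-K simulator against an observed
#' relative-volume trajectory under a known hypertonic protocol - the
#' per-oocyte estimation step for Lp, Ps and sigma. Residuals are taken on
#' relative volume; the optimiser is `stats::nlminb` launched from a fixed
#' multistart grid, so identical inputs give bit-identical results.
#' Standard errors come from the Gauss-Newton curvature (finite-difference
#' residual Jacobian) at the optimum.
#'
#' When only impermeant-bath (e.g. sucrose) data exist, fix `sigma = 1` and
#' `Ps = 0` via `fit_spec(free = "Lp")`: sigma and Ps are not identifiable
#' without a permeant.
#'
#' @param traj A [volume_trajectory()] (>= 5 samples).
#' @param geom An [oocyte_geometry()].
#' @param bath A [bath_solution()] describing the step protocol.
#' @param vb_fraction Osmotically inactive fraction.
#' @param spec A [fit_spec()].
#' @param osm_iso Isotonic osmolarity, mOsm.
#' @param t_max Optional cutoff: only samples with `time <= t_max` enter
#'   the residual (e.g. 2 for the 2-min sucrose window).
#' @param constants A [physical_constants()].
#' @param area_basis,drag Passed to the simulator; must match how the data
#'   were produced/interpreted.
#' @param rtol,atol Solver tolerances used inside the objective.
#' @return An object of class `kk_fit`: `params` ([kk_parameters()]),
#'   `se` (named standard errors), `rss`, `convergence`,
#'   `n_starts_converged`, `fitted` (simulated trajectory at the data
#'   times).
#' @examples
#' geom <- oocyte_geometry(0.12)
#' bath <- bath_solution(200, 1.3, "ethylene_glycol")
#' tr <- kk_simulate(kk_parameters(2.64, 25.49e-3, 0.8), geom, bath)
#' fit <- fit_kk(tr, geom, bath)
#' fit$params
#' @export
fit_kk <- function(traj, geom, bath, vb_fraction = 0.75,
                   spec = fit_spec(), osm_iso = 200, t_max = NULL,
                   constants = physical_constants(),
                   area_basis = c("apparent", "folded"), drag = TRUE,
                   rtol = 1e-10, atol = 1e-14) {
  area_basis <- match.arg(area_basis)
  stopifnot(inherits(spec, "fit_spec"))
  keep <- if (is.null(t_max)) rep(TRUE, nrow(traj)) else
    traj$time_min <= t_max + 1e-12
  times <- traj$time_min[keep]
  obs <- traj$rel_volume[keep]
  if (length(times) < 5) stop("trajectory must contain at least 5 samples")
  if ("Lp" %in% spec$free && diff(range(obs)) == 0)
    stop("degenerate trajectory: constant volume cannot identify Lp")

  lower_s <- to_scaled(as.list(spec$lower))
  upper_s <- to_scaled(as.list(spec$upper))
  free <- spec$free
  fixed_s <- to_scaled(modifyList(list(Lp = 0, Ps = 0, sigma = 1),
                                  spec$fixed))

  assemble <- function(theta) {
    s <- fixed_s
    s[free] <- theta
    from_scaled(s)
  }
  resid_fun <- function(theta) {
    p <- assemble(theta)
    sim <- kk_simulate(kk_parameters(p$Lp, p$Ps, p$sigma), geom, bath,
                       vb_fraction = vb_fraction, osm_iso = osm_iso,
                       times = times, constants = constants,
                       area_basis = area_basis, drag = drag,
                       rtol = rtol, atol = atol)
    sim$rel_volume - obs
  }
  obj <- function(theta) {
    r <- tryCatch(resid_fun(theta), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) return(1e10)
    sum(r^2)
  }

  best <- NULL
  n_conv <- 0L
  for (k in seq_len(nrow(spec$starts))) {
    th0 <- pmin(pmax(spec$starts[k, free], lower_s[free]), upper_s[free])
    fit <- tryCatch(
      nlminb(th0, obj, lower = lower_s[free], upper = upper_s[free],
             control = list(eval.max = 2000, iter.max = 1000,
                            rel.tol = 1e-14, x.tol = 1.5e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("all multistarts failed to converge")
  # polish the winner once more from its own optimum
  best <- nlminb(best$par, obj, lower = lower_s[free],
                 upper = upper_s[free],
                 control = list(eval.max = 2000, iter.max = 1000,
                                rel.tol = 1e-14, x.tol = 1.5e-10))

  theta <- setNames(best$par, free)
  p_hat <- assemble(theta)
  r_hat <- resid_fun(theta)
  rss <- sum(r_hat^2)

  # Gauss-Newton standard errors on the scaled basis, mapped back
  se <- setNames(rep(NA_real_, length(free)), free)
  n <- length(r_hat); np <- length(free)
  if (n > np) {
    J <- matrix(NA_real_, n, np)
    for (j in seq_len(np)) {
      h <- max(1e-6, 1e-6 * abs(theta[j]))
      tp <- theta; tm <- theta
      tp[j] <- min(theta[j] + h, upper_s[free][j])
      tm[j] <- max(theta[j] - h, lower_s[free][j])
      J[, j] <- (resid_fun(tp) - resid_fun(tm)) / (tp[j] - tm[j])
    }
    s2 <- rss / (n - np)
    cov_s <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(cov_s)) {
      se_s <- sqrt(pmax(diag(cov_s), 0))
      se <- setNames(se_s, free)
      if ("Ps" %in% free) se["Ps"] <- se["Ps"] / 1e3  # back to cm/min
    }
  }

  fitted <- kk_simulate(kk_parameters(p_hat$Lp, p_hat$Ps, p_hat$sigma),
                        geom, bath, vb_fraction = vb_fraction,
                        osm_iso = osm_iso, times = times,
                        constants = constants, area_basis = area_basis,
                        drag = drag, rtol = rtol, atol = atol)
  structure(list(params = kk_parameters(p_hat$Lp, p_hat$Ps, p_hat$sigma),
                 se = se, rss = rss, convergence = best$convergence,
                 n_starts_converged = n_conv, free = free,
                 n_samples = length(times), fitted = fitted),
            class = "kk_fit")
}

#' @export
print.kk_fit <- function(x, ...) {
  cat(sprintf(
    "K-K fit (%d samples, RSS %.3g, %d/%d starts converged)\n",
    x$n_samples, x$rss, x$n_starts_converged, 8L))
  fmt <- function(name, value, unit) {
    se <- x$se[name]
    cat(sprintf("  %-5s = %.4g %s%s\n", name, value, unit,
                if (!is.na(se)) sprintf("  (SE %.3g)", unname(se)) else ""))
  }
  fmt("Lp", x$params$Lp, "um/(min.atm)")
  fmt("Ps", x$params$Ps, "cm/min")
  fmt("sigma", x$params$sigma, "")
  invisible(x)
}

#' Residual profile of the reflection coefficient
#'
#' Re-fits (Lp, Ps) at each value of a fixed sigma grid and returns the
#' residual norm profile - a practical identifiability diagnostic: a flat
#' profile means sigma is not determined by the trajectory (always the case
#' for impermeant-only protocols, where sigma enters no active term).
#'
#' @inheritParams fit_kk
#' @param sigma_grid Numeric vector of sigma values in `[0, 1]`.
#' @param flat_tol Relative RSS range below which the profile is flagged
#'   flat.
#' @return A data frame (`sigma`, `rss`, `Lp`, `Ps`) with attribute
#'   `flat` (logical).
#' @export
profile_identifiability <- function(traj, geom, bath, vb_fraction = 0.75,
                                    sigma_grid = seq(0, 1, by = 0.1),
                                    osm_iso = 200,
                                    constants = physical_constants(),
                                    area_basis = c("apparent", "folded"),
                                    drag = TRUE, flat_tol = 1e-3) {
  area_basis <- match.arg(area_basis)
  rows <- lapply(sigma_grid, function(sg) {
    f <- fit_kk(traj, geom, bath, vb_fraction = vb_fraction,
                spec = fit_spec(free = c("Lp", "Ps"),
                                fixed = list(sigma = sg)),
                osm_iso = osm_iso, constants = constants,
                area_basis = area_basis, drag = drag)
    data.frame(sigma = sg, rss = f$rss, Lp = f$params$Lp, Ps = f$params$Ps)
  })
  out <- do.call(rbind, rows)
  rng <- diff(range(out$rss))
  flat <- rng <= flat_tol * max(out$rss, .Machine$double.eps)
  structure(out, flat = flat)
}
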