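#' Reference membrane-parameter anchors
#'
#' Published per-construct hydraulic conductivities and ethylene glycol
#' permeabilities for Xenopus oocytes expressing each aquaporin construct,
#' bundled as plain text. The `sigma_assumed` column is an assumption (the
#' source reports sigma only qualitatively), carried here so simulations
#' are fully specified.
#'
#' @return Data frame with columns `construct`, `protocol`,
#'   `Lp_um_min_atm`, `Ps_1e3_cm_min`, `sigma_assumed`.
#' @export
reference_parameters <- function() {
  read.csv(system.file("extdata", "reference_kk_parameters.csv",
                       package = "aquaflux", mustWork = TRUE),
           stringsAsFactors = FALSE, check.names = FALSE)
}

#' Specification of a synthetic oocyte batch
#'
#' Describes the population from which synthetic oocytes are drawn:
#' lognormal inter-oocyte variability around median membrane parameters
#' (permeabilities are positive and right-skewed), Gaussian diameter
#' variation, and multiplicative Gaussian measurement noise on relative
#' volume.
#'
#' @param n_oocytes Number of oocytes.
#' @param true_params Population-median [kk_parameters()].
#' @param cv_lognormal Coefficient of variation of Lp and Ps across
#'   oocytes (sigma is held fixed).
#' @param diameter_mean,diameter_sd Apparent diameter distribution, cm.
#' @param noise_sd_rel_volume Multiplicative noise SD on relative volume.
#' @param vb_fraction Osmotically inactive fraction.
#' @param seed Integer seed; expanded deterministically into per-oocyte
#'   substreams so any subset of the batch is reproducible.
#' @return An object of class `batch_spec`.
#' @export
batch_spec <- function(n_oocytes, true_params, cv_lognormal = 0.1,
                       diameter_mean = 0.12, diameter_sd = 0.004,
                       noise_sd_rel_volume = 0.01, vb_fraction = 0.75,
                       seed = 1L) {
  stopifnot(inherits(true_params, "kk_parameters"))
  if (n_oocytes < 1) stop("n_oocytes must be >= 1")
  if (cv_lognormal < 0 || noise_sd_rel_volume < 0 || diameter_sd < 0)
    stop("cv_lognormal, diameter_sd and noise_sd_rel_volume must be >= 0")
  structure(list(n_oocytes = as.integer(n_oocytes),
                 true_params = true_params, cv_lognormal = cv_lognormal,
                 diameter_mean = diameter_mean, diameter_sd = diameter_sd,
                 noise_sd_rel_volume = noise_sd_rel_volume,
                 vb_fraction = vb_fraction, seed = as.integer(seed)),
            class = "batch_spec")
}

# deterministic counter-based substream expansion; keeps seeds < 2^31
substream_seed <- function(seed, i, stream = 0L) {
  (as.numeric(seed) * 48271 + i * 9973 + stream * 7919) %% 2147483647
}

#' Default experimental protocols for synthetic bundles
#'
#' Four baths exercising every analysis stage: the hypotonic Pf assay
#' (10-fold diluted MBS, 2-s sampling, 20 s), the isotonic Ps substitution
#' assay (160 mM permeant, 5-s sampling, 1 min), hypertonic 0.9 M sucrose
#' and hypertonic 1.3 M ethylene glycol (10-s sampling, 10 min).
#'
#' @return Named list of protocol descriptions (`bath`, `duration`,
#'   `sample_interval`).
#' @export
default_protocols <- function() {
  list(
    hypotonic_pf = list(bath = bath_solution(20), duration = 1 / 3,
                        sample_interval = 1 / 30),
    isotonic_ps = list(bath = bath_solution(40, 0.16, "ethylene_glycol"),
                       duration = 1, sample_interval = 1 / 12),
    sucrose = list(bath = bath_solution(1460), duration = 10,
                   sample_interval = 1 / 6),
    eg = list(bath = bath_solution(200, 1.3, "ethylene_glycol"),
              duration = 10, sample_interval = 1 / 6))
}

#' Generate a synthetic experiment bundle
#'
#' Draws per-oocyte parameters and geometry, simulates every requested
#' protocol with the K-K model, perturbs the trajectories with
#' multiplicative Gaussian noise (the first sample is left at exactly 1,
#' the relative-volume convention), and synthesises a scintillation count
#' table for the hypertonic ethylene glycol protocol (Poisson counts
#' around the noise-free predicted uptake). Ground truth is recorded for
#' every oocyte.
#'
#' @param spec A [batch_spec()].
#' @param protocols Protocol list as from [default_protocols()] (any named
#'   subset).
#' @param cpm_background Mean background (time-zero) counts.
#' @param constants A [physical_constants()].
#' @param area_basis Membrane area basis for the simulations.
#' @return An object of class `experiment_bundle`: `truth` (data frame),
#'   `trajectories` (per-protocol list of [volume_trajectory()]s), `cpm`
#'   (data frame or NULL), `spec`.
#' @examples
#' spec <- batch_spec(3, kk_parameters(2.64, 25.49e-3, 0.8), seed = 7)
#' b <- generate_batch(spec, default_protocols()["eg"])
#' b$truth
#' @export
generate_batch <- function(spec, protocols = default_protocols(),
                           cpm_background = 300,
                           constants = physical_constants(),
                           area_basis = c("apparent", "folded")) {
  stopifnot(inherits(spec, "batch_spec"))
  area_basis <- match.arg(area_basis)
  if (length(protocols) == 0 || is.null(names(protocols)) ||
      any(names(protocols) == ""))
    stop("protocols must be a named list")
  sdlog <- sqrt(log(1 + spec$cv_lognormal^2))
  truth <- data.frame(oocyte_id = sprintf("oo%02d", seq_len(spec$n_oocytes)),
                      diameter_cm = NA_real_, Lp = NA_real_, Ps = NA_real_,
                      sigma = spec$true_params$sigma,
                      seed = NA_real_)
  trajectories <- setNames(vector("list", length(protocols)),
                           names(protocols))
  for (pn in names(protocols)) trajectories[[pn]] <- vector("list",
                                                            spec$n_oocytes)
  cpm_rows <- list()
  for (i in seq_len(spec$n_oocytes)) {
    si <- substream_seed(spec$seed, i)
    set.seed(si)
    truth$seed[i] <- si
    d <- max(rnorm(1, spec$diameter_mean, spec$diameter_sd),
             spec$diameter_mean / 2)
    # median-parameterised lognormal: meanlog = log(median)
    Lp_i <- rlnorm(1, log(spec$true_params$Lp), sdlog)
    Ps_i <- if (spec$true_params$Ps > 0)
      rlnorm(1, log(spec$true_params$Ps), sdlog) else 0
    truth$diameter_cm[i] <- d
    truth$Lp[i] <- Lp_i
    truth$Ps[i] <- Ps_i
    geom <- oocyte_geometry(d, constants)
    par_i <- kk_parameters(Lp_i, Ps_i, spec$true_params$sigma)
    for (pn in names(protocols)) {
      pr <- protocols[[pn]]
      tr <- kk_simulate(par_i, geom, pr$bath,
                        vb_fraction = spec$vb_fraction,
                        duration = pr$duration,
                        sample_interval = pr$sample_interval,
                        constants = constants, area_basis = area_basis)
      if (spec$noise_sd_rel_volume > 0) {
        fac <- exp(rnorm(nrow(tr), 0, spec$noise_sd_rel_volume))
        fac[1] <- 1
        tr <- volume_trajectory(tr$time_min, tr$rel_volume * fac,
                                attr(tr, "V0"), ns_mol = tr$ns_mol,
                                meta = attr(tr, "meta"))
      }
      trajectories[[pn]][[i]] <- tr
    }
    if ("eg" %in% names(protocols)) {
      pr <- protocols[["eg"]]
      conc <- predicted_concentration_from_kk(
        par_i, geom, pr$bath, vb_fraction = spec$vb_fraction,
        t = pr$duration, constants = constants, area_basis = area_basis)
      tr_eg <- trajectories[["eg"]][[i]]
      V_final_ul <- tr_eg$volume_cm3[nrow(tr_eg)] * 1e3
      net_expected <- conc * V_final_ul * 73000 / pr$bath$conc_permeant
      cpm_t0 <- rpois(1, cpm_background)
      cpm_t <- rpois(1, cpm_background + net_expected)
      cpm_rows[[length(cpm_rows) + 1]] <-
        data.frame(oocyte_id = truth$oocyte_id[i], cpm_t0 = cpm_t0,
                   cpm_t = cpm_t, V_final_ul = V_final_ul,
                   true_conc_mol_l = conc)
    }
  }
  structure(list(truth = truth, trajectories = trajectories,
                 cpm = if (length(cpm_rows)) do.call(rbind, cpm_rows)
                       else NULL,
                 spec = spec, area_basis = area_basis),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("Experiment bundle: %d oocytes, protocols: %s\n",
              x$spec$n_oocytes,
              paste(names(x$trajectories), collapse = ", ")))
  invisible(x)
}

#' Write worked example fixtures to a directory
#'
#' Deterministically regenerates the small plain-text fixtures used in the
#' worked examples: the loop-fragment table, the reference parameter
#' anchors, and one noise-free example trajectory CSV per hypertonic
#' protocol. Re-running produces byte-identical files.
#'
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
generate_worked_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (f in c("aqp3b_loop_fragments.tsv", "aqp3b_loop_offsets.tsv",
              "reference_kk_parameters.csv")) {
    src <- system.file("extdata", f, package = "aquaflux", mustWork = TRUE)
    dst <- file.path(dir, f)
    file.copy(src, dst, overwrite = TRUE)
    paths <- c(paths, dst)
  }
  geom <- oocyte_geometry(0.12)
  demos <- list(
    sucrose_t85a = list(params = kk_parameters(2.57),
                        bath = bath_solution(1460)),
    eg_t85a = list(params = kk_parameters(2.64, 25.49e-3, 0.8),
                   bath = bath_solution(200, 1.3, "ethylene_glycol")))
  for (nm in names(demos)) {
    tr <- kk_simulate(demos[[nm]]$params, geom, demos[[nm]]$bath,
                      duration = 10)
    dst <- file.path(dir, paste0("trajectory_", nm, ".csv"))
    write_trajectory_csv(tr, dst)
    paths <- c(paths, dst)
  }
  invisible(paths)
}
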