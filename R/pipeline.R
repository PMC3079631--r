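# Pipeline configuration and command-line surface.

bath_from_config <- function(b) {
  if (is.null(b)) stop("stage requires a 'bath' object")
  bath_solution(osm_impermeant = b$osm_impermeant,
                conc_permeant = if (is.null(b$conc_permeant)) 0
                                else b$conc_permeant,
                permeant_id = if (is.null(b$permeant_id)) "none"
                              else b$permeant_id,
                pH_label = if (is.null(b$pH_label)) NA_character_
                           else b$pH_label)
}

require_file <- function(path, field) {
  if (is.null(path)) stop(sprintf("config field '%s' is required", field))
  if (!file.exists(path))
    stop(sprintf("config field '%s': file not found: %s", field, path))
  path
}

provenance <- function(config, inputs = character()) {
  sums <- if (length(inputs)) paste(unname(tools::md5sum(inputs)),
                                    collapse = ";") else ""
  data.frame(package_version = as.character(packageVersion("aquaflux")),
             seed = if (is.null(config$seed)) NA_integer_ else config$seed,
             input_md5 = sums, stringsAsFactors = FALSE)
}

#' Run a configured analysis pipeline
#'
#' Executes the requested stages in order. A config is a named list (or a
#' path to a JSON file) with optional global fields `seed`, `out_dir`,
#' `constants` (overrides for [physical_constants()]), `geometry`
#' (`apparent_diameter_cm`), `vb_fraction`, `osm_iso`, and a `stages`
#' array. Each stage is a list with an `op` field among `"synth"`,
#' `"simulate"`, `"pf"`, `"ps"`, `"lp"`, `"fit_kk"`, `"uptake"`,
#' `"mutate"`, `"motifs"`, `"verify_table2"` plus op-specific fields.
#' Every output CSV carries provenance columns (package version, seed,
#' md5 of file inputs). Re-running an identical config reproduces
#' byte-identical result CSVs.
#'
#' @param config Named list or path to a JSON config file.
#' @return Invisibly, a named list of per-stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    require_file(config, "config")
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE,
                                  simplifyMatrix = FALSE)
  }
  if (is.null(config$stages) || length(config$stages) == 0)
    stop("config must contain a non-empty 'stages' array")
  constants <- do.call(physical_constants,
                       if (is.null(config$constants)) list()
                       else config$constants)
  geom <- oocyte_geometry(
    if (is.null(config$geometry$apparent_diameter_cm)) 0.12
    else config$geometry$apparent_diameter_cm, constants)
  vb <- if (is.null(config$vb_fraction)) 0.75 else config$vb_fraction
  osm_iso <- if (is.null(config$osm_iso)) 200 else config$osm_iso
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  emit <- function(idx, op, df, inputs = character()) {
    df <- cbind(df, provenance(config, inputs))
    path <- file.path(out_dir, sprintf("%02d_%s.csv", idx, op))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }
  load_traj <- function(stage, field = "trajectory_csv") {
    path <- require_file(stage[[field]], field)
    list(traj = read_trajectory_csv(
           path,
           time_unit = if (is.null(stage$time_unit)) "min"
                       else stage$time_unit,
           V0 = stage$V0),
         path = path)
  }

  for (idx in seq_along(config$stages)) {
    stage <- config$stages[[idx]]
    op <- stage$op
    if (is.null(op)) stop(sprintf("stages[%d]: missing 'op'", idx))
    res <- switch(
      op,
      synth = {
        pp <- stage$params
        spec <- batch_spec(
          n_oocytes = if (is.null(stage$n_oocytes)) 5 else stage$n_oocytes,
          true_params = kk_parameters(pp$Lp,
                                      if (is.null(pp$Ps)) 0 else pp$Ps,
                                      if (is.null(pp$sigma)) 1
                                      else pp$sigma),
          cv_lognormal = if (is.null(stage$cv)) 0.1 else stage$cv,
          noise_sd_rel_volume = if (is.null(stage$noise_sd)) 0.01
                                else stage$noise_sd,
          vb_fraction = vb,
          seed = if (is.null(config$seed)) 1L else config$seed)
        prot <- default_protocols()
        if (!is.null(stage$protocols)) {
          missing_p <- setdiff(unlist(stage$protocols), names(prot))
          if (length(missing_p))
            stop("unknown protocol(s): ", paste(missing_p, collapse = ", "))
          prot <- prot[unlist(stage$protocols)]
        }
        bundle <- generate_batch(spec, prot, constants = constants)
        emit(idx, op, bundle$truth)
        bundle
      },
      simulate = {
        pp <- stage$params
        tr <- kk_simulate(
          kk_parameters(pp$Lp, if (is.null(pp$Ps)) 0 else pp$Ps,
                        if (is.null(pp$sigma)) 1 else pp$sigma),
          geom, bath_from_config(stage$bath), vb_fraction = vb,
          osm_iso = osm_iso,
          duration = if (is.null(stage$duration)) 10 else stage$duration,
          sample_interval = if (is.null(stage$sample_interval)) 1 / 6
                            else stage$sample_interval,
          constants = constants)
        write_trajectory_csv(tr, file.path(out_dir,
                                           sprintf("%02d_simulate.csv",
                                                   idx)))
        tr
      },
      pf = {
        lt <- load_traj(stage)
        w <- if (is.null(stage$window)) slope_window(0, 1 / 3)
             else slope_window(stage$window[[1]], stage$window[[2]])
        r <- compute_pf(lt$traj, geom, osm_in = stage$osm_in,
                        osm_out = stage$osm_out, window = w,
                        constants = constants)
        emit(idx, op, data.frame(kind = r$kind, value = r$value,
                                 units = r$units, slope = r$slope,
                                 r_squared = r$r_squared,
                                 n_samples = r$n_samples),
             lt$path)
        r
      },
      ps = {
        lt <- load_traj(stage)
        w <- if (is.null(stage$window)) slope_window(0, 1)
             else slope_window(stage$window[[1]], stage$window[[2]])
        r <- compute_ps(lt$traj, geom, window = w)
        emit(idx, op, data.frame(kind = r$kind, value = r$value,
                                 units = r$units, slope = r$slope,
                                 r_squared = r$r_squared,
                                 n_samples = r$n_samples),
             lt$path)
        r
      },
      lp = {
        lt <- load_traj(stage)
        r <- estimate_lp_linear(lt$traj, geom,
                                bath_from_config(stage$bath),
                                t_cutoff = if (is.null(stage$t_cutoff)) 2
                                           else stage$t_cutoff,
                                osm_iso = osm_iso, constants = constants)
        emit(idx, op, data.frame(kind = r$kind, value = r$value,
                                 units = r$units, slope = r$slope,
                                 n_samples = r$n_samples),
             lt$path)
        r
      },
      fit_kk = {
        bath <- bath_from_config(stage$bath)
        spec <- if (is.null(stage$free)) fit_spec()
                else fit_spec(free = unlist(stage$free))
        if (!is.null(stage$use_previous)) {
          bundle <- results[[stage$use_previous]]
          if (is.null(bundle) || !inherits(bundle, "experiment_bundle"))
            stop(sprintf("stage '%s' is not an earlier synth stage",
                         stage$use_previous))
          prot_name <- if (is.null(stage$protocol)) "eg"
                       else stage$protocol
          trs <- bundle$trajectories[[prot_name]]
          if (is.null(trs)) stop("bundle lacks protocol: ", prot_name)
          fits <- lapply(seq_along(trs), function(i) {
            g <- oocyte_geometry(bundle$truth$diameter_cm[i], constants)
            fit_kk(trs[[i]], g, bath, vb_fraction = vb, spec = spec,
                   osm_iso = osm_iso, constants = constants)
          })
          df <- data.frame(
            oocyte_id = bundle$truth$oocyte_id,
            true_Lp = bundle$truth$Lp, true_Ps = bundle$truth$Ps,
            Lp = vapply(fits, function(f) f$params$Lp, 1),
            Ps = vapply(fits, function(f) f$params$Ps, 1),
            sigma = vapply(fits, function(f) f$params$sigma, 1),
            rss = vapply(fits, function(f) f$rss, 1))
          emit(idx, op, df)
          list(fits = fits, recovery = df)
        } else {
          lt <- load_traj(stage)
          f <- fit_kk(lt$traj, geom, bath, vb_fraction = vb, spec = spec,
                      osm_iso = osm_iso, constants = constants,
                      t_max = stage$t_max)
          emit(idx, op,
               data.frame(Lp = f$params$Lp, Ps = f$params$Ps,
                          sigma = f$params$sigma,
                          se_Lp = unname(f$se["Lp"])[1] %||% NA_real_,
                          se_Ps = unname(f$se["Ps"])[1] %||% NA_real_,
                          se_sigma = unname(f$se["sigma"])[1] %||%
                            NA_real_,
                          rss = f$rss, convergence = f$convergence),
               lt$path)
          write_trajectory_csv(f$fitted,
                               file.path(out_dir,
                                         sprintf("%02d_fit_kk_curve.csv",
                                                 idx)))
          f
        }
      },
      uptake = {
        path <- require_file(stage$cpm_csv, "cpm_csv")
        df <- read_cpm_csv(path)
        vf <- if ("V_final_ul" %in% names(df)) df$V_final_ul
              else stage$V_final_ul
        if (is.null(vf)) stop("uptake: V_final_ul needed (column or field)")
        conc <- mapply(function(ct, c0, v)
          intracellular_concentration(
            uptake_measurement(ct, c0, V_final = v)),
          df$cpm_t, df$cpm_t0, vf)
        out <- cbind(df, conc_mol_l = conc)
        emit(idx, op, out, path)
        out
      },
      mutate = {
        if (is.null(stage$construct)) stop("mutate: 'construct' required")
        specs <- parse_construct_name(stage$construct)
        seqs <- if (!is.null(stage$fasta))
          read_fasta(require_file(stage$fasta, "fasta"))
        else if (!is.null(stage$sequence))
          list(protein_sequence("input", stage$sequence))
        else stop("mutate: provide 'fasta' or 'sequence'")
        off <- if (is.null(stage$offset)) 0 else stage$offset
        mutated <- lapply(seqs, apply_mutations, specs = specs,
                          offset = off)
        emit(idx, op,
             data.frame(id = vapply(mutated, function(s) s$id, ""),
                        residues = vapply(mutated,
                                          function(s) s$residues, "")))
        mutated
      },
      motifs = {
        if (is.null(stage$sequence)) stop("motifs: 'sequence' required")
        m <- find_np_motifs(stage$sequence)
        emit(idx, op, if (nrow(m)) m else
          data.frame(start = NA_integer_, triplet = NA_character_,
                     canonical = NA))
        m
      },
      verify_table2 = {
        rep <- verify_table2()
        emit(idx, op, as.data.frame(rep))
        rep
      },
      stop(sprintf("stages[%d]: unknown op '%s'", idx, op)))
    nm <- if (!is.null(stage$name)) stage$name else sprintf("%02d_%s",
                                                            idx, op)
    results[[nm]] <- res
  }
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Command-line entry point
#'
#' Dispatches `aquaflux <subcommand> --flag value ...` onto
#' [run_pipeline()]. Subcommands: `simulate`, `pf`, `ps`, `lp`, `fit-kk`,
#' `uptake`, `mutate`, `motifs`, `synth`, `verify-table2`, or `run
#' --config file.json` for a full pipeline. A ready-to-use launcher script
#' is installed at `system.file("cli", "aquaflux.R", package =
#' "aquaflux")`.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   trailing `commandArgs`).
#' @return Invisibly, the pipeline results.
#' @export
aqp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: aquaflux <run|simulate|pf|ps|lp|fit-kk|uptake|mutate|",
         "motifs|synth|verify-table2> [--flag value ...]")
  sub <- args[1]
  flags <- list()
  i <- 2
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("expected --flag, got: ", args[i])
    key <- substring(args[i], 3)
    if (i + 1 > length(args)) stop("missing value for --", key)
    val <- args[i + 1]
    num <- suppressWarnings(as.numeric(val))
    flags[[key]] <- if (!is.na(num)) num else val
    i <- i + 2
  }
  if (sub == "run")
    return(run_pipeline(flags$config %||%
                          stop("run requires --config file.json")))
  op <- gsub("-", "_", sub, fixed = TRUE)
  stage <- list(op = op)
  known_bath <- c("osm_impermeant", "conc_permeant", "permeant_id")
  bath <- flags[names(flags) %in% known_bath]
  if (length(bath)) stage$bath <- bath
  for (k in setdiff(names(flags),
                    c(known_bath, "out", "seed", "diameter"))) {
    key <- gsub("-", "_", k, fixed = TRUE)
    stage[[key]] <- flags[[k]]
  }
  if (op %in% c("pf", "ps", "lp", "fit_kk") &&
      !is.null(flags$trajectory))
    stage$trajectory_csv <- flags$trajectory
  if (op == "mutate" && !is.null(flags$mut)) stage$construct <- flags$mut
  if (op %in% c("simulate", "synth")) {
    stage$params <- list(Lp = flags$Lp %||% 1, Ps = flags$Ps %||% 0,
                         sigma = flags$sigma %||% 1)
  }
  config <- list(out_dir = flags$out %||% ".",
                 seed = flags$seed %||% 1,
                 geometry = list(apparent_diameter_cm =
                                   flags$diameter %||% 0.12),
                 stages = list(stage))
  run_pipeline(config)
}
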