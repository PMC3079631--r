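# CSV plumbing. Dialect: comma-separated, UTF-8, mandatory header, decimal
# point; units declared in column names (time_min, volume_cm3, ...).

#' Read an oocyte trajectory from CSV
#'
#' Accepts a time column (`time_min` or `time_s`; or a bare `time` column
#' with the unit given via `time_unit`) plus exactly one volume column:
#' `rel_volume`, `volume_cm3` or `apparent_diameter_cm` (diameters are
#' cubed to volumes on read). When only relative volume is present, `V0`
#' must be supplied.
#'
#' @param path CSV file path.
#' @param time_unit Unit of a bare `time` column: `"min"` or `"s"`.
#' @param V0 Initial volume, cm^3 (required for relative-volume input).
#' @return A [volume_trajectory()].
#' @export
read_trajectory_csv <- function(path, time_unit = c("min", "s"), V0 = NULL) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("time_min", "time_s", "time"), names(df))
  if (length(tcol) == 0) stop("no time column (time_min/time_s/time) in ",
                              path)
  t <- df[[tcol[1]]]
  if (tcol[1] == "time_s" || (tcol[1] == "time" && time_unit == "s"))
    t <- t / 60
  vcols <- intersect(c("rel_volume", "volume_cm3", "apparent_diameter_cm"),
                     names(df))
  if (length(vcols) == 0)
    stop("no volume column (rel_volume/volume_cm3/apparent_diameter_cm) in ",
         path)
  vcol <- vcols[1]
  if (vcol == "rel_volume") {
    if (is.null(V0) && "volume_cm3" %in% names(df))
      V0 <- df$volume_cm3[1] / df$rel_volume[1]
    if (is.null(V0)) stop("V0 required when reading relative volumes")
    rel <- df$rel_volume
  } else if (vcol == "volume_cm3") {
    V0 <- if (is.null(V0)) df$volume_cm3[1] else V0
    rel <- df$volume_cm3 / V0
  } else {
    vol <- pi / 6 * df$apparent_diameter_cm^3
    V0 <- if (is.null(V0)) vol[1] else V0
    rel <- vol / V0
  }
  ns <- if ("internal_permeant_mol" %in% names(df))
    df$internal_permeant_mol else NULL
  volume_trajectory(t, rel, V0, ns_mol = ns)
}

#' Write a trajectory to CSV
#'
#' Columns: `time_min`, `rel_volume`, `volume_cm3` and (when present)
#' `internal_permeant_mol`.
#'
#' @param traj A [volume_trajectory()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time_min = traj$time_min, rel_volume = traj$rel_volume,
                   volume_cm3 = traj$volume_cm3)
  if (!is.null(traj$ns_mol)) df$internal_permeant_mol <- traj$ns_mol
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scintillation count table
#'
#' Expected columns: `oocyte_id`, `cpm_t0`, `cpm_t`, optionally `group`
#' and `V_final_ul`.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_cpm_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("oocyte_id", "cpm_t0", "cpm_t")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("cpm table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}
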