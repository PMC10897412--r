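# CSV/JSON readers and writers plus config handling. All dialects are
# plain-text CSV with exact headers and '#' comment lines; kHz/ng appear at
# the file surface, SI units inside.

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  }
  for (col in required) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric or missing values in '%s' at data row(s) %s",
                   path, col, paste(utils::head(bad, 5L), collapse = ", ")))
    }
    df[[col]] <- v
  }
  df
}

#' Read a frequency-sweep CSV
#'
#' Dialect: header `frequency_hz,amplitude_m,phase_rad`, comment lines start
#' with `#`. Raw photodiode sweeps use `amplitude_v` instead of
#' `amplitude_m`; they are converted with the optical-lever
#' `sensitivityVPerM` (required in that case).
#'
#' @param path CSV path.
#' @param sensitivityVPerM optical lever sensitivity in V/m, needed when the
#'   file carries `amplitude_v`.
#' @return A [SweepSpectrum-class].
#' @export
readSweepCsv <- function(path, sensitivityVPerM = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- names(utils::read.csv(path, comment.char = "#", nrows = 1L))
  if ("amplitude_v" %in% header) {
    if (is.null(sensitivityVPerM)) {
      stop("amplitude_v column requires sensitivityVPerM")
    }
    df <- .read_csv_checked(path, c("frequency_hz", "amplitude_v", "phase_rad"))
    amp <- voltsToMeters(df$amplitude_v, sensitivityVPerM)
  } else {
    df <- .read_csv_checked(path, c("frequency_hz", "amplitude_m", "phase_rad"))
    amp <- df$amplitude_m
  }
  SweepSpectrum(df$frequency_hz, amp, phase = df$phase_rad)
}

#' Write a frequency-sweep CSV
#'
#' @param spectrum a [SweepSpectrum-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSweepCsv <- function(spectrum, path) {
  stopifnot(is(spectrum, "SweepSpectrum"))
  df <- data.frame(frequency_hz = frequencies(spectrum),
                   amplitude_m = amplitude(spectrum),
                   phase_rad = phase(spectrum))
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-cell measurement CSV
#'
#' Dialect: `time_s,spring_constant_n_per_m,f_before_hz,f_after_hz,position_fraction`.
#'
#' @param path CSV path.
#' @return data.frame with those columns, numeric.
#' @seealso [measureMasses()] to append apparent/corrected masses.
#' @export
readMeasurementCsv <- function(path) {
  .read_csv_checked(path, c("time_s", "spring_constant_n_per_m",
                            "f_before_hz", "f_after_hz", "position_fraction"))
}

#' Write a measurement table with mass readout columns
#'
#' Appends the output dialect columns `apparent_mass_ng`,
#' `corrected_mass_ng` and `flag` (masses converted to ng at the file
#' surface).
#'
#' @param measured result of [measureMasses()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMeasurementCsv <- function(measured, path) {
  out <- measured
  out$apparent_mass_ng <- out$apparent_mass_kg * 1e12
  out$corrected_mass_ng <- out$corrected_mass_kg * 1e12
  out$apparent_mass_kg <- NULL
  out$corrected_mass_kg <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ensemble CSV
#'
#' Dialect: `f_cant_hz,m_app_ng,m_real_ng` (masses in ng at the file
#' surface). Returns SI columns plus the readout ratio.
#'
#' @param path CSV path.
#' @return data.frame with `f_cant_hz`, `m_app_kg`, `m_real_kg`, `ratio`.
#' @export
readEnsembleCsv <- function(path) {
  df <- .read_csv_checked(path, c("f_cant_hz", "m_app_ng", "m_real_ng"))
  if (any(df$m_real_ng <= 0)) stop(path, ": m_real_ng must be > 0")
  data.frame(f_cant_hz = df$f_cant_hz,
             m_app_kg = df$m_app_ng * 1e-12,
             m_real_kg = df$m_real_ng * 1e-12,
             ratio = df$m_app_ng / df$m_real_ng)
}

#' Write an ensemble CSV
#'
#' @param points data.frame with `f_cant_hz`, `m_app_kg`, `m_real_kg` (the
#'   output of [makeEnsembleExperiment()] works directly).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEnsembleCsv <- function(points, path) {
  need <- c("f_cant_hz", "m_app_kg", "m_real_kg")
  miss <- setdiff(need, names(points))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(f_cant_hz = points$f_cant_hz,
                   m_app_ng = points$m_app_kg * 1e12,
                   m_real_ng = points$m_real_kg * 1e12)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a diameter CSV
#'
#' Dialect: a `diameter_um` column (raw specimens) or the histogram pair
#' `bin_center_um,count`.
#'
#' @param path CSV path.
#' @return Numeric diameters in m, or a data.frame with `bin_center_m` and
#'   `count` for histogram input (both accepted by [distributionToMass()]).
#' @export
readDiameterCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- names(utils::read.csv(path, comment.char = "#", nrows = 1L))
  if ("diameter_um" %in% header) {
    df <- .read_csv_checked(path, "diameter_um")
    return(df$diameter_um * 1e-6)
  }
  df <- .read_csv_checked(path, c("bin_center_um", "count"))
  data.frame(bin_center_m = df$bin_center_um * 1e-6, count = df$count)
}

#' Write a result object as JSON
#'
#' [EnsembleFitResult-class] objects are flattened to the result dialect
#' `{f_cell_hz, f_cell_se_hz, q_cell, q_cell_se, n, flags, bins}`; plain
#' lists are written as-is.
#'
#' @param result an [EnsembleFitResult-class] or a list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResultJson <- function(result, path) {
  if (is(result, "EnsembleFitResult")) {
    result <- list(
      f_cell_hz = result@fCell, f_cell_se_hz = result@fCellSe,
      q_cell = result@qCell, q_cell_se = result@qCellSe,
      n = result@nPoints, flags = result@flags,
      bins = result@bins
    )
  }
  jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.config_known <- list(
  cantilever = c("spring_constant_n_per_m", "eigenfrequency_khz",
                 "quality_factor"),
  cell = c("mass_ng", "eigenfrequency_khz", "stiffness_n_per_m",
           "quality_factor", "damping_ns_per_m", "shape_factor_m",
           "elastic_modulus_pa")
)

#' Read a model configuration file
#'
#' JSON with a `cantilever` block (`spring_constant_n_per_m`,
#' `eigenfrequency_khz`, `quality_factor`) and an optional `cell` block
#' (`mass_ng` plus `eigenfrequency_khz` or `stiffness_n_per_m`,
#' `quality_factor` or `damping_ns_per_m`, optional `shape_factor_m`,
#' `elastic_modulus_pa`). Unknown keys are rejected rather than silently
#' ignored.
#'
#' @param path JSON path.
#' @return list with `cantilever` ([CantileverModel-class]) and, when
#'   present, `cell` ([CellMechanicalModel-class]).
#' @export
readModelConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown_blocks <- setdiff(names(cfg), names(.config_known))
  if (length(unknown_blocks)) {
    stop("unknown config block(s): ", paste(unknown_blocks, collapse = ", "))
  }
  for (blk in names(cfg)) {
    unk <- setdiff(names(cfg[[blk]]), .config_known[[blk]])
    if (length(unk)) {
      stop(sprintf("unknown key(s) in '%s': %s", blk, paste(unk, collapse = ", ")))
    }
  }
  if (is.null(cfg$cantilever)) stop("config must contain a 'cantilever' block")
  ca <- cfg$cantilever
  out <- list(cantilever = CantileverModel(ca$spring_constant_n_per_m,
                                           ca$eigenfrequency_khz * 1e3,
                                           ca$quality_factor))
  if (!is.null(cfg$cell)) {
    ce <- cfg$cell
    out$cell <- CellMechanicalModel(
      mass = ce$mass_ng * 1e-12,
      eigenfrequency = if (is.null(ce$eigenfrequency_khz)) NULL
                       else ce$eigenfrequency_khz * 1e3,
      stiffness = ce$stiffness_n_per_m,
      qualityFactor = ce$quality_factor,
      damping = if (is.null(ce$damping_ns_per_m)) NULL else ce$damping_ns_per_m,
      elasticModulus = ce$elastic_modulus_pa,
      shapeFactor = ce$shape_factor_m
    )
  }
  out
}
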