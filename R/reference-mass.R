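# Reference (ground-truth) masses from size measurements: Coulter-style
# diameter distributions for suspended cells (spherical shape assumed) and
# optical diameters for glass beads, via sphere volume times density.

#' Default densities and the Coulter diameter gate
#'
#' Defaults used throughout the reference-mass module: cell density
#' 1.06 g/cm^3, glass-bead density 1.8 g/cm^3, and the 9-24 um diameter
#' acquisition gate of the Coulter measurement.
#'
#' @format list with `cellDensity`, `beadDensity` (kg/m^3) and `gate`
#'   (m, length 2).
#' @export
referenceDefaults <- list(
  cellDensity = 1060,   # kg/m^3
  beadDensity = 1800,   # kg/m^3
  gate = c(9e-6, 24e-6) # m
)

#' Mass of a sphere of given diameter and density
#'
#' `m = rho * pi * d^3 / 6`; the workhorse converting suspended-cell (or
#' bead) diameters to reference masses.
#'
#' @param diameter diameter in m (>= 0, vectorised).
#' @param density density in kg/m^3 (> 0).
#' @return Mass in kg.
#' @examples
#' sphereMass(20e-6, 1060) * 1e12  # ~4.44 ng
#' sphereMass(15e-6, 1800) * 1e12  # ~3.18 ng (glass bead)
#' @export
sphereMass <- function(diameter, density) {
  diameter <- as.numeric(diameter)
  density <- as.numeric(density)
  if (any(!is.finite(diameter)) || any(diameter < 0)) {
    stop("diameter must be >= 0")
  }
  if (any(!is.finite(density)) || any(density <= 0)) stop("density must be > 0")
  density * pi * diameter^3 / 6
}

#' Apply the diameter acquisition gate
#'
#' @param diameters diameters in m.
#' @param gate length-2 numeric gate in m (default 9-24 um).
#' @return The diameters inside the gate (idempotent).
#' @export
gateDiameters <- function(diameters, gate = referenceDefaults$gate) {
  diameters <- as.numeric(diameters)
  diameters[diameters >= gate[1] & diameters <= gate[2]]
}

#' Convert a diameter distribution to a mass distribution
#'
#' Per-specimen sphere masses plus summary statistics. Accepts either a raw
#' diameter vector or a `(bin_center, count)` histogram data.frame (columns
#' `bin_center_m`, `count`); the histogram path uses bin centers, a
#' documented approximation. When a `repeats` grouping is given, the summary
#' additionally reports the across-repeat mean and SD of the per-repeat
#' means (the level at which instrument repeats are usually compared).
#'
#' @param diameters numeric diameters in m, or a data.frame with
#'   `bin_center_m` and `count`.
#' @param density density in kg/m^3 (default the cell density).
#' @param gate diameter gate in m; specimens outside are dropped.
#' @param repeats optional grouping vector (one entry per diameter).
#' @return list with `masses` (kg), `mean`, `sd`, `n`,
#'   `mass_equivalent_diameter` (the diameter whose sphere mass equals the
#'   mean mass), and, with `repeats`, `repeat_means`, `repeat_mean`,
#'   `repeat_sd`.
#' @examples
#' d <- c(16, 17, 18, 19, 20) * 1e-6
#' distributionToMass(d)$mean * 1e12  # ng
#' @export
distributionToMass <- function(diameters, density = referenceDefaults$cellDensity,
                               gate = referenceDefaults$gate, repeats = NULL) {
  if (is.data.frame(diameters)) {
    need <- c("bin_center_m", "count")
    if (!all(need %in% names(diameters))) {
      stop("histogram input needs columns bin_center_m and count")
    }
    diameters <- rep(diameters$bin_center_m, times = diameters$count)
  }
  diameters <- as.numeric(diameters)
  if (length(diameters) < 1L) stop("empty diameter distribution")
  keep <- diameters >= gate[1] & diameters <= gate[2]
  if (!is.null(repeats)) {
    repeats <- rep_len(repeats, length(diameters))[keep]
  }
  diameters <- diameters[keep]
  if (length(diameters) < 1L) stop("no diameters inside the gate")

  masses <- sphereMass(diameters, density)
  mu <- mean(masses)
  out <- list(
    masses = masses,
    mean = mu,
    sd = if (length(masses) > 1L) stats::sd(masses) else 0,
    n = length(masses),
    mass_equivalent_diameter = (6 * mu / (pi * density))^(1 / 3)
  )
  if (!is.null(repeats)) {
    rm <- tapply(masses, repeats, mean)
    out$repeat_means <- as.numeric(rm)
    out$repeat_mean <- mean(rm)
    out$repeat_sd <- if (length(rm) > 1L) stats::sd(rm) else 0
  }
  out
}

#' Scale a reference mass distribution for chemical crosslinking
#'
#' Glutaraldehyde crosslinking shrinks the cell volume; the reference masses
#' scale by the retained-mass `factor` (default 0.8, a ~20% reduction).
#'
#' @param dist result of [distributionToMass()], or a numeric mass vector.
#' @param factor retained-mass fraction (> 0; 1 is the identity).
#' @return Same shape as the input with masses and summaries scaled.
#' @export
crosslinkReference <- function(dist, factor = 0.8) {
  factor <- as.numeric(factor)
  if (!is.finite(factor) || factor <= 0) {
    stop("factor must be > 0 (a zero-mass cell is non-physical)")
  }
  if (is.numeric(dist)) return(dist * factor)
  if (!is.list(dist) || is.null(dist$masses)) {
    stop("dist must be a distributionToMass() result or a numeric vector")
  }
  dist$masses <- dist$masses * factor
  dist$mean <- dist$mean * factor
  dist$sd <- dist$sd * factor
  dist$mass_equivalent_diameter <- dist$mass_equivalent_diameter * factor^(1 / 3)
  if (!is.null(dist$repeat_means)) {
    dist$repeat_means <- dist$repeat_means * factor
    dist$repeat_mean <- dist$repeat_mean * factor
    dist$repeat_sd <- dist$repeat_sd * factor
  }
  dist
}
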