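# Seeded generators reproducing the statistical structure of every input the
# analysis consumes: ensemble experiments across cantilever banks, growth
# experiments as consecutive noisy sweeps, crosslinking scenarios, single
# noisy sweeps, and Coulter-style diameter samples. All generators are pure
# functions of (spec, seed); nothing touches the global RNG state.

#' Cell-population specification for the ensemble generator
#'
#' Defaults describe the measured HeLa population: mass 3.14 +/- 0.26 ng,
#' population-average eigenfrequency 14.4 kHz (between-cell SD 0 by default,
#' since the ensemble fit targets a population average), quality factor 0.3,
#' and multiplicative lognormal measurement noise with CV 0.4 on the
#' apparent mass.
#'
#' @param massMean,massSd cell mass mean and SD in kg.
#' @param fCellMean,fCellSd whole-cell eigenfrequency mean and between-cell
#'   SD in Hz.
#' @param qCell cell quality factor.
#' @param noiseCv coefficient of variation of the multiplicative lognormal
#'   noise on the apparent mass.
#' @return list of generator parameters.
#' @export
populationSpec <- function(massMean = 3.14e-12, massSd = 0.26e-12,
                           fCellMean = 14.4e3, fCellSd = 0,
                           qCell = 0.3, noiseCv = 0.4) {
  stopifnot(massMean > 0, massSd >= 0, fCellMean > 0, fCellSd >= 0,
            qCell > 0, noiseCv >= 0)
  list(massMean = massMean, massSd = massSd, fCellMean = fCellMean,
       fCellSd = fCellSd, qCell = qCell, noiseCv = noiseCv)
}

#' Microcantilever bank specification
#'
#' The classes of FIB-milled rectangular microcantilevers used across the
#' 3-110 kHz range: eigenfrequency range (in liquid) and spring-constant
#' range per class, plus the in-liquid cantilever quality factor (default 3,
#' an assumption typical for such levers in water).
#'
#' @param qCant cantilever quality factor in liquid.
#' @return list with a `classes` data.frame (`f_lo_hz`, `f_hi_hz`,
#'   `k_lo`, `k_hi` in N/m) and `qCant`.
#' @export
cantileverBank <- function(qCant = 3) {
  stopifnot(qCant > 0)
  classes <- data.frame(
    f_lo_hz = c(90e3, 60e3, 45e3, 25e3, 15e3, 3e3),
    f_hi_hz = c(110e3, 80e3, 45e3, 25e3, 15e3, 8e3),
    k_lo = c(7.8, 8.1, 2.3, 2.2, 0.2, 0.09),
    k_hi = c(11.6, 15.6, 3.2, 2.5, 0.8, 0.3)
  )
  list(classes = classes, qCant = qCant)
}

# nearest bank class for an eigenfrequency (distance to the class interval)
.bank_class <- function(f, classes) {
  d <- pmax(classes$f_lo_hz - f, 0) + pmax(f - classes$f_hi_hz, 0)
  which.min(d)
}

.truncated_normal <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

# mean-one multiplicative lognormal noise with coefficient of variation cv
.lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic ensemble experiment
#'
#' Draws `n` single-cell measurements across cantilever eigenfrequencies
#' (uniform over `fRange`): per cell a mass and eigenfrequency from the
#' population spec, the readout fraction from the closed-form
#' readout-accuracy law (`mode = "closed_form"`) or from the full 2-DOF
#' virtual experiment (`mode = "full_2dof"`, slower: each point runs the
#' sweep-and-fit pipeline with a cantilever drawn from the bank), then
#' multiplicative lognormal noise on the apparent mass. The reference mass
#' `m_real` is the population mean by default (the convention of the
#' ensemble readout curve) or the per-cell true mass.
#'
#' @param pop a [populationSpec()].
#' @param bank a [cantileverBank()] (used by `mode = "full_2dof"`).
#' @param n number of cells (>= 1).
#' @param fRange cantilever eigenfrequency range in Hz.
#' @param mode `"closed_form"` or `"full_2dof"`.
#' @param referenceMode `"population"` (m_real = population mean mass) or
#'   `"per_cell"` (m_real = each cell's true mass).
#' @param seed mandatory integer seed.
#' @return data.frame with `f_cant_hz`, `m_app_kg`, `m_real_kg`, `ratio`
#'   (= m_app/m_real), `true_mass_kg`, `true_ratio` (noise-free readout
#'   fraction).
#' @examples
#' pts <- makeEnsembleExperiment(n = 50, seed = 7)
#' fit <- fitReadoutCurve(pts, seed = 7)
#' @export
makeEnsembleExperiment <- function(pop = populationSpec(),
                                   bank = cantileverBank(),
                                   n = 178, fRange = c(3e3, 110e3),
                                   mode = c("closed_form", "full_2dof"),
                                   referenceMode = c("population", "per_cell"),
                                   seed) {
  mode <- match.arg(mode)
  referenceMode <- match.arg(referenceMode)
  if (missing(seed)) stop("seed is mandatory")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")

  withr::with_seed(seed, {
    fCant <- stats::runif(n, fRange[1], fRange[2])
    mass <- .truncated_normal(n, pop$massMean, pop$massSd, lower = 1e-15)
    fCell <- .truncated_normal(n, pop$fCellMean, pop$fCellSd, lower = 1)
    trueRatio <- if (mode == "closed_form") {
      readoutAccuracy(fCant, fCell, pop$qCell)
    } else {
      vapply(seq_len(n), function(i) {
        cl <- .bank_class(fCant[i], bank$classes)
        k <- stats::runif(1, bank$classes$k_lo[cl], bank$classes$k_hi[cl])
        cant <- CantileverModel(k, fCant[i], bank$qCant)
        cell <- CellMechanicalModel(mass[i], eigenfrequency = fCell[i],
                                    qualityFactor = pop$qCell)
        simulateApparentMass(cant, cell) / mass[i]
      }, numeric(1))
    }
    mApp <- trueRatio * mass * .lognormal_noise(n, pop$noiseCv)
    mReal <- if (referenceMode == "population") rep(pop$massMean, n) else mass
    data.frame(f_cant_hz = fCant, m_app_kg = mApp, m_real_kg = mReal,
               ratio = mApp / mReal, true_mass_kg = mass,
               true_ratio = trueRatio)
  })
}

#' Apply the chemical-crosslinking scenario to a cell model
#'
#' Glutaraldehyde crosslinking stiffens the cell by ~3x and shrinks its mass
#' by ~20%. The coupling damping is kept (the viscosity scale mu and shape
#' factor are unchanged), so the quality factor rises by
#' `sqrt(stiffnessFactor * massFactor)` and the eigenfrequency by
#' `sqrt(stiffnessFactor / massFactor)` (~1.94x at the defaults).
#'
#' @param cell a [CellMechanicalModel-class].
#' @param stiffnessFactor multiplier on the coupling stiffness (default 3).
#' @param massFactor multiplier on the mass (default 0.8).
#' @return A new [CellMechanicalModel-class].
#' @export
applyCrosslinking <- function(cell, stiffnessFactor = 3, massFactor = 0.8) {
  stopifnot(is(cell, "CellMechanicalModel"),
            stiffnessFactor > 0, massFactor > 0)
  E <- cell@elasticModulus
  CellMechanicalModel(
    mass = cellMass(cell) * massFactor,
    stiffness = couplingStiffness(cell) * stiffnessFactor,
    damping = couplingDamping(cell),
    elasticModulus = if (is.finite(E)) E * stiffnessFactor else NULL,
    shapeFactor = if (is.finite(cell@shapeFactor)) cell@shapeFactor else NULL,
    viscosity = if (is.finite(cell@viscosity)) cell@viscosity else NULL
  )
}

#' Generate one noisy frequency sweep
#'
#' Samples the 2-DOF (or bare-cantilever) response on a linear grid around
#' the cantilever resonance, then applies multiplicative Gaussian amplitude
#' noise and additive phase noise. Deterministic under the seed.
#'
#' @param cantilever a [CantileverModel-class].
#' @param cell a [CellMechanicalModel-class] or `NULL`.
#' @param noiseCv relative amplitude noise (Gaussian SD as a fraction of the
#'   amplitude); also the SD (rad) of the phase noise.
#' @param nPoints grid points (default 401).
#' @param span grid from `(1-span)` to `(1+span)` times the cantilever
#'   eigenfrequency (default 0.7).
#' @param seed mandatory integer seed.
#' @return A [SweepSpectrum-class].
#' @export
makeNoisySweep <- function(cantilever, cell = NULL, noiseCv = 0.05,
                           nPoints = 401, span = 0.7, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(is(cantilever, "CantileverModel"), noiseCv >= 0, span > 0, span < 1)
  f0 <- eigenfrequency(cantilever)
  grid <- seq((1 - span) * f0, (1 + span) * f0, length.out = as.integer(nPoints))
  clean <- frequencyResponse(cantilever, cell, grid)
  withr::with_seed(seed, {
    a <- amplitude(clean) * (1 + stats::rnorm(length(grid), 0, noiseCv))
    ph <- phase(clean) + stats::rnorm(length(grid), 0, noiseCv)
    SweepSpectrum(grid, abs(a), phase = ph,
                  driveAmplitude = clean@driveAmplitude)
  })
}

# built-in phenomenological growth profiles: apparent mass (kg) vs time (s)
# on the given cantilever. "collagen" is anchored to the observed apparent
# mass increase 0.59 -> 3.04 ng within 120 min; "stiffening" ramps the
# whole-cell stiffness linearly from 0 to 0.4 N/m at fixed mass 3.14 ng
# (overshoots then declines slightly when the ramp crosses the cantilever
# eigenfrequency); "constant" holds the apparent mass at the readout of the
# average HeLa cell.
.growth_profile <- function(profile, cantilever, duration) {
  if (is.function(profile)) return(profile)
  fc <- eigenfrequency(cantilever)
  hela <- list(m = 3.14e-12, f = 14.4e3, q = 0.3)
  switch(profile,
    collagen = function(t) {
      (0.59e-12 + (3.04e-12 - 0.59e-12) * pmin(t / 7200, 1))
    },
    constant = function(t) {
      rep(readoutAccuracy(fc, hela$f, hela$q) * hela$m, length(t))
    },
    stiffening = function(t) {
      k <- 0.4 * pmin(t / duration, 1)
      cc <- 5e-8 + 3.49e-5 * k
      vapply(seq_along(k), function(i) {
        .readout_accuracy_kmc(fc, k[i], hela$m, cc[i]) * hela$m
      }, numeric(1))
    },
    stop("unknown growth profile: ", profile)
  )
}

#' Generate a synthetic growth experiment
#'
#' Produces the raw data stream of a long-term mass measurement: consecutive
#' noisy frequency sweeps every `dt` seconds whose fitted trajectory
#' reproduces a phenomenological apparent-mass profile through the full
#' readout chain. Each time point's loaded eigenfrequency is obtained by
#' inverting the rigid-point-mass law for the profile's apparent mass, and
#' an SHO sweep is synthesised there with multiplicative amplitude noise.
#'
#' Built-in profiles: `"collagen"` (apparent mass rising 0.59 to 3.04 ng
#' over 120 min), `"stiffening"` (whole-cell stiffness ramp 0 to 0.4 N/m at
#' fixed 3.14 ng mass - non-monotone on a low-frequency cantilever),
#' `"constant"`. A custom profile is a `function(t)` returning apparent
#' mass in kg.
#'
#' @param profile profile name or `function(t) -> kg`.
#' @param cantilever a [CantileverModel-class] (default a 70 kHz, 8 N/m,
#'   Q 3 lever).
#' @param duration experiment length in s (default 7200 = 120 min).
#' @param dt sweep repetition interval in s (default 10).
#' @param noiseCv relative amplitude noise per sweep (default 0.02).
#' @param nPoints grid points per sweep.
#' @param seed mandatory integer seed.
#' @return list with `sweeps` (list of [SweepSpectrum-class]), `times` (s),
#'   `fBefore` (Hz), `springConstant` (N/m), and `truth` (data.frame
#'   `time_s`, `apparent_mass_kg`).
#' @examples
#' \donttest{
#' g <- makeGrowthExperiment("collagen", dt = 600, seed = 3)
#' tr <- massTrajectory(g$sweeps, g$times, g$fBefore, g$springConstant)
#' }
#' @export
makeGrowthExperiment <- function(profile = "collagen",
                                 cantilever = CantileverModel(8, 70e3, 3),
                                 duration = 7200, dt = 10, noiseCv = 0.02,
                                 nPoints = 301, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(is(cantilever, "CantileverModel"), duration > 0, dt > 0)
  times <- seq(0, duration, by = dt)
  prof <- .growth_profile(profile, cantilever, duration)
  mApp <- prof(times)
  kc <- springConstant(cantilever)
  fBefore <- eigenfrequency(cantilever)
  fAfter <- frequencyAfterAttachment(kc, fBefore, mApp)

  sweeps <- withr::with_seed(seed, lapply(seq_along(times), function(i) {
    loaded <- CantileverModel(kc, fAfter[i], qualityFactor(cantilever))
    grid <- seq(0.4 * fBefore, 1.4 * fBefore, length.out = as.integer(nPoints))
    clean <- frequencyResponse(loaded, NULL, grid)
    a <- amplitude(clean) * (1 + stats::rnorm(length(grid), 0, noiseCv))
    SweepSpectrum(grid, abs(a), phase = phase(clean))
  }))

  list(sweeps = sweeps, times = times, fBefore = fBefore,
       springConstant = kc,
       truth = data.frame(time_s = times, apparent_mass_kg = mApp))
}

#' Generate a Coulter-style diameter sample
#'
#' Normal diameters truncated to the acquisition gate. The default mean,
#' 17.8 um, is the mass-equivalent diameter of a 3.14 ng cell at density
#' 1.06 g/cm^3 (a derived quantity, not an instrument reading); it sits
#' inside the 16-20 um selection window used for single-cell pickup.
#'
#' @param n sample size (>= 1).
#' @param meanDiameter mean diameter in m.
#' @param sd diameter SD in m.
#' @param gate acquisition gate in m (default 9-24 um).
#' @param seed mandatory integer seed.
#' @return Numeric diameters in m.
#' @export
makeCoulterSample <- function(n, meanDiameter = 17.8e-6, sd = 0.5e-6,
                              gate = referenceDefaults$gate, seed) {
  if (missing(seed)) stop("seed is mandatory")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  stopifnot(meanDiameter > 0, sd >= 0)
  if (meanDiameter < gate[1] || meanDiameter > gate[2]) {
    stop("meanDiameter outside the acquisition gate")
  }
  withr::with_seed(seed,
    .truncated_normal(n, meanDiameter, sd, lower = gate[1], upper = gate[2]))
}
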