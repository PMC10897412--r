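# Frequency-domain physics of the 2-degree-of-freedom lumped-mass model:
# a driven, damped cantilever (k_c, m_c, c_c) carrying a point-mass cell
# (m) attached through a Kelvin-Voigt element (k_cell || c_cell).
#
# Time convention: e^{+i omega t}. With x = X e^{i omega t} the equation of
# motion gives (k + i omega c - omega^2 m) X = F, i.e. viscous dissipation
# appears as +i omega c, and the imaginary part of the effective dynamic
# mass is <= 0 (energy flows into the cell, never out).

#' Complex dynamic stiffness of the Kelvin-Voigt attachment
#'
#' `K*(omega) = k_cell + i * omega * c_cell` under the `e^{+i omega t}`
#' convention.
#'
#' @param cell a [CellMechanicalModel-class].
#' @param frequency actuation frequency in Hz (vectorised, >= 0).
#' @return Complex stiffness in N/m.
#' @examples
#' hela <- CellMechanicalModel(3.14e-12, eigenfrequency = 14.4e3,
#'                             qualityFactor = 0.3)
#' complexCoupling(hela, 14.4e3)
#' @export
complexCoupling <- function(cell, frequency) {
  stopifnot(is(cell, "CellMechanicalModel"))
  frequency <- as.numeric(frequency)
  if (any(!is.finite(frequency)) || any(frequency < 0)) {
    stop("frequency must be finite and >= 0")
  }
  complex(real = couplingStiffness(cell),
          imaginary = 2 * pi * frequency * couplingDamping(cell))
}

#' Effective dynamic mass of the attached cell
#'
#' A payload coupled through a spring-damper element does not load the
#' resonator with its full mass: it presents the complex, frequency-dependent
#' effective mass
#' `m_eff(omega) = m * K*(omega) / (K*(omega) - omega^2 m)`.
#' At `omega -> 0` every compartment follows the cantilever and
#' `m_eff -> m`; far above the cell eigenfrequency the cell decouples and
#' `m_eff -> 0`. The real part evaluated at the cantilever eigenfrequency,
#' divided by `m`, is identically the closed-form readout-accuracy law
#' (see [readoutAccuracy()]).
#'
#' @param cell a [CellMechanicalModel-class].
#' @param frequency actuation frequency in Hz (vectorised, >= 0).
#' @return Complex effective mass in kg; `Im <= 0` under the
#'   `e^{+i omega t}` convention.
#' @examples
#' hela <- CellMechanicalModel(3.14e-12, eigenfrequency = 14.4e3,
#'                             qualityFactor = 0.3)
#' Re(effectiveDynamicMass(hela, 75e3)) * 1e12  # ~0.878 ng
#' @export
effectiveDynamicMass <- function(cell, frequency) {
  stopifnot(is(cell, "CellMechanicalModel"))
  frequency <- as.numeric(frequency)
  if (any(!is.finite(frequency)) || any(frequency < 0)) {
    stop("frequency must be finite and >= 0")
  }
  m <- cellMass(cell)
  omega <- 2 * pi * frequency
  K <- complexCoupling(cell, frequency)
  den <- K - omega^2 * m
  bad <- Mod(den) == 0
  if (any(bad)) {
    stop(sprintf(
      "undamped resonance pole at %.6g Hz: K*(omega) - omega^2 m = 0",
      frequency[which(bad)[1]]))
  }
  m * K / den
}

#' Cantilever frequency response with or without an attached cell
#'
#' Complex deflection of the cantilever end per actuation frequency,
#' `X(omega) = F / (k_c + i omega c_c - omega^2 (m_c + m_eff(omega)))`,
#' where `m_eff` is the cell's effective dynamic mass
#' ([effectiveDynamicMass()]) or 0 without a cell (plain driven damped
#' oscillator). At zero frequency without a cell the amplitude is the static
#' compliance `F / k_c`.
#'
#' @param cantilever a [CantileverModel-class].
#' @param cell a [CellMechanicalModel-class] or `NULL` for the bare lever.
#' @param frequency strictly increasing, positive frequency grid in Hz.
#' @param driveForce drive force in N (> 0). Defaults to
#'   `springConstant * 0.16 nm`, anchoring the static amplitude to the
#'   instrument's sub-nanometre photothermal drive.
#' @return A [SweepSpectrum-class].
#' @export
frequencyResponse <- function(cantilever, cell = NULL, frequency,
                              driveForce = NULL) {
  stopifnot(is(cantilever, "CantileverModel"))
  frequency <- as.numeric(frequency)
  if (length(frequency) < 1L) stop("empty frequency grid")
  if (any(!is.finite(frequency)) || any(frequency < 0)) {
    stop("frequencies must be finite and >= 0")
  }
  if (any(diff(frequency) <= 0)) stop("frequency grid must be strictly increasing")
  if (is.null(driveForce)) {
    driveForce <- springConstant(cantilever) * 0.16e-9
  }
  driveForce <- as.numeric(driveForce)
  if (!is.finite(driveForce) || driveForce <= 0) stop("driveForce must be > 0")

  kc <- springConstant(cantilever)
  mc <- modalMass(cantilever)
  cc <- dampingCoefficient(cantilever)
  omega <- 2 * pi * frequency
  meff <- if (is.null(cell)) 0 + 0i else effectiveDynamicMass(cell, frequency)
  den <- complex(real = kc, imaginary = omega * cc) - omega^2 * (mc + meff)
  SweepSpectrum(frequency, driveForce / den,
                driveAmplitude = driveForce / kc)
}

# ---- SHO sweep fitting -----------------------------------------------------

# Amplitude of a driven damped oscillator, normalised so a is the
# zero-frequency (static) amplitude:
#   A(f) = a * f0^2 / sqrt((f0^2 - f^2)^2 + (f * f0 / Q)^2)
.sho_amp <- function(f, f0, Q, a) {
  a * f0^2 / sqrt((f0^2 - f^2)^2 + (f * f0 / Q)^2)
}

# Parabolic interpolation of the log-amplitude around the grid maximum.
# Returns the interpolated peak frequency and index; errors when the max
# sits on the boundary (peak not bracketed by the grid).
.peak_interp <- function(f, a) {
  i <- which.max(a)
  if (i == 1L || i == length(a)) {
    stop("peak not bracketed: amplitude maximum at grid boundary")
  }
  la <- log(a[(i - 1L):(i + 1L)])
  curv <- la[1] - 2 * la[2] + la[3]
  delta <- if (curv < 0) 0.5 * (la[1] - la[3]) / curv else 0
  delta <- max(-1, min(1, delta))
  # local quadratic in index space, mapped back through the (possibly
  # non-uniform) grid by linear interpolation between neighbours
  fpk <- if (delta >= 0) f[i] + delta * (f[i + 1L] - f[i])
         else f[i] + delta * (f[i] - f[i - 1L])
  list(frequency = fpk, index = i)
}

# Half-power (-3 dB) bandwidth Q estimate around the peak; conservative
# fallback when a crossing is missing on one side.
.q_halfpower <- function(f, a, ipk) {
  thr <- a[ipk] / sqrt(2)
  lo <- NA_real_
  for (j in seq(ipk, 2L)) {
    if (a[j - 1L] < thr && a[j] >= thr) {
      lo <- f[j - 1L] + (thr - a[j - 1L]) / (a[j] - a[j - 1L]) * (f[j] - f[j - 1L])
      break
    }
  }
  hi <- NA_real_
  for (j in seq(ipk, length(a) - 1L)) {
    if (a[j + 1L] < thr && a[j] >= thr) {
      hi <- f[j] + (a[j] - thr) / (a[j] - a[j + 1L]) * (f[j + 1L] - f[j])
      break
    }
  }
  if (is.na(lo) || is.na(hi) || hi <= lo) return(2)
  max(f[ipk] / (hi - lo), 0.2)
}

.sho_fit <- function(f, a, baseline = FALSE) {
  if (length(f) < 7L) stop("need at least 7 points bracketing the maximum")
  pk <- .peak_interp(f, a)
  q0 <- .q_halfpower(f, a, pk$index)
  f00 <- if (q0 > 1 / sqrt(2)) pk$frequency / sqrt(1 - 1 / (2 * q0^2))
         else pk$frequency
  scale <- max(a)
  an <- a / scale
  # static amplitude start: A_peak ~ a * Q near resonance
  a0 <- max(an) / max(q0, 0.5)

  obj <- function(p) {
    mod <- .sho_amp(f, exp(p[1]), exp(p[2]), exp(p[3]))
    if (baseline) mod <- mod + p[4]^2
    sum((an - mod)^2)
  }
  p0 <- c(log(f00), log(q0), log(a0))
  if (baseline) p0 <- c(p0, sqrt(max(min(an), 1e-12)))
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  conv <- is.finite(fit$value)
  if (!conv) stop("SHO fit did not converge")
  p <- fit$par
  list(f0 = exp(p[1]), Q = exp(p[2]), scale = exp(p[3]) * scale,
       baseline = if (baseline) p[4]^2 * scale else 0,
       residual = fit$value * scale^2, converged = conv)
}

#' Apparent eigenfrequency of a sweep spectrum
#'
#' Extracts the resonance frequency the instrument would report. The default
#' `sho_fit` method least-squares fits the driven-damped-oscillator
#' amplitude model (parameters f0, Q, scale, optional constant baseline) and
#' returns its f0, matching the simple-harmonic-oscillator assumption of
#' the readout. The `peak` method interpolates the log-amplitude maximum
#' parabolically and de-biases it back to f0 with the half-power Q estimate
#' (an SHO amplitude peaks at `f0 * sqrt(1 - 1/(2 Q^2))`, not at f0).
#'
#' @param spectrum a [SweepSpectrum-class] with at least 7 points bracketing
#'   a local amplitude maximum.
#' @param method `"sho_fit"` (default) or `"peak"`.
#' @return Apparent eigenfrequency in Hz.
#' @seealso [fitSweep()] for the full fit (f0, Q, scale, residual).
#' @export
apparentEigenfrequency <- function(spectrum, method = c("sho_fit", "peak")) {
  method <- match.arg(method)
  stopifnot(is(spectrum, "SweepSpectrum"))
  f <- frequencies(spectrum)
  a <- amplitude(spectrum)
  if (length(f) < 7L) stop("need at least 7 points bracketing the maximum")
  if (method == "sho_fit") {
    return(.sho_fit(f, a)$f0)
  }
  pk <- .peak_interp(f, a)
  q <- .q_halfpower(f, a, pk$index)
  if (q > 1 / sqrt(2)) pk$frequency / sqrt(1 - 1 / (2 * q^2)) else pk$frequency
}

# default grid spec: coarse log grid around the cantilever resonance with a
# refined linear window (+/- 3 half-widths) around the detected peak.
.default_grid_spec <- function() {
  list(n = 1001L, span = 5, refine = TRUE, refineN = 801L, refineHalfwidths = 3)
}

.log_grid <- function(f0, spec) {
  exp(seq(log(f0 / spec$span), log(f0 * spec$span), length.out = spec$n))
}

# full sweep-and-fit pipeline for one configuration; returns fitted f0
.measure_f0 <- function(cantilever, cell, spec) {
  f0c <- eigenfrequency(cantilever)
  sp <- frequencyResponse(cantilever, cell, .log_grid(f0c, spec))
  fit <- .sho_fit(frequencies(sp), amplitude(sp))
  if (!isTRUE(spec$refine)) return(fit$f0)
  hw <- fit$f0 / (2 * max(fit$Q, 0.5))
  lo <- max(fit$f0 - spec$refineHalfwidths * hw, f0c / (2 * spec$span))
  hi <- fit$f0 + spec$refineHalfwidths * hw
  grid <- seq(lo, hi, length.out = spec$refineN)
  sp2 <- frequencyResponse(cantilever, cell, grid)
  .sho_fit(frequencies(sp2), amplitude(sp2))$f0
}

#' Simulate the apparent mass the picobalance would report
#'
#' Runs the full virtual experiment: sweep the bare cantilever, fit the SHO
#' model to get `f_before`; attach the cell (2-DOF response), sweep and fit
#' again for `f_after`; convert the eigenfrequency pair to an apparent mass
#' with the rigid-point-mass law ([massFromFrequencyShift()]). In the limit
#' of vanishing mass ratio and large cantilever Q this converges to
#' `Re(m_eff(2 pi f_cant))`, i.e. the closed-form readout-accuracy value
#' times the true mass.
#'
#' @param cantilever a [CantileverModel-class].
#' @param cell a [CellMechanicalModel-class].
#' @param gridSpec list with elements `n` (coarse log-grid points), `span`
#'   (grid from `f0/span` to `f0*span`), `refine`, `refineN`,
#'   `refineHalfwidths`; defaults are used for missing entries.
#' @return Apparent mass in kg.
#' @examples
#' cant <- CantileverModel(8, 75e3, 100)
#' rigid <- CellMechanicalModel(3.14e-12, eigenfrequency = 100 * 75e3,
#'                              qualityFactor = 5)
#' simulateApparentMass(cant, rigid) * 1e12  # ~3.14 ng (rigid limit)
#' @export
simulateApparentMass <- function(cantilever, cell, gridSpec = list()) {
  stopifnot(is(cantilever, "CantileverModel"), is(cell, "CellMechanicalModel"))
  spec <- utils::modifyList(.default_grid_spec(), gridSpec)
  fBefore <- .measure_f0(cantilever, NULL, spec)
  fAfter <- .measure_f0(cantilever, cell, spec)
  massFromFrequencyShift(springConstant(cantilever), fBefore, fAfter)
}

#' Closed-form mass readout accuracy of the picobalance
#'
#' The ratio of apparent to real cell mass as a function of the cantilever
#' eigenfrequency `f_cant`, the whole-cell eigenfrequency `f_cell`, and the
#' cell quality factor `Q_cell`:
#' \deqn{\frac{m_{app}}{m_{real}} = 1 +
#'   \frac{f_{cant}^2 (f_{cell}^2 - f_{cant}^2)}
#'        {(f_{cell}^2 - f_{cant}^2)^2 + f_{cant}^2 f_{cell}^2 / Q_{cell}^2}}
#' It equals `Re(m_eff(2 pi f_cant)) / m` identically. Limits: 1 as
#' `f_cant -> 0` (the whole cell follows the lever and the rigid-mass law is
#' exact), 0 as `f_cant -> infinity` (the cell decouples), and exactly 1 at
#' `f_cant = f_cell`. Near `f_cant = f_cell` with weak damping the readout
#' can overshoot above 1.
#'
#' @param fCant cantilever eigenfrequency in Hz (> 0, vectorised).
#' @param fCell whole-cell eigenfrequency in Hz (> 0).
#' @param qCell cell quality factor (> 0; `Inf` for undamped, which is
#'   singular at `fCant == fCell`).
#' @return Dimensionless ratio m_app / m_real.
#' @examples
#' readoutAccuracy(75e3, 14.4e3, 0.3)  # ~0.28: a 75 kHz lever sees ~28%
#' readoutAccuracy(15e3, 14.4e3, 0.3)  # ~0.99: a 15 kHz lever is accurate
#' @export
readoutAccuracy <- function(fCant, fCell, qCell) {
  fCant <- as.numeric(fCant); fCell <- as.numeric(fCell)
  qCell <- as.numeric(qCell)
  if (any(!is.finite(fCant)) || any(fCant <= 0)) stop("fCant must be > 0")
  if (any(!is.finite(fCell)) || any(fCell <= 0)) stop("fCell must be > 0")
  if (any(qCell <= 0)) stop("qCell must be > 0")
  x <- fCell^2
  f2 <- fCant^2
  qinv2 <- ifelse(is.infinite(qCell), 0, 1 / qCell^2)
  den <- (x - f2)^2 + f2 * x * qinv2
  if (any(den == 0)) {
    stop("singular: fCant equals fCell with infinite qCell")
  }
  1 + f2 * (x - f2) / den
}

# Readout accuracy straight from (k_cell, m, c_cell); needed where Q is
# undefined (k = 0 with damping present). Equal to Re{m_eff}/m.
.readout_accuracy_kmc <- function(fCant, k, m, cc) {
  omega <- 2 * pi * fCant
  num <- k * (k - omega^2 * m) + omega^2 * cc^2
  den <- (k - omega^2 * m)^2 + omega^2 * cc^2
  if (any(den == 0)) stop("singular: undamped resonance at fCant")
  num / den
}

#' Readout fraction along a cell-stiffening ramp
#'
#' Evaluates the mass readout fraction while the whole-cell stiffness ramps
#' up (the lumped-model picture of cell spreading/stiffening: `k_cell`
#' linearly increased from 0 to 0.4 N/m). The attachment damping follows the
#' `dampingRule`:
#' \itemize{
#'   \item `list(cMin=, beta=)` - linear rule `c_cell = cMin + beta * k_cell`
#'     (default `cMin = 5e-8` N s/m, i.e. a minimal viscosity scale of
#'     2.5 mPa s times a 2.0e-5 m shape factor; `beta = 3.49e-5` s
#'     calibrated so `Q_cell = 0.3` at the fitted HeLa state
#'     k = 0.0257 N/m, m = 3.14 ng).
#'   \item `list(fixedQ=)` - hold `Q_cell` constant along the ramp.
#' }
#'
#' @param cantilever a [CantileverModel-class].
#' @param cellMass cell mass in kg.
#' @param kGrid non-negative, increasing stiffness values in N/m.
#' @param dampingRule see Details.
#' @param method `"closed_form"` (fast path, `Re(m_eff)/m`) or `"full_2dof"`
#'   (virtual sweep experiment per point via [simulateApparentMass()]).
#' @param gridSpec passed to [simulateApparentMass()] for `"full_2dof"`.
#' @return data.frame with columns `k_cell`, `c_cell`, `f_cell`, `q_cell`,
#'   `ratio` (m_app / m_real).
#' @export
stiffeningTrajectory <- function(cantilever, cellMass, kGrid,
                                 dampingRule = list(cMin = 5e-8, beta = 3.49e-5),
                                 method = c("closed_form", "full_2dof"),
                                 gridSpec = list()) {
  method <- match.arg(method)
  stopifnot(is(cantilever, "CantileverModel"))
  kGrid <- as.numeric(kGrid)
  if (any(kGrid < 0)) stop("kGrid must be non-negative")
  if (length(kGrid) > 1L && any(diff(kGrid) < 0)) stop("kGrid must be increasing")
  m <- as.numeric(cellMass)
  if (!is.finite(m) || m <= 0) stop("cellMass must be > 0")

  fCell <- sqrt(kGrid / m) / (2 * pi)
  if (!is.null(dampingRule$fixedQ)) {
    q <- as.numeric(dampingRule$fixedQ)
    cc <- ifelse(kGrid > 0, sqrt(kGrid * m) / q, 0)
  } else {
    cc <- dampingRule$cMin + dampingRule$beta * kGrid
  }
  qCell <- ifelse(cc > 0, sqrt(kGrid * m) / cc, Inf)

  fc <- eigenfrequency(cantilever)
  ratio <- if (method == "closed_form") {
    vapply(seq_along(kGrid), function(i) {
      .readout_accuracy_kmc(fc, kGrid[i], m, cc[i])
    }, numeric(1))
  } else {
    vapply(seq_along(kGrid), function(i) {
      cell <- CellMechanicalModel(m, stiffness = kGrid[i], damping = cc[i])
      simulateApparentMass(cantilever, cell, gridSpec) / m
    }, numeric(1))
  }
  data.frame(k_cell = kGrid, c_cell = cc, f_cell = fCell, q_cell = qCell,
             ratio = ratio)
}
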