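# Picobalance bookkeeping: the rigid-point-mass law converting an
# eigenfrequency pair to an apparent mass, the clamped-free beam mode shape
# used for the cell-position correction, sweep fitting, optical-lever unit
# conversion, and time-series mass trajectories.

#' Apparent mass from an eigenfrequency shift
#'
#' The rigid-point-mass law of cantilever mass sensing:
#' \deqn{m^{*} = \frac{k_{cant}}{4\pi^2}
#'   \left(\frac{1}{f_{after}^2} - \frac{1}{f_{before}^2}\right)}
#' where `f_before` and `f_after` are the cantilever eigenfrequencies before
#' and after payload attachment. Noise can push `f_after` above `f_before`;
#' the resulting small negative mass is returned as-is (flag it downstream,
#' do not clip - averaging must see it).
#'
#' @param springConstant cantilever spring constant in N/m (> 0).
#' @param fBefore eigenfrequency before attachment in Hz (> 0).
#' @param fAfter eigenfrequency after attachment in Hz (> 0).
#' @return Apparent (uncorrected) mass in kg; vectorised.
#' @examples
#' massFromFrequencyShift(8, 70e3, 67485) * 1e12  # ~3.14 ng
#' @export
massFromFrequencyShift <- function(springConstant, fBefore, fAfter) {
  springConstant <- as.numeric(springConstant)
  fBefore <- as.numeric(fBefore)
  fAfter <- as.numeric(fAfter)
  if (any(!is.finite(springConstant)) || any(springConstant <= 0)) {
    stop("springConstant must be > 0")
  }
  if (any(!is.finite(fBefore)) || any(fBefore <= 0) ||
      any(!is.finite(fAfter)) || any(fAfter <= 0)) {
    stop("frequencies must be finite and > 0")
  }
  springConstant / (4 * pi^2) * (1 / fAfter^2 - 1 / fBefore^2)
}

#' Invert the rigid-point-mass law
#'
#' Eigenfrequency after attaching a rigid mass `m`:
#' `1/f_after^2 = 1/f_before^2 + 4 pi^2 m / k`. Used by the synthetic-data
#' generators and as the round-trip inverse of [massFromFrequencyShift()].
#'
#' @param springConstant cantilever spring constant in N/m.
#' @param fBefore eigenfrequency before attachment in Hz.
#' @param mass attached mass in kg (may be slightly negative from noise, as
#'   long as the argument of the square root stays positive).
#' @return `f_after` in Hz; vectorised.
#' @export
frequencyAfterAttachment <- function(springConstant, fBefore, mass) {
  springConstant <- as.numeric(springConstant)
  fBefore <- as.numeric(fBefore)
  mass <- as.numeric(mass)
  if (any(!is.finite(springConstant)) || any(springConstant <= 0)) {
    stop("springConstant must be > 0")
  }
  if (any(!is.finite(fBefore)) || any(fBefore <= 0)) {
    stop("fBefore must be > 0")
  }
  arg <- 1 / fBefore^2 + 4 * pi^2 * mass / springConstant
  if (any(arg <= 0)) stop("mass too negative: no real eigenfrequency")
  1 / sqrt(arg)
}

# first clamped-free Euler-Bernoulli eigenvalue and mode constant
.beam_lambda1 <- 1.875104068711961
.beam_sigma1 <- (cosh(.beam_lambda1) + cos(.beam_lambda1)) /
  (sinh(.beam_lambda1) + sin(.beam_lambda1))

#' First flexural mode shape of a clamped-free beam
#'
#' Euler-Bernoulli first mode of a cantilevered beam, normalised to 1 at the
#' free end: a point mass at fractional position `xi` contributes
#' `phi(xi)^2` of its mass to the modal mass, which motivates the position
#' correction of [correctForPosition()].
#'
#' @param positionFraction position along the beam in `[0, 1]`
#'   (0 = clamped end, 1 = free end); vectorised.
#' @return `phi(xi)`, dimensionless; 0 at the clamp, 1 at the free end,
#'   strictly increasing.
#' @examples
#' modeShape(c(0, 0.8, 1))
#' @export
modeShape <- function(positionFraction) {
  xi <- as.numeric(positionFraction)
  if (any(!is.finite(xi)) || any(xi < 0) || any(xi > 1)) {
    stop("positionFraction must lie in [0, 1]")
  }
  l <- .beam_lambda1
  s <- .beam_sigma1
  num <- cosh(l * xi) - cos(l * xi) - s * (sinh(l * xi) - sin(l * xi))
  den <- cosh(l) - cos(l) - s * (sinh(l) - sin(l))
  num / den
}

#' Correct an apparent mass for the cell position on the beam
#'
#' A point mass at fractional beam position `xi` shifts the eigenfrequency
#' as if it were `phi(xi)^2` times lighter at the free end, so the total
#' mass is `m_apparent / phi(xi)^2`. Corrections beyond the `cutoff`
#' position (default 0.2, a ~40x correction) are refused: they amplify
#' noise past any useful accuracy.
#'
#' @param apparentMass apparent mass in kg (finite; may be negative).
#' @param positionFraction position in `(cutoff, 1]`.
#' @param cutoff smallest accepted position fraction (default 0.2).
#' @return Corrected total mass in kg; vectorised.
#' @examples
#' correctForPosition(1e-12, 0.8) * 1e12  # ~1.9 ng
#' @export
correctForPosition <- function(apparentMass, positionFraction, cutoff = 0.2) {
  apparentMass <- as.numeric(apparentMass)
  xi <- as.numeric(positionFraction)
  if (any(!is.finite(apparentMass))) stop("apparentMass must be finite")
  if (any(!is.finite(xi)) || any(xi > 1)) {
    stop("positionFraction must lie in (cutoff, 1]")
  }
  if (any(xi <= cutoff)) {
    stop(sprintf(
      "positionFraction <= %.3g refused: position correction > %.3gx is noise-dominated",
      cutoff, 1 / modeShape(cutoff)^2))
  }
  apparentMass / modeShape(xi)^2
}

#' Fit the driven damped oscillator model to a sweep
#'
#' Least-squares fit of the SHO amplitude model
#' `A(f) = a f0^2 / sqrt((f0^2 - f^2)^2 + (f f0 / Q)^2)` (optionally plus a
#' constant baseline) to a [SweepSpectrum-class], as used to determine the
#' cantilever eigenfrequency from a frequency sweep.
#'
#' @param spectrum a [SweepSpectrum-class] with >= 7 points bracketing a
#'   local amplitude maximum.
#' @param baseline logical: include a constant amplitude offset.
#' @return list with `f0` (Hz), `Q`, `scale` (static amplitude, m),
#'   `baseline` (m), `residual` (sum of squared amplitude residuals, m^2)
#'   and `converged`.
#' @seealso [apparentEigenfrequency()] for just f0.
#' @export
fitSweep <- function(spectrum, baseline = FALSE) {
  stopifnot(is(spectrum, "SweepSpectrum"))
  .sho_fit(frequencies(spectrum), amplitude(spectrum), baseline = baseline)
}

#' Convert photodiode volts to meters
#'
#' Divides the raw photodiode amplitude by the optical lever sensitivity
#' (the slope of the deflection signal when pressing the lever against a
#' hard surface).
#'
#' @param amplitudeV amplitude in V; vectorised.
#' @param sensitivityVPerM optical lever sensitivity in V/m (> 0).
#' @return Amplitude in m.
#' @examples
#' voltsToMeters(1.243e-2, 7.77e7) * 1e9  # ~0.16 nm
#' @export
voltsToMeters <- function(amplitudeV, sensitivityVPerM) {
  s <- as.numeric(sensitivityVPerM)
  if (any(!is.finite(s)) || any(s <= 0)) stop("sensitivity must be > 0")
  as.numeric(amplitudeV) / s
}

#' Mass trajectory from consecutive frequency sweeps
#'
#' The continuous measurement mode of the picobalance: each sweep (repeated
#' every ~10 s) is SHO-fitted for the loaded eigenfrequency, converted to an
#' apparent mass against the shared pre-attachment calibration `fBefore`,
#' and corrected for the cell position on the beam. Failed fits and negative
#' masses are flagged, never dropped.
#'
#' @param sweeps list of [SweepSpectrum-class] objects.
#' @param times timestamps in s, strictly increasing, one per sweep.
#' @param fBefore pre-attachment eigenfrequency in Hz (shared calibration).
#' @param springConstant cantilever spring constant in N/m.
#' @param positions cell position fraction(s) along the beam, scalar or one
#'   per sweep (default 1, free end).
#' @param smoothWindow optional odd integer: rolling-median window applied
#'   to the corrected masses (default `NULL`, no smoothing).
#' @return data.frame with `time_s`, `f_after_hz`, `apparent_mass_kg`,
#'   `corrected_mass_kg`, `flag` (`"ok"`, `"negative_mass"` or
#'   `"fit_failed"`).
#' @export
massTrajectory <- function(sweeps, times, fBefore, springConstant,
                           positions = 1, smoothWindow = NULL) {
  if (length(sweeps) < 1L) stop("need at least one sweep")
  times <- as.numeric(times)
  if (length(times) != length(sweeps)) stop("one timestamp per sweep required")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  positions <- rep_len(as.numeric(positions), length(sweeps))

  fAfter <- rep(NA_real_, length(sweeps))
  flag <- rep("ok", length(sweeps))
  for (i in seq_along(sweeps)) {
    fAfter[i] <- tryCatch(.sho_fit(frequencies(sweeps[[i]]),
                                   amplitude(sweeps[[i]]))$f0,
                          error = function(e) NA_real_)
    if (is.na(fAfter[i])) flag[i] <- "fit_failed"
  }
  if (all(flag == "fit_failed")) stop("all sweep fits failed")

  apparent <- ifelse(is.na(fAfter), NA_real_,
                     massFromFrequencyShift(springConstant, fBefore,
                                            ifelse(is.na(fAfter), fBefore, fAfter)))
  corrected <- ifelse(is.na(apparent), NA_real_,
                      apparent / modeShape(positions)^2)
  flag[!is.na(apparent) & apparent < 0 & flag == "ok"] <- "negative_mass"

  if (!is.null(smoothWindow)) {
    w <- as.integer(smoothWindow)
    if (w %% 2L == 0L || w < 3L) stop("smoothWindow must be an odd integer >= 3")
    corrected <- stats::runmed(corrected, w, endrule = "keep")
  }
  data.frame(time_s = times, f_after_hz = fAfter,
             apparent_mass_kg = apparent, corrected_mass_kg = corrected,
             flag = flag)
}

#' Apply the mass readout to a per-cell measurement table
#'
#' Row-wise eigenfrequency-pair bookkeeping for measurement tables read by
#' [readMeasurementCsv()]: apparent mass, position-corrected mass and a
#' quality flag per row.
#'
#' @param measurements data.frame with columns `spring_constant_n_per_m`,
#'   `f_before_hz`, `f_after_hz`, `position_fraction` (and optionally
#'   `time_s`).
#' @param cutoff position cutoff passed to [correctForPosition()].
#' @return The input with columns `apparent_mass_kg`, `corrected_mass_kg`
#'   and `flag` appended.
#' @export
measureMasses <- function(measurements, cutoff = 0.2) {
  need <- c("spring_constant_n_per_m", "f_before_hz", "f_after_hz",
            "position_fraction")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  m <- massFromFrequencyShift(measurements$spring_constant_n_per_m,
                              measurements$f_before_hz,
                              measurements$f_after_hz)
  corrected <- correctForPosition(m, measurements$position_fraction,
                                  cutoff = cutoff)
  measurements$apparent_mass_kg <- m
  measurements$corrected_mass_kg <- corrected
  measurements$flag <- ifelse(m < 0, "negative_mass", "ok")
  measurements
}
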