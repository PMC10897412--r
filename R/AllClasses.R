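# Central S4 classes. All quantities are SI internally (Hz, kg, N/m, N s/m);
# kHz/ng appear only at I/O boundaries.

.rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.xmin)

#' Lumped-mass model of the resonating microcantilever
#'
#' The cantilever's first flexural mode is modelled as a driven, damped
#' point-mass oscillator (a Kelvin-Voigt element): spring constant `k`,
#' modal mass `m = k / (4 pi^2 f0^2)` and damping `c = sqrt(k m) / Q`. The
#' user supplies the three measurable quantities (spring constant,
#' eigenfrequency in liquid, quality factor); mass and damping are derived.
#'
#' @slot springConstant spring constant in N/m.
#' @slot eigenfrequency natural frequency f0 in Hz.
#' @slot qualityFactor dimensionless Q (around 3 for rectangular levers in
#'   liquid).
#'
#' @seealso [CantileverModel()] for construction, [frequencyResponse()],
#'   [simulateApparentMass()].
#' @export
setClass("CantileverModel",
  representation(
    springConstant = "numeric",
    eigenfrequency = "numeric",
    qualityFactor = "numeric"
  )
)

setValidity("CantileverModel", function(object) {
  v <- c(object@springConstant, object@eigenfrequency, object@qualityFactor)
  if (length(object@springConstant) != 1L || length(object@eigenfrequency) != 1L ||
      length(object@qualityFactor) != 1L) {
    return("springConstant, eigenfrequency and qualityFactor must be scalars")
  }
  if (any(!is.finite(v)) || any(v <= 0)) {
    return("springConstant, eigenfrequency and qualityFactor must be finite and > 0")
  }
  TRUE
})

#' Construct a cantilever model
#'
#' @param springConstant spring constant in N/m (> 0).
#' @param eigenfrequency first-mode eigenfrequency in Hz (> 0).
#' @param qualityFactor dimensionless quality factor (> 0).
#' @return A [CantileverModel-class] object.
#' @examples
#' cant <- CantileverModel(springConstant = 8, eigenfrequency = 75e3,
#'                         qualityFactor = 3)
#' modalMass(cant)  # kg
#' @export
CantileverModel <- function(springConstant, eigenfrequency, qualityFactor) {
  new("CantileverModel",
    springConstant = as.numeric(springConstant),
    eigenfrequency = as.numeric(eigenfrequency),
    qualityFactor = as.numeric(qualityFactor)
  )
}

#' @rdname springConstant
#' @export
setMethod("springConstant", "CantileverModel", function(x) x@springConstant)

#' @rdname eigenfrequency
#' @export
setMethod("eigenfrequency", "CantileverModel", function(x) x@eigenfrequency)

#' @rdname qualityFactor
#' @export
setMethod("qualityFactor", "CantileverModel", function(x) x@qualityFactor)

#' @rdname modalMass
#' @export
setMethod("modalMass", "CantileverModel", function(x) {
  x@springConstant / (4 * pi^2 * x@eigenfrequency^2)
})

#' @rdname dampingCoefficient
#' @export
setMethod("dampingCoefficient", "CantileverModel", function(x) {
  sqrt(x@springConstant * modalMass(x)) / x@qualityFactor
})

setMethod("show", "CantileverModel", function(object) {
  cat("CantileverModel\n")
  cat(sprintf("  spring constant : %.4g N/m\n", object@springConstant))
  cat(sprintf("  eigenfrequency  : %.4f kHz\n", object@eigenfrequency / 1e3))
  cat(sprintf("  quality factor  : %.3g\n", object@qualityFactor))
  cat(sprintf("  modal mass      : %.4g ng (derived)\n", modalMass(object) * 1e12))
  cat(sprintf("  damping         : %.4g N s/m (derived)\n",
              dampingCoefficient(object)))
  invisible(NULL)
})

#' Lumped mechanical model of the attached cell
#'
#' The cell is a point mass coupled to the cantilever through a Kelvin-Voigt
#' element (spring `k_cell` in parallel with damper `c_cell`), forming a
#' 2-degree-of-freedom system with the cantilever. Equivalent
#' parametrisations: `(stiffness, damping)` or `(eigenfrequency,
#' qualityFactor)` with `k = 4 pi^2 m f^2`, `c = sqrt(k m) / Q`. Optionally
#' the stiffness decomposes as `k_cell = E * F(S)` (elastic modulus times a
#' geometry-dependent shape factor with units of length) and the damping as
#' `c_cell = mu * F(S)`.
#'
#' @slot mass cell mass in kg (> 0).
#' @slot stiffness coupling stiffness k_cell in N/m (>= 0).
#' @slot damping coupling damping c_cell in N s/m (>= 0).
#' @slot elasticModulus optional Young's modulus E in Pa (NA if unset).
#' @slot shapeFactor optional shape factor F(S) in m (NA if unset).
#' @slot viscosity optional viscosity scale mu in Pa s (NA if unset).
#'
#' @seealso [CellMechanicalModel()], [effectiveDynamicMass()],
#'   [readoutAccuracy()].
#' @export
setClass("CellMechanicalModel",
  representation(
    mass = "numeric",
    stiffness = "numeric",
    damping = "numeric",
    elasticModulus = "numeric",
    shapeFactor = "numeric",
    viscosity = "numeric"
  ),
  prototype(elasticModulus = NA_real_, shapeFactor = NA_real_,
            viscosity = NA_real_)
)

setValidity("CellMechanicalModel", function(object) {
  if (!is.finite(object@mass) || object@mass <= 0) {
    return("mass must be finite and > 0")
  }
  if (!is.finite(object@stiffness) || object@stiffness < 0) {
    return("stiffness must be finite and >= 0")
  }
  if (!is.finite(object@damping) || object@damping < 0) {
    return("damping must be finite and >= 0")
  }
  if (is.finite(object@elasticModulus) && is.finite(object@shapeFactor)) {
    k <- object@elasticModulus * object@shapeFactor
    if (.rel_err(object@stiffness, k) > 1e-9) {
      return("stiffness is inconsistent with elasticModulus * shapeFactor")
    }
  }
  if (is.finite(object@viscosity) && is.finite(object@shapeFactor)) {
    cc <- object@viscosity * object@shapeFactor
    if (.rel_err(object@damping, cc) > 1e-9) {
      return("damping is inconsistent with viscosity * shapeFactor")
    }
  }
  TRUE
})

#' Construct a cell mechanical model
#'
#' Supply the mass plus either `(stiffness, damping)`, or `(eigenfrequency,
#' qualityFactor)`, or `(elasticModulus, shapeFactor)` for the stiffness and
#' `(viscosity, shapeFactor)` for the damping. Mixed forms are allowed as
#' long as they are not contradictory.
#'
#' @param mass cell mass in kg (> 0).
#' @param eigenfrequency whole-cell eigenfrequency in Hz; converted to
#'   stiffness via `k = 4 pi^2 m f^2`.
#' @param qualityFactor whole-cell quality factor; converted to damping via
#'   `c = sqrt(k m) / Q` (requires a positive stiffness).
#' @param stiffness coupling stiffness k_cell in N/m.
#' @param damping coupling damping c_cell in N s/m.
#' @param elasticModulus Young's modulus E in Pa (used with `shapeFactor`).
#' @param shapeFactor shape factor F(S) in m.
#' @param viscosity viscosity scale mu in Pa s (used with `shapeFactor`).
#' @return A [CellMechanicalModel-class] object.
#' @examples
#' # the population-average HeLa cell of the readout-curve fit
#' hela <- CellMechanicalModel(mass = 3.14e-12, eigenfrequency = 14.4e3,
#'                             qualityFactor = 0.3)
#' couplingStiffness(hela)  # ~0.0257 N/m
#' @export
CellMechanicalModel <- function(mass, eigenfrequency = NULL,
                                qualityFactor = NULL, stiffness = NULL,
                                damping = NULL, elasticModulus = NULL,
                                shapeFactor = NULL, viscosity = NULL) {
  mass <- as.numeric(mass)
  if (!is.finite(mass) || mass <= 0) stop("mass must be finite and > 0")

  k <- stiffness
  if (is.null(k) && !is.null(eigenfrequency)) {
    k <- 4 * pi^2 * mass * as.numeric(eigenfrequency)^2
  }
  if (is.null(k) && !is.null(elasticModulus) && !is.null(shapeFactor)) {
    k <- as.numeric(elasticModulus) * as.numeric(shapeFactor)
  }
  if (is.null(k)) k <- 0

  cc <- damping
  if (is.null(cc) && !is.null(qualityFactor)) {
    if (k <= 0) stop("qualityFactor needs a positive coupling stiffness")
    cc <- sqrt(k * mass) / as.numeric(qualityFactor)
  }
  if (is.null(cc) && !is.null(viscosity) && !is.null(shapeFactor)) {
    cc <- as.numeric(viscosity) * as.numeric(shapeFactor)
  }
  if (is.null(cc)) cc <- 0

  new("CellMechanicalModel",
    mass = mass, stiffness = as.numeric(k), damping = as.numeric(cc),
    elasticModulus = if (is.null(elasticModulus)) NA_real_ else as.numeric(elasticModulus),
    shapeFactor = if (is.null(shapeFactor)) NA_real_ else as.numeric(shapeFactor),
    viscosity = if (is.null(viscosity)) NA_real_ else as.numeric(viscosity)
  )
}

#' @rdname cellMass
#' @export
setMethod("cellMass", "CellMechanicalModel", function(x) x@mass)

#' @rdname couplingStiffness
#' @export
setMethod("couplingStiffness", "CellMechanicalModel", function(x) x@stiffness)

#' @rdname couplingDamping
#' @export
setMethod("couplingDamping", "CellMechanicalModel", function(x) x@damping)

#' @rdname eigenfrequency
#' @export
setMethod("eigenfrequency", "CellMechanicalModel", function(x) {
  sqrt(x@stiffness / x@mass) / (2 * pi)
})

#' @rdname qualityFactor
#' @export
setMethod("qualityFactor", "CellMechanicalModel", function(x) {
  if (x@damping == 0) return(Inf)
  sqrt(x@stiffness * x@mass) / x@damping
})

setMethod("show", "CellMechanicalModel", function(object) {
  cat("CellMechanicalModel\n")
  cat(sprintf("  mass            : %.4g ng\n", object@mass * 1e12))
  cat(sprintf("  stiffness k_cell: %.4g N/m\n", object@stiffness))
  cat(sprintf("  damping c_cell  : %.4g N s/m\n", object@damping))
  cat(sprintf("  eigenfrequency  : %.4f kHz (derived)\n",
              eigenfrequency(object) / 1e3))
  cat(sprintf("  quality factor  : %.3g (derived)\n", qualityFactor(object)))
  if (is.finite(object@elasticModulus)) {
    cat(sprintf("  Young's modulus : %.4g Pa\n", object@elasticModulus))
  }
  if (is.finite(object@shapeFactor)) {
    cat(sprintf("  shape factor    : %.4g m\n", object@shapeFactor))
  }
  invisible(NULL)
})

#' Frequency-sweep spectrum of the cantilever end
#'
#' A strictly increasing actuation-frequency grid with the complex
#' displacement response of the cantilever free end. Amplitude and phase are
#' the modulus and argument of the complex response. The time convention is
#' `e^{+i omega t}`, so viscous dissipation enters as `+ i omega c`.
#'
#' @slot frequency actuation frequencies in Hz, strictly increasing.
#' @slot response complex displacement in m, same length as `frequency`.
#' @slot driveAmplitude optional drive scale in m (NA if unset).
#'
#' @seealso [SweepSpectrum()], [frequencyResponse()], [fitSweep()].
#' @export
setClass("SweepSpectrum",
  representation(
    frequency = "numeric",
    response = "complex",
    driveAmplitude = "numeric"
  ),
  prototype(driveAmplitude = NA_real_)
)

setValidity("SweepSpectrum", function(object) {
  if (length(object@frequency) != length(object@response)) {
    return("frequency and response must have the same length")
  }
  if (length(object@frequency) < 1L) return("empty frequency grid")
  if (any(!is.finite(object@frequency)) || any(object@frequency < 0)) {
    return("frequencies must be finite and non-negative")
  }
  if (any(diff(object@frequency) <= 0)) {
    return("frequency grid must be strictly increasing")
  }
  if (any(!is.finite(Re(object@response))) || any(!is.finite(Im(object@response)))) {
    return("response must be finite")
  }
  TRUE
})

#' Construct a sweep spectrum
#'
#' @param frequency strictly increasing frequencies in Hz.
#' @param response complex response in m, or a real amplitude when `phase`
#'   is supplied separately.
#' @param phase optional phase in rad, combined as
#'   `response * exp(1i * phase)` when `response` is real.
#' @param driveAmplitude optional drive scale in m.
#' @return A [SweepSpectrum-class] object.
#' @export
SweepSpectrum <- function(frequency, response, phase = NULL,
                          driveAmplitude = NA_real_) {
  if (!is.complex(response)) {
    response <- if (is.null(phase)) complex(real = response, imaginary = 0)
                else as.numeric(response) * exp(1i * as.numeric(phase))
  }
  new("SweepSpectrum", frequency = as.numeric(frequency),
      response = response, driveAmplitude = as.numeric(driveAmplitude))
}

#' @rdname frequencies
#' @export
setMethod("frequencies", "SweepSpectrum", function(x) x@frequency)

#' @rdname responses
#' @export
setMethod("responses", "SweepSpectrum", function(x) x@response)

#' @rdname amplitude
#' @export
setMethod("amplitude", "SweepSpectrum", function(x) Mod(x@response))

#' @rdname phase
#' @export
setMethod("phase", "SweepSpectrum", function(x) Arg(x@response))

setMethod("show", "SweepSpectrum", function(object) {
  n <- length(object@frequency)
  cat("SweepSpectrum\n")
  cat(sprintf("  %d points, %.4g - %.4g kHz\n", n,
              object@frequency[1] / 1e3, object@frequency[n] / 1e3))
  cat(sprintf("  peak amplitude %.4g nm at %.4g kHz\n",
              max(Mod(object@response)) * 1e9,
              object@frequency[which.max(Mod(object@response))] / 1e3))
  invisible(NULL)
})

#' Length of a sweep spectrum
#' @param x a [SweepSpectrum-class].
#' @return Number of frequency points.
#' @export
setMethod("length", "SweepSpectrum", function(x) length(x@frequency))

#' Result of the ensemble readout-curve fit
#'
#' Holds the population-average cell eigenfrequency and quality factor
#' estimated by nonlinear least squares of the readout-accuracy law to
#' (cantilever eigenfrequency, relative mass) points, with Jacobian-based
#' standard errors, the binned summaries, and diagnostics.
#'
#' @slot fCell fitted cell eigenfrequency in Hz.
#' @slot qCell fitted cell quality factor.
#' @slot fCellSe standard error of `fCell` in Hz.
#' @slot qCellSe standard error of `qCell`.
#' @slot covariance 2x2 covariance matrix of (fCell, qCell).
#' @slot nPoints number of points used in the fit.
#' @slot bins data.frame of binned summaries (centers, means, SDs, counts).
#' @slot flags character vector, e.g. `"rigid_limit"` for flat-at-1 data.
#' @slot converged logical.
#' @slot residualSS residual sum of squares at the optimum.
#'
#' @seealso [fitReadoutCurve()].
#' @export
setClass("EnsembleFitResult",
  representation(
    fCell = "numeric", qCell = "numeric",
    fCellSe = "numeric", qCellSe = "numeric",
    covariance = "matrix", nPoints = "integer",
    bins = "data.frame", flags = "character",
    converged = "logical", residualSS = "numeric"
  )
)

setValidity("EnsembleFitResult", function(object) {
  if (is.finite(object@fCellSe) && object@fCellSe < 0) return("fCellSe must be >= 0")
  if (is.finite(object@qCellSe) && object@qCellSe < 0) return("qCellSe must be >= 0")
  TRUE
})

#' @rdname eigenfrequency
#' @export
setMethod("eigenfrequency", "EnsembleFitResult", function(x) x@fCell)

#' @rdname qualityFactor
#' @export
setMethod("qualityFactor", "EnsembleFitResult", function(x) x@qCell)

setMethod("show", "EnsembleFitResult", function(object) {
  cat("EnsembleFitResult\n")
  cat(sprintf("  f_cell : %.2f +/- %.2f kHz\n",
              object@fCell / 1e3, object@fCellSe / 1e3))
  cat(sprintf("  Q_cell : %.3f +/- %.3f\n", object@qCell, object@qCellSe))
  cat(sprintf("  n = %d points, residual SS = %.4g\n",
              object@nPoints, object@residualSS))
  if (length(object@flags)) {
    cat("  flags  :", paste(object@flags, collapse = ", "), "\n")
  }
  invisible(NULL)
})
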