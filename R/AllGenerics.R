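#' @import methods
NULL

#' Spring constant of a resonator
#'
#' @param x a [CantileverModel-class] object.
#' @return Spring constant in N/m.
#' @export
setGeneric("springConstant", function(x) standardGeneric("springConstant"))

#' Eigenfrequency of a mechanical model
#'
#' Natural (undamped) resonance frequency, in Hz. For a
#' [CellMechanicalModel-class] this is the whole-cell eigenfrequency
#' f_cell = sqrt(k_cell / m_cell) / (2 * pi), the inversion of the
#' stiffness law k = 4 pi^2 m f^2.
#'
#' @param x a [CantileverModel-class] or [CellMechanicalModel-class].
#' @return Frequency in Hz (0 for a cell with no coupling stiffness).
#' @export
setGeneric("eigenfrequency", function(x) standardGeneric("eigenfrequency"))

#' Quality factor of a mechanical model
#'
#' Dimensionless ratio Q = sqrt(k * m) / c; low values mean strong viscous
#' damping (whole HeLa cells here have Q around 0.3).
#'
#' @param x a [CantileverModel-class] or [CellMechanicalModel-class].
#' @return Dimensionless quality factor (`Inf` for an undamped model).
#' @export
setGeneric("qualityFactor", function(x) standardGeneric("qualityFactor"))

#' Modal mass of the cantilever
#'
#' The effective point mass of the first flexural mode,
#' m = k / (4 pi^2 f^2).
#'
#' @param x a [CantileverModel-class].
#' @return Mass in kg.
#' @export
setGeneric("modalMass", function(x) standardGeneric("modalMass"))

#' Damping coefficient of the cantilever
#'
#' c = sqrt(k * m) / Q for the lumped Kelvin-Voigt cantilever model.
#'
#' @param x a [CantileverModel-class].
#' @return Damping coefficient in N s/m.
#' @export
setGeneric("dampingCoefficient", function(x) standardGeneric("dampingCoefficient"))

#' Cell mass
#'
#' @param x a [CellMechanicalModel-class].
#' @return Mass in kg.
#' @export
setGeneric("cellMass", function(x) standardGeneric("cellMass"))

#' Coupling stiffness of the cell attachment
#'
#' Whole-cell spring constant k_cell of the Kelvin-Voigt element linking the
#' cell point mass to the cantilever; k_cell = E * F(S) when an elastic
#' modulus and a shape factor are supplied.
#'
#' @param x a [CellMechanicalModel-class].
#' @return Stiffness in N/m.
#' @export
setGeneric("couplingStiffness", function(x) standardGeneric("couplingStiffness"))

#' Coupling damping of the cell attachment
#'
#' Damping coefficient c_cell of the Kelvin-Voigt element; c_cell = mu * F(S)
#' when a viscosity scale and a shape factor are supplied.
#'
#' @param x a [CellMechanicalModel-class].
#' @return Damping coefficient in N s/m.
#' @export
setGeneric("couplingDamping", function(x) standardGeneric("couplingDamping"))

#' Frequency grid of a sweep
#'
#' @param x a [SweepSpectrum-class].
#' @return Strictly increasing actuation frequencies in Hz.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' Complex response of a sweep
#'
#' @param x a [SweepSpectrum-class].
#' @return Complex displacement of the cantilever end, in m.
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))

#' Oscillation amplitude of a sweep
#'
#' @param x a [SweepSpectrum-class].
#' @return Modulus of the complex response, in m.
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' Oscillation phase of a sweep
#'
#' @param x a [SweepSpectrum-class].
#' @return Argument of the complex response, in rad.
#' @export
setGeneric("phase", function(x) standardGeneric("phase"))
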