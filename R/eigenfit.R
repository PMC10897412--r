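# Ensemble inference: bin (f_cant, m_app/m_real) points, fit the closed-form
# readout-accuracy law to extract the population-average cell eigenfrequency
# and Q-factor, and derive whole-cell stiffness and Young's modulus.

.ensure_ratio <- function(points) {
  if (!is.data.frame(points)) stop("points must be a data.frame")
  if (!"f_cant_hz" %in% names(points)) stop("missing column: f_cant_hz")
  if (!"ratio" %in% names(points)) {
    if (!all(c("m_app_kg", "m_real_kg") %in% names(points))) {
      stop("need either a 'ratio' column or 'm_app_kg' and 'm_real_kg'")
    }
    if (any(points$m_real_kg <= 0)) stop("m_real_kg must be > 0")
    points$ratio <- points$m_app_kg / points$m_real_kg
  }
  if (any(!is.finite(points$ratio))) stop("ratios must be finite")
  if (any(!is.finite(points$f_cant_hz)) || any(points$f_cant_hz <= 0)) {
    stop("f_cant_hz must be finite and > 0")
  }
  points
}

#' Bin ensemble points over the cantilever-frequency axis
#'
#' Splits the `f_cant` range into `nBins` equidistant bins on the linear
#' frequency axis and summarises the relative mass per bin (as the green
#' bin means drawn on the readout curve).
#'
#' @param points data.frame with `f_cant_hz` and either `ratio` or the pair
#'   `m_app_kg`, `m_real_kg`.
#' @param nBins number of equidistant bins (default 7).
#' @return data.frame with `center_hz`, `mean_ratio`, `sd_ratio`, `n` for
#'   each non-empty bin (empty bins are dropped with a message).
#' @export
binEnsemble <- function(points, nBins = 7) {
  points <- .ensure_ratio(points)
  nBins <- as.integer(nBins)
  if (is.na(nBins) || nBins < 1L) stop("nBins must be a positive integer")
  f <- points$f_cant_hz
  lo <- min(f); hi <- max(f)
  if (lo == hi) stop("all points share the same cantilever frequency")
  breaks <- seq(lo, hi, length.out = nBins + 1L)
  idx <- findInterval(f, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  out <- do.call(rbind, lapply(seq_len(nBins), function(b) {
    sel <- idx == b
    if (!any(sel)) return(NULL)
    data.frame(center_hz = (breaks[b] + breaks[b + 1L]) / 2,
               mean_ratio = mean(points$ratio[sel]),
               sd_ratio = stats::sd(points$ratio[sel]),
               n = sum(sel))
  }))
  dropped <- nBins - nrow(out)
  if (dropped > 0L) message(dropped, " empty bin(s) dropped")
  out
}

# model + numeric Jacobian wrt (fCell, qCell) on the natural scale
.readout_model <- function(fCant, fCell, qCell) {
  readoutAccuracy(fCant, fCell, qCell)
}

.readout_jacobian <- function(fCant, fCell, qCell) {
  hf <- fCell * 1e-6
  hq <- qCell * 1e-6
  cbind(
    (.readout_model(fCant, fCell + hf, qCell) -
       .readout_model(fCant, fCell - hf, qCell)) / (2 * hf),
    (.readout_model(fCant, fCell, qCell + hq) -
       .readout_model(fCant, fCell, qCell - hq)) / (2 * hq)
  )
}

#' Fit the readout-accuracy law to an ensemble
#'
#' Nonlinear least squares of the closed-form readout-accuracy curve in
#' `(f_cell, Q_cell)` to (cantilever eigenfrequency, relative mass) points.
#' Optimisation runs in log-parameters for positivity, with seeded
#' multi-start (5 starts) to avoid local minima. The default weighting,
#' `"relative"`, is iteratively reweighted least squares with weights
#' `1/mu^2` - the quasi-likelihood estimator when the scatter is
#' multiplicative with constant coefficient of variation, which is how the
#' measured relative masses disperse; `"none"` gives plain unweighted least
#' squares, and `"inverse_variance"` weights binned means by their standard
#' errors (`fitOn = "binned"` only). Standard errors come from the
#' Jacobian-based covariance scaled by the residual variance.
#'
#' The two parameters are strongly correlated: away from the bend at
#' `f_cant ~ f_cell` the curve constrains mainly the combination
#' `f_cell^2 (1/Q^2 - 1)`, so single-dataset estimates wander along that
#' ridge while remaining median-unbiased over replicates. Expect wide
#' standard errors at realistic noise; they are reported honestly.
#'
#' Flat-at-1 data (rigid payloads such as glass beads: the readout fraction
#' carries no information about `f_cell` beyond a lower bound) are detected
#' by comparing the fitted residual sum of squares against the constant-1
#' model; such fits carry the `"rigid_limit"` flag and the reported
#' `f_cell` must be read as a lower bound, not a point estimate.
#'
#' @param points data.frame with `f_cant_hz` and `ratio` (or `m_app_kg` +
#'   `m_real_kg`); at least 5 points.
#' @param fitOn `"raw"` (default) or `"binned"`.
#' @param nBins bins used for the binned summaries (and the binned fit).
#' @param weighting `"relative"` (default, IRLS with weights `1/mu^2`),
#'   `"none"`, or `"inverse_variance"` (binned fit only).
#' @param bounds list with `fCell` (Hz) and `qCell` ranges; defaults
#'   `c(500, 5e5)` Hz and `c(0.01, 100)`.
#' @param seed integer seed for the multi-start jitter.
#' @return An [EnsembleFitResult-class].
#' @examples
#' pts <- data.frame(f_cant_hz = seq(3e3, 110e3, length.out = 50))
#' pts$ratio <- readoutAccuracy(pts$f_cant_hz, 20e3, 0.5)
#' fit <- fitReadoutCurve(pts, seed = 1)
#' eigenfrequency(fit) / 1e3  # 20 kHz recovered
#' @export
fitReadoutCurve <- function(points, fitOn = c("raw", "binned"), nBins = 7,
                            weighting = c("relative", "none",
                                          "inverse_variance"),
                            bounds = list(fCell = c(500, 5e5),
                                          qCell = c(0.01, 100)),
                            seed = 1) {
  fitOn <- match.arg(fitOn)
  weighting <- match.arg(weighting)
  points <- .ensure_ratio(points)
  if (nrow(points) < 5L) stop("need at least 5 points")
  bins <- binEnsemble(points, nBins)

  if (fitOn == "raw") {
    if (weighting == "inverse_variance") {
      stop("inverse_variance weighting needs fitOn = 'binned'")
    }
    f <- points$f_cant_hz
    y <- points$ratio
  } else {
    f <- bins$center_hz
    y <- bins$mean_ratio
  }
  w <- if (weighting == "inverse_variance") {
    v <- bins$sd_ratio^2 / bins$n
    ok <- is.finite(v) & v > 0
    ifelse(ok, 1 / v, if (any(ok)) max(1 / v[ok]) else 1)
  } else rep(1, length(y))

  lb <- log(c(bounds$fCell[1], bounds$qCell[1]))
  ub <- log(c(bounds$fCell[2], bounds$qCell[2]))
  fmax <- max(f)
  base_starts <- list(c(0.10 * fmax, 0.3), c(0.30 * fmax, 0.3),
                      c(0.05 * fmax, 1), c(0.50 * fmax, 0.1),
                      c(0.20 * fmax, 3))
  starts <- withr::with_seed(seed, lapply(base_starts, function(s) {
    pmin(pmax(log(s) + stats::rnorm(2, 0, 0.05), lb), ub)
  }))

  run_multistart <- function(wts) {
    obj <- function(p) {
      mu <- .readout_model(f, exp(p[1]), exp(p[2]))
      sum(wts * (y - mu)^2)
    }
    best <- NULL
    for (p0 in starts) {
      fit <- tryCatch(
        stats::optim(p0, obj, method = "L-BFGS-B", lower = lb, upper = ub,
                     control = list(maxit = 500, factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop("readout-curve fit failed from all starts")
    best
  }

  best <- run_multistart(w)
  if (weighting == "relative") {
    # IRLS: weights from the current curve, floored so the decaying
    # high-frequency tail cannot dominate; converges in a few passes
    for (iter in 1:3) {
      mu <- .readout_model(f, exp(best$par[1]), exp(best$par[2]))
      w <- 1 / pmax(mu, 0.05)^2
      best <- run_multistart(w)
    }
  }
  # high-precision polish at the final weights (L-BFGS-B stops at factr)
  obj_final <- function(p) {
    p <- pmin(pmax(p, lb), ub)
    mu <- .readout_model(f, exp(p[1]), exp(p[2]))
    sum(w * (y - mu)^2)
  }
  polish <- stats::optim(best$par, obj_final, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 2000))
  if (polish$value <= best$value) {
    best$par <- pmin(pmax(polish$par, lb), ub)
    best$value <- polish$value
  }

  fCell <- exp(best$par[1])
  qCell <- exp(best$par[2])
  rss <- best$value
  n <- length(y)

  # covariance on the natural scale from the Jacobian at the optimum
  J <- .readout_jacobian(f, fCell, qCell) * sqrt(w)
  dof <- max(n - 2L, 1L)
  sigma2 <- rss / dof
  covm <- tryCatch(sigma2 * solve(crossprod(J)),
                   error = function(e) matrix(NA_real_, 2, 2))
  ses <- suppressWarnings(sqrt(diag(covm)))

  flags <- character(0)
  ss_flat <- sum(w * (y - 1)^2)
  at_upper <- fCell >= 0.99 * bounds$fCell[2]
  if (ss_flat <= 1.05 * rss || at_upper) flags <- c(flags, "rigid_limit")

  new("EnsembleFitResult",
      fCell = fCell, qCell = qCell,
      fCellSe = ses[1], qCellSe = ses[2],
      covariance = covm, nPoints = as.integer(nrow(points)),
      bins = bins, flags = flags,
      converged = best$convergence == 0, residualSS = rss)
}

#' Whole-cell spring constant from the cell eigenfrequency
#'
#' `k_cell = 4 pi^2 m_cell f_cell^2`: the stiffness of the entire cell seen
#' as a lumped oscillator of mass `m_cell` resonating at `f_cell`.
#'
#' @param fCell cell eigenfrequency in Hz (>= 0, vectorised).
#' @param mass cell mass in kg (> 0).
#' @return Stiffness in N/m.
#' @examples
#' cellStiffness(14.4e3, 3.14e-12)  # ~0.0257 N/m, i.e. 0.03 at 1 sig fig
#' @export
cellStiffness <- function(fCell, mass) {
  fCell <- as.numeric(fCell)
  mass <- as.numeric(mass)
  if (any(!is.finite(fCell)) || any(fCell < 0)) stop("fCell must be >= 0")
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("mass must be > 0")
  4 * pi^2 * mass * fCell^2
}

#' Young's modulus from the whole-cell stiffness
#'
#' The whole-cell spring constant decomposes as `k_cell = E * F(S)` with a
#' geometry-dependent shape factor `F(S)` (units of length, obtained from
#' finite-element modelling of the imaged cell shape - it must be supplied
#' by the user, this package does not compute it).
#'
#' @param stiffness whole-cell spring constant in N/m (>= 0).
#' @param shapeFactor shape factor F(S) in m (> 0).
#' @return Young's modulus E in Pa.
#' @examples
#' youngsModulus(0.02571, 1.978e-5)  # ~1.3 kPa
#' @export
youngsModulus <- function(stiffness, shapeFactor = NULL) {
  if (is.null(shapeFactor) || !length(shapeFactor) || all(is.na(shapeFactor))) {
    stop("FEM-derived shape factor required to convert stiffness to a modulus")
  }
  stiffness <- as.numeric(stiffness)
  shapeFactor <- as.numeric(shapeFactor)
  if (any(!is.finite(stiffness)) || any(stiffness < 0)) {
    stop("stiffness must be >= 0")
  }
  if (any(!is.finite(shapeFactor)) || any(shapeFactor <= 0)) {
    stop("shapeFactor must be > 0")
  }
  stiffness / shapeFactor
}
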