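# Ensemble inference: binning, readout-curve fitting, and the derived
# whole-cell stiffness and modulus.

test_that("equidistant binning matches an independent histogram", {
  # one point per bin
  pts <- data.frame(f_cant_hz = seq(10e3, 70e3, by = 10e3),
                    ratio = c(1, .9, .7, .5, .4, .3, .25))
  b <- binEnsemble(pts, 7)
  expect_equal(nrow(b), 7)
  expect_equal(b$mean_ratio, pts$ratio)
  expect_equal(b$n, rep(1L, 7))
  # seeded ensemble vs an independent cut()/tapply() implementation
  pts <- makeEnsembleExperiment(seed = 21)
  b <- binEnsemble(pts, 7)
  br <- seq(min(pts$f_cant_hz), max(pts$f_cant_hz), length.out = 8)
  grp <- cut(pts$f_cant_hz, br, include.lowest = TRUE)
  expect_equal(b$mean_ratio, as.numeric(tapply(pts$ratio, grp, mean)))
  expect_equal(b$n, as.integer(table(grp)))
  expect_error(binEnsemble(pts, 0), "nBins")
  expect_error(binEnsemble(data.frame(f_cant_hz = rep(5e4, 10), ratio = 1)),
               "same cantilever frequency")
})

test_that("noiseless readout curves are recovered exactly", {
  pts <- data.frame(f_cant_hz = seq(3e3, 110e3, length.out = 50))
  pts$ratio <- readoutAccuracy(pts$f_cant_hz, 20e3, 0.5)
  fit <- fitReadoutCurve(pts, seed = 1)
  expect_equal(eigenfrequency(fit), 20e3, tolerance = 1e-6)
  expect_equal(qualityFactor(fit), 0.5, tolerance = 1e-6)
  expect_true(fit@converged)
  expect_length(fit@flags, 0)
  # the binned route carries the bin-center approximation (seven wide bins
  # over 3-110 kHz), so it only agrees coarsely even on clean data
  fitb <- fitReadoutCurve(pts, fitOn = "binned", seed = 1)
  expect_equal(eigenfrequency(fitb), 20e3, tolerance = 0.1)
  fitu <- fitReadoutCurve(pts, weighting = "none", seed = 1)
  expect_equal(eigenfrequency(fitu), 20e3, tolerance = 1e-6)
  expect_error(fitReadoutCurve(pts[1:3, ]), "at least 5")
})

test_that("estimator is consistent as noise vanishes and n grows", {
  pop <- populationSpec(noiseCv = 0.01, massSd = 0)
  pts <- makeEnsembleExperiment(pop = pop, n = 1e4, seed = 9)
  fit <- fitReadoutCurve(pts, seed = 9)
  expect_equal(eigenfrequency(fit), 14.4e3, tolerance = 5e-3)
  expect_equal(qualityFactor(fit), 0.3, tolerance = 5e-3)
})

test_that("recovery is median-unbiased over replicated ensembles", {
  # the Fig. 5b-scale design: the single-dataset estimates ride the
  # f^2(1/Q^2-1) ridge, but the median over replicates must stay tight
  res <- vapply(1:200, function(s) {
    fit <- fitReadoutCurve(makeEnsembleExperiment(seed = s), seed = s)
    c(fit@fCell, fit@qCell)
  }, numeric(2))
  expect_lt(abs(stats::median(res[1, ]) - 14.4e3) / 14.4e3, 0.02)
  expect_lt(abs(stats::median(res[2, ]) - 0.3), 0.03)
})

test_that("scale equivariance: rescaling frequencies rescales f_cell only", {
  withr::with_seed(13, {
    f <- stats::runif(60, 3e3, 110e3)
    y <- readoutAccuracy(f, 14.4e3, 0.3) *
      stats::rlnorm(60, -0.02, 0.2)
  })
  fit1 <- fitReadoutCurve(data.frame(f_cant_hz = f, ratio = y), seed = 2)
  s <- 2.5
  fit2 <- fitReadoutCurve(data.frame(f_cant_hz = s * f, ratio = y), seed = 2)
  expect_equal(eigenfrequency(fit2) / eigenfrequency(fit1), s,
               tolerance = 1e-4)
  expect_equal(qualityFactor(fit2), qualityFactor(fit1), tolerance = 1e-4)
})

test_that("flat-at-1 rigid payload data raise the rigid_limit flag", {
  withr::with_seed(3, {
    pts <- data.frame(f_cant_hz = seq(3e3, 110e3, length.out = 40),
                      ratio = 1 + stats::rnorm(40, 0, 0.01))
  })
  fit <- fitReadoutCurve(pts, seed = 1)
  expect_true("rigid_limit" %in% fit@flags)
  # a genuinely soft cell must not be flagged
  soft <- makeEnsembleExperiment(seed = 2)
  expect_false("rigid_limit" %in% fitReadoutCurve(soft, seed = 2)@flags)
})

test_that("standard errors are finite, positive and honest about the ridge", {
  fit <- fitReadoutCurve(makeEnsembleExperiment(seed = 14), seed = 14)
  expect_true(is.finite(fit@fCellSe) && fit@fCellSe > 0)
  expect_true(is.finite(fit@qCellSe) && fit@qCellSe > 0)
  # f_cell and Q trade off along the ridge f^2(1/Q^2 - 1) = const: at a
  # fixed tail amplitude a larger Q forces a larger f_cell, so the fitted
  # pair is strongly positively correlated
  rho <- fit@covariance[1, 2] /
    sqrt(fit@covariance[1, 1] * fit@covariance[2, 2])
  expect_gt(rho, 0.5)
})

test_that("whole-cell stiffness follows the quadratic frequency law", {
  k <- cellStiffness(14.4e3, 3.14e-12)
  expect_equal(k, 0.0257, tolerance = 1e-3)
  expect_identical(signif(k, 1), 0.03)
  expect_identical(cellStiffness(0, 1e-12), 0)
  expect_equal(cellStiffness(2 * 14.4e3, 3.14e-12) / k, 4, tolerance = 1e-12)
  expect_error(cellStiffness(14.4e3, 0), "mass")
})

test_that("Young's modulus needs the shape factor and scales reciprocally", {
  expect_equal(youngsModulus(0.02571, 1.978e-5), 1300, tolerance = 1e-3)
  expect_identical(youngsModulus(0, 1.978e-5), 0)
  expect_equal(youngsModulus(0.02571, 2 * 1.978e-5),
               youngsModulus(0.02571, 1.978e-5) / 2, tolerance = 1e-12)
  expect_error(youngsModulus(0.0257), "shape factor")
  expect_error(youngsModulus(0.0257, -1), "shapeFactor")
})
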