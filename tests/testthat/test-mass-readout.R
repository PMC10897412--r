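# Mass bookkeeping: the frequency-shift law, beam-position correction,
# sweep fitting, unit conversion and trajectories.

test_that("frequency-shift mass law matches its analytic inversion", {
  # f_after back-computed so that m = 3.14 ng at k = 8 N/m, f_before = 70 kHz
  fAfter <- 1 / sqrt(1 / 70e3^2 + 4 * pi^2 * 3.14e-12 / 8)
  expect_equal(fAfter, 67485, tolerance = 1e-4)
  expect_equal(massFromFrequencyShift(8, 70e3, fAfter), 3.14e-12,
               tolerance = 1e-12)
  expect_equal(massFromFrequencyShift(8, 70e3, 67485) * 1e12, 3.14,
               tolerance = 1e-3)
  # zero shift, zero mass
  expect_identical(massFromFrequencyShift(8, 70e3, 70e3), 0)
  # inverted shift gives a small negative mass (kept, not clipped)
  expect_lt(massFromFrequencyShift(8, 70e3, 70.1e3), 0)
  expect_error(massFromFrequencyShift(8, 0, 70e3), "frequencies")
  expect_error(massFromFrequencyShift(-8, 70e3, 69e3), "springConstant")
})

test_that("round trip and linearity of the mass law", {
  withr::with_seed(5, {
    for (i in 1:50) {
      k <- stats::runif(1, 0.1, 20)
      fb <- stats::runif(1, 3e3, 110e3)
      m <- 10^stats::runif(1, -13, -11)
      fa <- frequencyAfterAttachment(k, fb, m)
      expect_equal(massFromFrequencyShift(k, fb, fa), m, tolerance = 1e-10)
      # linear in spring constant
      expect_equal(massFromFrequencyShift(2 * k, fb, fa),
                   2 * massFromFrequencyShift(k, fb, fa), tolerance = 1e-12)
    }
  })
})

test_that("beam mode shape is normalised, clamped and strictly increasing", {
  expect_identical(modeShape(0), 0)
  expect_equal(modeShape(1), 1, tolerance = 1e-15)
  xi <- seq(0, 1, length.out = 200)
  expect_true(all(diff(modeShape(xi)) > 0))
  # closed-form evaluation at the worked point
  expect_equal(modeShape(0.8), 0.7255, tolerance = 1e-4)
  expect_equal(1 / modeShape(0.8)^2, 1.900, tolerance = 1e-4)
  expect_error(modeShape(1.2), "\\[0, 1\\]")
})

test_that("position correction divides by the squared mode shape", {
  expect_identical(correctForPosition(2.5e-12, 1), 2.5e-12)
  expect_equal(correctForPosition(1e-12, 0.8) * 1e12, 1.900, tolerance = 1e-4)
  # corrections beyond the cutoff are refused
  expect_error(correctForPosition(1e-12, 0.1), "refused")
  # monotone: closer to the clamp means larger corrected mass
  xi <- seq(0.25, 1, length.out = 50)
  expect_true(all(diff(correctForPosition(1e-12, xi)) < 0))
})

test_that("sweep fit recovers f0 and Q, also under amplitude noise", {
  cant <- CantileverModel(8, 70e3, 3)
  clean <- makeNoisySweep(cant, noiseCv = 0, seed = 1)
  fit <- fitSweep(clean)
  expect_equal(fit$f0, 70e3, tolerance = 1e-6)
  expect_equal(fit$Q, 3, tolerance = 1e-4)
  expect_equal(fit$scale, 0.16e-9, tolerance = 1e-4)
  # Monte-Carlo property: 5% relative amplitude noise at Q = 3, f0
  # recovered within 0.2% in the median over 100 seeded replicates
  errs <- vapply(1:100, function(s) {
    sp <- makeNoisySweep(cant, noiseCv = 0.05, nPoints = 201, seed = s)
    abs(fitSweep(sp)$f0 - 70e3) / 70e3
  }, numeric(1))
  expect_lt(stats::median(errs), 0.002)
})

test_that("optical lever conversion is exact and invertible", {
  expect_identical(voltsToMeters(0, 7.77e7), 0)
  # instrument anchor: 0.16 nm mean oscillation amplitude
  expect_equal(voltsToMeters(1.243e-2, 7.77e7) * 1e9, 0.16, tolerance = 1e-3)
  x <- c(1e-3, 2.7e-2, 5)
  expect_equal(voltsToMeters(x, 3.38e7) * 3.38e7, x, tolerance = 1e-15)
  expect_error(voltsToMeters(1, 0), "sensitivity")
})

test_that("constant cell gives a flat mass trajectory", {
  g <- makeGrowthExperiment("constant", dt = 600, noiseCv = 0.01, seed = 2)
  tr <- massTrajectory(g$sweeps, g$times, g$fBefore, g$springConstant)
  expect_true(all(tr$flag == "ok"))
  # dispersion bounded by the noise level of the sweep fit
  expect_lt(stats::sd(tr$corrected_mass_kg) / mean(tr$corrected_mass_kg), 0.05)
})

test_that("growth trajectories reproduce the substrate morphologies", {
  # rising apparent mass on a high-frequency lever, anchored 0.59 -> 3.04 ng
  g <- makeGrowthExperiment("collagen", dt = 360, noiseCv = 0.01, seed = 3)
  tr <- massTrajectory(g$sweeps, g$times, g$fBefore, g$springConstant)
  n <- nrow(tr)
  expect_equal(tr$apparent_mass_kg[1] * 1e12, 0.59, tolerance = 0.05)
  expect_equal(tr$apparent_mass_kg[n] * 1e12, 3.04, tolerance = 0.05)
  expect_gt(stats::cor(tr$time_s, tr$apparent_mass_kg), 0.99)
  # stiffening ramp on a 15 kHz lever: non-monotone, late slight decrease
  lo <- makeGrowthExperiment("stiffening",
                             cantilever = CantileverModel(0.5, 15e3, 3),
                             dt = 360, noiseCv = 0.005, seed = 4)
  tr2 <- massTrajectory(lo$sweeps, lo$times, lo$fBefore, lo$springConstant)
  ipk <- which.max(tr2$apparent_mass_kg)
  expect_gt(ipk, 1)
  expect_lt(ipk, nrow(tr2))
  expect_lt(tr2$apparent_mass_kg[nrow(tr2)], tr2$apparent_mass_kg[ipk])
  expect_error(massTrajectory(list(), numeric(0), 70e3, 8), "at least one")
})

test_that("measurement tables gain apparent and corrected masses with flags", {
  df <- data.frame(time_s = c(0, 10), spring_constant_n_per_m = 8,
                   f_before_hz = 70e3, f_after_hz = c(67485, 70.05e3),
                   position_fraction = c(1, 0.8))
  out <- measureMasses(df)
  expect_equal(out$apparent_mass_kg[1], 3.14e-12, tolerance = 1e-3)
  expect_equal(out$corrected_mass_kg[2],
               out$apparent_mass_kg[2] / modeShape(0.8)^2)
  expect_identical(out$flag, c("ok", "negative_mass"))
  expect_error(measureMasses(df[, -2]), "missing column")
})
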