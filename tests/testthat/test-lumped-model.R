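# 2-DOF lumped-mass physics: coupling, effective dynamic mass, frequency
# response, sweep readout and the closed-form readout-accuracy law.

test_that("model classes derive and round-trip their parameters", {
  cant <- CantileverModel(8, 75e3, 3)
  # rebuild (f, Q) from (k, m, c)
  m <- modalMass(cant); cc <- dampingCoefficient(cant)
  expect_equal(sqrt(8 / m) / (2 * pi), 75e3, tolerance = 1e-12)
  expect_equal(sqrt(8 * m) / cc, 3, tolerance = 1e-12)

  cell <- hela_cell()
  k <- couplingStiffness(cell); cd <- couplingDamping(cell)
  expect_equal(sqrt(k / cellMass(cell)) / (2 * pi), 14.4e3, tolerance = 1e-12)
  expect_equal(sqrt(k * cellMass(cell)) / cd, 0.3, tolerance = 1e-12)
  # k_cell = E * F(S) consistency is enforced
  ok <- CellMechanicalModel(3.14e-12, elasticModulus = 1300,
                            shapeFactor = 1.978e-5)
  expect_equal(couplingStiffness(ok), 1300 * 1.978e-5)
  expect_error(CellMechanicalModel(3.14e-12, stiffness = 0.5,
                                   elasticModulus = 1300,
                                   shapeFactor = 1.978e-5),
               "inconsistent")
  expect_error(CantileverModel(-1, 75e3, 3))
  expect_error(CellMechanicalModel(0))
})

test_that("complex coupling stiffness follows K* = k + i 2 pi f c", {
  cell <- CellMechanicalModel(3.14e-12, stiffness = 0.0257, damping = 1e-7)
  # static limit and free mass
  expect_identical(complexCoupling(cell, 0), complex(real = 0.0257, imaginary = 0))
  free <- CellMechanicalModel(1e-12)
  expect_identical(complexCoupling(free, 5e4), 0 + 0i)
  # direct arithmetic: 2 pi * 14400 * 1e-7
  z <- complexCoupling(cell, 14.4e3)
  expect_equal(Re(z), 0.0257)
  expect_equal(Im(z), 2 * pi * 14400 * 1e-7, tolerance = 1e-12)
  expect_equal(Im(z), 9.0478e-3, tolerance = 1e-4)
  expect_error(complexCoupling(cell, -1), "frequency")
})

test_that("effective dynamic mass has the stated limits and dissipative sign", {
  cell <- hela_cell()
  m <- cellMass(cell)
  # all compartments follow at zero frequency
  expect_equal(effectiveDynamicMass(cell, 0), complex(real = m, imaginary = 0))
  # hand-evaluated readout ratio at 75 kHz: 0.2797 * 3.14 ng = 0.878 ng
  ratio <- readout_by_hand(75, 14.4, 0.3)
  expect_equal(ratio, 0.2797, tolerance = 1e-3)
  expect_equal(Re(effectiveDynamicMass(cell, 75e3)), ratio * m,
               tolerance = 1e-10)
  expect_equal(Re(effectiveDynamicMass(cell, 75e3)) * 1e12, 0.878,
               tolerance = 1e-3)
  # undamped closed form below resonance
  und <- CellMechanicalModel(m, eigenfrequency = 14.4e3)  # c = 0
  f <- 10e3
  expect_equal(effectiveDynamicMass(und, f),
               complex(real = m * 14.4e3^2 / (14.4e3^2 - f^2), imaginary = 0),
               tolerance = 1e-12)
  # exact undamped pole is signalled, not inf
  expect_error(effectiveDynamicMass(und, 14.4e3), "pole")
  # e^{+i omega t} convention: Im{m_eff} <= 0 (energy flows into the cell)
  withr::with_seed(11, {
    for (i in 1:200) {
      cl <- CellMechanicalModel(10^runif(1, -13, -11),
                                eigenfrequency = 10^runif(1, 3, 5.7),
                                qualityFactor = 10^runif(1, -1.3, 1.7))
      expect_lte(Im(effectiveDynamicMass(cl, 10^runif(1, 3, 5.7))), 0)
    }
  })
})

test_that("frequency response reduces to the driven damped oscillator", {
  cant <- CantileverModel(8, 75e3, 100)
  # static compliance without a cell
  sp <- frequencyResponse(cant, NULL, c(0, 1, 2), driveForce = 8 * 0.16e-9)
  expect_equal(amplitude(sp)[1], 0.16e-9, tolerance = 1e-12)
  # SHO peak position
  grid <- seq(70e3, 80e3, length.out = 4001)
  sp <- frequencyResponse(cant, NULL, grid)
  fpk <- grid[which.max(amplitude(sp))]
  expect_lt(abs(fpk - 75e3 * sqrt(1 - 1 / (2 * 100^2))), diff(grid)[1])
  expect_error(frequencyResponse(cant, NULL, numeric(0)), "empty")
  expect_error(frequencyResponse(cant, NULL, grid, driveForce = -1), "driveForce")
})

test_that("quasi-rigid payload reproduces the 1-DOF summed-mass eigenfrequency", {
  cant <- cant_75k()
  rigid <- CellMechanicalModel(3.14e-12, eigenfrequency = 100 * 75e3,
                               qualityFactor = 5)
  grid <- exp(seq(log(30e3), log(120e3), length.out = 2001))
  sp <- frequencyResponse(cant, rigid, grid)
  fHat <- apparentEigenfrequency(sp)
  fRef <- sqrt(8 / (modalMass(cant) + 3.14e-12)) / (2 * pi)
  expect_equal(fHat, fRef, tolerance = 1e-3)
})

test_that("apparent eigenfrequency extraction is exact on SHO spectra", {
  f0 <- 70e3; q <- 5
  grid <- seq(30e3, 120e3, length.out = 801)
  amp <- f0^2 / sqrt((f0^2 - grid^2)^2 + (grid * f0 / q)^2)
  sp <- SweepSpectrum(grid, amp)
  expect_equal(apparentEigenfrequency(sp, "sho_fit"), f0, tolerance = 1e-6)
  # the raw amplitude maximum sits at f0 sqrt(1 - 1/(2Q^2)); the peak
  # method must de-bias back to f0
  expect_equal(apparentEigenfrequency(sp, "peak"), f0, tolerance = 2e-3)
  # degenerate monotone spectrum
  mono <- SweepSpectrum(grid, exp(-grid / 2e4))
  expect_error(apparentEigenfrequency(mono), "not bracketed")
  expect_error(apparentEigenfrequency(SweepSpectrum(1:5, 5:1)), "7 points")
})

test_that("readout accuracy matches hand arithmetic, limits and boundaries", {
  # hand-derived values (kHz^4 arithmetic in the helper)
  expect_equal(readoutAccuracy(75e3, 14.4e3, 0.3), readout_by_hand(75, 14.4, 0.3),
               tolerance = 1e-12)
  expect_equal(readoutAccuracy(75e3, 14.4e3, 0.3), 0.2797, tolerance = 1e-3)
  expect_equal(readoutAccuracy(15e3, 14.4e3, 0.3), 0.9923, tolerance = 1e-4)
  # exact unity when the two eigenfrequencies coincide, for any Q
  for (q in c(0.05, 0.3, 7)) {
    expect_identical(readoutAccuracy(14.4e3, 14.4e3, q), 1)
  }
  # limits
  expect_equal(readoutAccuracy(14.4e3 * 1e-4, 14.4e3, 0.3), 1, tolerance = 1e-6)
  expect_lt(readoutAccuracy(14.4e3 * 1e4, 14.4e3, 0.3), 1e-6)
  # undamped closed form
  fr <- c(5e3, 10e3, 13e3)
  expect_equal(readoutAccuracy(fr, 14.4e3, 1e9),
               14.4e3^2 / (14.4e3^2 - fr^2), tolerance = 1e-6)
  # errors
  expect_error(readoutAccuracy(75e3, 14.4e3, 0), "qCell")
  expect_error(readoutAccuracy(14.4e3, 14.4e3, Inf), "singular")
  expect_error(readoutAccuracy(-1, 14.4e3, 0.3), "fCant")
})

test_that("algebraic identity: Re{m_eff}/m equals the readout law everywhere", {
  withr::with_seed(42, {
    n <- 1e4
    fCant <- 10^stats::runif(n, log10(1e3), log10(5e5))
    fCell <- 10^stats::runif(n, log10(1e3), log10(5e5))
    q <- 10^stats::runif(n, log10(0.05), log10(50))
    m <- 3.14e-12
    lhs <- vapply(seq_len(n), function(i) {
      cell <- CellMechanicalModel(m, eigenfrequency = fCell[i],
                                  qualityFactor = q[i])
      Re(effectiveDynamicMass(cell, fCant[i])) / m
    }, numeric(1))
    rhs <- readoutAccuracy(fCant, fCell, q)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  })
})

test_that("virtual sweep experiment agrees with the closed form (oracle equivalence)", {
  # small mass ratio + high cantilever Q: the full 2-DOF pipeline must land
  # on the closed-form readout fraction
  withr::with_seed(7, {
    for (i in 1:50) {
      fCant <- 10^stats::runif(1, 4, 5)
      k <- stats::runif(1, 2, 10)
      cant <- CantileverModel(k, fCant, stats::runif(1, 100, 300))
      m <- 1e-3 * modalMass(cant)
      fCell <- fCant * 10^stats::runif(1, -0.5, 0.5)
      q <- 10^stats::runif(1, -1, 0.3)
      cell <- CellMechanicalModel(m, eigenfrequency = fCell, qualityFactor = q)
      simRatio <- simulateApparentMass(cant, cell, fast_grid) / m
      eq3 <- readoutAccuracy(fCant, fCell, q)
      expect_lt(abs(simRatio - eq3), 0.01 * max(1, abs(eq3)))
    }
  })
})

test_that("simulated apparent mass hits the rigid limit and the Eq. 3 oracle", {
  cant <- cant_75k()
  rigid <- CellMechanicalModel(3.14e-12, eigenfrequency = 100 * 75e3,
                               qualityFactor = 5)
  expect_equal(simulateApparentMass(cant, rigid), 3.14e-12, tolerance = 1e-2)
  soft <- CellMechanicalModel(1e-3 * modalMass(cant), eigenfrequency = 14.4e3,
                              qualityFactor = 0.3)
  expect_equal(simulateApparentMass(cant, soft) / cellMass(soft),
               0.2797, tolerance = 1e-2)
  # vanishing payload reads as nothing (grid-resolution zero)
  tiny <- CellMechanicalModel(1e-20, eigenfrequency = 14.4e3,
                              qualityFactor = 0.3)
  expect_lt(abs(simulateApparentMass(cant, tiny)), 1e-15)
})

test_that("stiffening trajectories reproduce the readout morphology", {
  m <- 3.14e-12
  kGrid <- seq(0, 0.4, length.out = 81)
  # 75 kHz lever: monotone rise, starting near zero
  hi <- stiffeningTrajectory(CantileverModel(8, 75e3, 3), m, kGrid)
  expect_lt(hi$ratio[1], 0.01)
  expect_true(all(diff(hi$ratio) > -1e-9))
  # ramp crossing a 15 kHz lever: transient overshoot then slight decline
  lo <- stiffeningTrajectory(CantileverModel(0.5, 15e3, 3), m, kGrid)
  ipk <- which.max(lo$ratio)
  expect_gt(lo$ratio[ipk], 1)            # overshoot above the true mass
  expect_lt(ipk, length(kGrid))          # interior maximum
  expect_lt(lo$ratio[length(kGrid)], lo$ratio[ipk])  # late decline
  # rigid end of the ramp reads the full mass
  kRigid <- cellStiffness(10 * 15e3, m)
  rig <- stiffeningTrajectory(CantileverModel(0.5, 15e3, 3), m,
                              c(0, kRigid))
  expect_equal(rig$ratio[2], 1, tolerance = 2e-2)
  # fixed-Q damping rule hits the hand-derived point
  fx <- stiffeningTrajectory(CantileverModel(0.5, 15e3, 3), m,
                             cellStiffness(14.4e3, m),
                             dampingRule = list(fixedQ = 0.3))
  expect_equal(fx$ratio, 0.9923, tolerance = 1e-2)
  expect_error(stiffeningTrajectory(cant_75k(), m, c(-0.1, 0.2)), "non-negative")
})

test_that("rigid payloads read within 1% across the full cantilever range", {
  fCant <- seq(3e3, 110e3, length.out = 40)
  r <- readoutAccuracy(fCant, 20 * fCant, 5)
  expect_true(all(r >= 0.99 & r <= 1.01))
})
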