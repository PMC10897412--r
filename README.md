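# picomass

Single-cell mass, eigenfrequency and quality factor from resonating
microcantilevers.

## The problem

A picobalance weighs an adherent cell by tracking the eigenfrequency of a
photothermally actuated microcantilever before and after the cell attaches:

    m* = (k_cant / 4π²) (1/f_after² − 1/f_before²)

This rigid-point-mass law is exact only when every part of the payload
follows the lever in phase. A living cell is viscoelastic: once the lever
oscillates near or above the whole-cell eigenfrequency, cell compartments
decouple and the balance under-reads the mass — by several-fold on fast
levers. `picomass` implements the two-degree-of-freedom lumped-mass model
that explains this, and turns it into an estimator: the cell is a point
mass m attached through a Kelvin–Voigt element (spring k_cell, damper
c_cell), presenting the complex effective mass

    m_eff(ω) = m · K*(ω) / (K*(ω) − ω² m),   K*(ω) = k_cell + iω c_cell

to the lever. Evaluated at the cantilever eigenfrequency this gives the
closed-form readout-accuracy law

    m_app/m_real = 1 + f_cant²(f_cell² − f_cant²) /
                   [ (f_cell² − f_cant²)² + f_cant² f_cell² / Q_cell² ]

with f_cell = √(k_cell/m)/2π and Q_cell = √(k_cell·m)/c_cell. Fitting this
law to relative masses measured with cantilevers of many different
eigenfrequencies (3–110 kHz) recovers the population-average cell
eigenfrequency and quality factor, and from them the whole-cell stiffness
k_cell = 4π² m f_cell² and, given a shape factor, a Young's modulus
E = k_cell/F(S).

The package is aimed at instrument builders and mechanobiologists who need
to (i) correct cantilever mass measurements for cell mechanics, (ii)
extract f_cell and Q_cell from ensemble experiments, and (iii) prototype
experimental designs against a fully synthetic, seeded data generator.

## What's inside

* `CantileverModel`, `CellMechanicalModel`, `SweepSpectrum` — S4 models of
  the resonator, the viscoelastically attached cell, and frequency sweeps.
* `frequencyResponse()`, `effectiveDynamicMass()`, `readoutAccuracy()`,
  `simulateApparentMass()`, `stiffeningTrajectory()` — the 2-DOF physics.
* `massFromFrequencyShift()`, `modeShape()`, `correctForPosition()`,
  `fitSweep()`, `massTrajectory()` — picobalance bookkeeping.
* `binEnsemble()`, `fitReadoutCurve()`, `cellStiffness()`,
  `youngsModulus()` — ensemble inference.
* `sphereMass()`, `distributionToMass()`, `crosslinkReference()` — Coulter
  style reference masses.
* `makeEnsembleExperiment()`, `makeGrowthExperiment()`, `makeNoisySweep()`,
  `makeCoulterSample()`, `applyCrosslinking()` — seeded generators.
* `runPipeline()` and a thin CLI (`inst/cli/picomass.R`) for end-to-end
  runs; CSV/JSON dialect readers and writers.

## Worked example

```r
library(picomass)

pts <- makeEnsembleExperiment(seed = 1)   # 178 cells, levers 3-110 kHz
fit <- fitReadoutCurve(pts, seed = 1)
fit
#> EnsembleFitResult
#>   f_cell : 16.94 +/- 4.15 kHz
#>   Q_cell : 0.346 +/- 0.081
#>   n = 178 points, residual SS = 27.03

signif(cellStiffness(eigenfrequency(fit), 3.14e-12), 2)
#> [1] 0.036
```

The generating world has f_cell = 14.4 kHz and Q_cell = 0.3; this seed's
estimate sits 18% high with a ±4 kHz standard error, which is honest: at
measurement noise of CV 0.4 the two parameters trade off along the ridge
f_cell²(1/Q² − 1) ≈ const and single-ensemble estimates are intrinsically
wide, while medians over replicated ensembles are tight (within 2% — see
the methods vignette). The readout law itself shows why slow levers weigh
cells correctly and fast ones do not:

```r
readoutAccuracy(c(15e3, 75e3), 14.4e3, 0.3)
#> [1] 0.9923483 0.2797534
```

a 15 kHz lever reads 99% of the true mass, a 75 kHz lever 28% — the
~3.5-fold readout difference seen between slow and fast cantilevers.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package: the ensemble-fitted
cell eigenfrequency (kHz) and quality factor from a freshly generated
seeded synthetic ensemble; the whole-cell spring constant from the mean
cell mass and fitted eigenfrequency (one significant figure); the relative
spread of the substrate-dependent mean masses; the stiffness factor for a
√2 eigenfrequency increase; and the 15 kHz/75 kHz readout ratio at the
fitted cell parameters. Results are written as JSON to `--out`.
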