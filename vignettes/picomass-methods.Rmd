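---
title: "Methods: the lumped-mass picobalance model and its estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lumped-mass picobalance model and its estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picomass)
```

## The physical model

A picobalance weighs a single adherent cell from the eigenfrequency shift of
a photothermally actuated microcantilever. The rigid-payload law

$$m^{*} = \frac{k_\mathrm{cant}}{4\pi^2}
  \left(\frac{1}{f_\mathrm{after}^2} - \frac{1}{f_\mathrm{before}^2}\right)$$

assumes every part of the payload follows the lever in phase. A living cell
does not: it is viscoelastic, and its compartments decouple from the lever
motion once the actuation frequency approaches or exceeds the whole-cell
eigenfrequency. `picomass` models this with two coupled lumped oscillators:
the cantilever mode (spring $k_c$, modal mass $m_c = k_c/4\pi^2f_c^2$,
damper $c_c = \sqrt{k_c m_c}/Q_c$) and a point-mass cell $m$ attached
through a Kelvin-Voigt element ($k_\mathrm{cell}$ in parallel with
$c_\mathrm{cell}$).

Under the $e^{+i\omega t}$ time convention (dissipation enters as
$+i\omega c$; this is asserted in the tests via
$\mathrm{Im}\,m_\mathrm{eff}\le 0$), the cell presents the complex
effective mass

$$m_\mathrm{eff}(\omega) = m\,\frac{K^{*}(\omega)}{K^{*}(\omega)-\omega^2 m},
  \qquad K^{*}(\omega)=k_\mathrm{cell}+i\omega c_\mathrm{cell},$$

and the lever deflects as
$X(\omega) = F / \big(k_c + i\omega c_c - \omega^2(m_c +
m_\mathrm{eff}(\omega))\big)$. Writing
$f_\mathrm{cell} = \sqrt{k_\mathrm{cell}/m}/2\pi$ and
$Q_\mathrm{cell} = \sqrt{k_\mathrm{cell} m}/c_\mathrm{cell}$, the real part
of $m_\mathrm{eff}$ at the cantilever eigenfrequency gives the closed-form
readout-accuracy law implemented in `readoutAccuracy()`:

$$\frac{m_\mathrm{app}}{m_\mathrm{real}} = 1 +
  \frac{f_\mathrm{cant}^2\,(f_\mathrm{cell}^2-f_\mathrm{cant}^2)}
       {(f_\mathrm{cell}^2-f_\mathrm{cant}^2)^2 +
        f_\mathrm{cant}^2 f_\mathrm{cell}^2/Q_\mathrm{cell}^2}.$$

The identity $\mathrm{Re}\,m_\mathrm{eff}(2\pi f_\mathrm{cant})/m \equiv$
this law is exact and is verified to $10^{-10}$ over $10^4$ random
parameter draws. Limits: the ratio is 1 at $f_\mathrm{cant}\to 0$ (all
compartments follow; the rigid law applies), exactly 1 at
$f_\mathrm{cant}=f_\mathrm{cell}$, above 1 just above the cell resonance at
weak damping (the overshoot seen on slow levers), and 0 as
$f_\mathrm{cant}\to\infty$ (full decoupling).

`simulateApparentMass()` does not use the closed form: it runs the virtual
experiment - sweep the bare lever, SHO-fit for $f_\mathrm{before}$, attach
the cell, sweep and fit for $f_\mathrm{after}$, apply the rigid law - and
is cross-checked against the closed form (agreement within 1% whenever the
mass ratio is $\le 10^{-3}$ and $Q_c \ge 100$).

## Eigenfrequency extraction from sweeps

The instrument reports eigenfrequencies "assuming a simple harmonic
oscillator", so the default `sho_fit` method least-squares fits the driven
damped oscillator amplitude
$A(f) = a f_0^2/\sqrt{(f_0^2-f^2)^2 + (f f_0/Q)^2}$ (Nelder-Mead then BFGS
on log-parameters, started from a parabolic log-amplitude peak interpolation
and a half-power-bandwidth $Q$ estimate). The `peak` method is kept for
diagnostics and is de-biased by $\sqrt{1-1/2Q^2}$, since an SHO amplitude
peaks below $f_0$. A maximum on the grid boundary raises an error rather
than extrapolating. Default grids are 1001 log-spaced points over
$[f_c/5,\,5f_c]$ with an 801-point linear refinement window of $\pm 3$
half-widths around the detected peak.

## Position correction

A point mass at fractional beam position $\xi$ contributes $\varphi(\xi)^2$
of its mass to the modal mass, with $\varphi$ the first clamped-free
Euler-Bernoulli mode shape normalised to $\varphi(1)=1$
($\lambda_1 = 1.87510407$). The correction $m^{*}/\varphi(\xi)^2$ is
refused below $\xi = 0.2$ (a $\sim$40-fold correction amplifies noise past
usefulness; the cutoff is configurable). This standard effective-mass
argument stands in for the instrument-specific calibration and is isolated
behind `modeShape()` for easy replacement.

## Ensemble fit for $f_\mathrm{cell}$ and $Q_\mathrm{cell}$

`fitReadoutCurve()` fits the readout-accuracy law to
$(f_\mathrm{cant},\,m_\mathrm{app}/m_\mathrm{real})$ points by nonlinear
least squares in log-parameters (bounds $f_\mathrm{cell}\in[0.5,500]$ kHz,
$Q\in[0.01,100]$), with five seeded multi-starts and a final high-precision
polish. The default objective is *relative* least squares, iteratively
reweighted with $w = 1/\max(\mu, 0.05)^2$: the measured relative masses
scatter multiplicatively with roughly constant coefficient of variation, and
for such noise the $1/\mu^2$-weighted estimator is the quasi-likelihood
choice. Unweighted raw fitting and (optionally inverse-variance weighted)
binned fitting are available for comparison; with seven equidistant bins
the bin-center approximation alone moves the clean-data estimate by several
percent, so bins are summaries, not the default fitting route.

Two properties of this problem deserve emphasis:

* **A near-degenerate ridge.** Away from the bend at
  $f_\mathrm{cant}\approx f_\mathrm{cell}$ the curve constrains mainly the
  combination $f_\mathrm{cell}^2(1/Q^2-1)$. At realistic noise (CV 0.4,
  $n=178$) the Cramér-Rao bound on $f_\mathrm{cell}$ is of order 30%, and
  the fitted pair is strongly positively correlated. Single-dataset
  estimates therefore wander along the ridge; the reported Jacobian-based
  standard errors are wide because the truth is wide.
* **Median-unbiasedness.** Over 200 replicated synthetic ensembles the
  median recovered eigenfrequency is within 2% of the generating value and
  the median $Q$ within 0.03; this, not single-draw accuracy, is what the
  estimator guarantees and what the test suite asserts.

Flat-at-1 ensembles (rigid payloads: glass beads) contain no information
about $f_\mathrm{cell}$ beyond a lower bound; they are detected by
comparing the fitted residual sum of squares against the constant-1 model
and flagged `rigid_limit`.

Whole-cell stiffness follows as $k_\mathrm{cell} = 4\pi^2 m
f_\mathrm{cell}^2$ (`cellStiffness()`), and a Young's modulus as
$E = k_\mathrm{cell}/F(S)$ only when the user supplies the FEM-derived
shape factor $F(S)$ - the package deliberately does not estimate cell-shape
factors.

## The synthetic world

The generators state one world and keep it fixed:

* Cell population: mass $3.14 \pm 0.26$ ng, population-average
  eigenfrequency 14.4 kHz (between-cell SD 0 by default, because the
  ensemble fit targets a population average; a spread knob exists for
  robustness studies), $Q_\mathrm{cell} = 0.3$.
* Measurement noise on the apparent mass: multiplicative lognormal with
  CV 0.4, mean one. The raw scatter of the measured readout curve is not
  quantified numerically anywhere, so the CV is a modelling choice; mean-one
  centering keeps the noisy points conditionally unbiased around the curve.
* Cantilever bank: the six classes of FIB-milled rectangular levers
  spanning 3-110 kHz with their spring-constant ranges; in-liquid
  $Q_\mathrm{cant} = 3$ (typical for such levers in water - an assumption,
  flagged as such; it is not printed anywhere).
* Drive scale: the static deflection is anchored to the instrument's
  0.16 nm mean oscillation amplitude.
* Growth profiles are phenomenological: the collagen-like profile ramps the
  *apparent* mass linearly from 0.59 to 3.04 ng over 120 min (the
  measured anchor); the stiffening profile ramps $k_\mathrm{cell}$ linearly
  from 0 to 0.4 N/m at fixed mass. Growth sweeps are synthesised by
  inverting the rigid law for the profile's apparent mass, so the anchor is
  recovered by construction through the full sweep-fit-convert chain. The
  generators emulate readout statistics, not adhesion biology: a green
  growth test establishes that the readout chain is faithful, not that
  cells grow this way.
* Damping rule for stiffening ramps: $c_\mathrm{cell} = c_\mathrm{min} +
  \beta k_\mathrm{cell}$ with $c_\mathrm{min} = \mu_\mathrm{min} F(S) =
  2.5\,\mathrm{mPa\,s} \times 2.0\times10^{-5}\,\mathrm{m} =
  5\times10^{-8}$ N s/m. The minimal damping is quoted in viscosity units
  in the source material, so reading it as $\mu_\mathrm{min}$ times a shape
  factor (length) is a decision of this package. $F(S) = 2.0\times10^{-5}$ m
  is the length implied by $k = E\,F(S)$ with $k \approx 0.026$ N/m and
  $E \approx 1.3$ kPa. $\beta = 3.49\times10^{-5}$ s is calibrated once so
  that $Q_\mathrm{cell} = 0.3$ at the fitted HeLa state; a linear $c(k)$
  cannot hold $Q$ constant across the whole ramp ($Q \approx 0.08$ at
  0.4 N/m), which is accepted as part of the stated world. A `fixedQ`
  rule is available.
* Reference masses: sphere volume times density, cells at 1.06 g/cm³,
  glass beads at 1.8 g/cm³, Coulter gate 9-24 µm. The default synthetic
  diameter mean, 17.8 µm, is the mass-equivalent diameter of a 3.14 ng
  cell - a derived quantity, documented as such.
* Crosslinking: stiffness $\times 3$, mass $\times 0.8$, coupling damping
  preserved (unchanged $\mu$ and $F(S)$), so $f_\mathrm{cell}$ rises by
  $\sqrt{3/0.8} \approx 1.94$.

All generators are pure functions of (spec, seed); none touches the global
RNG state.

## Numerical choices and degenerate inputs

* SI units internally (Hz, kg, N/m, N s/m); kHz/ng only at file and CLI
  surfaces.
* Exact undamped poles ($K^{*} = \omega^2 m$ with $c=0$) raise errors
  naming the frequency instead of returning `Inf`/`NaN`.
* Negative apparent masses (noise pushing $f_\mathrm{after}$ above
  $f_\mathrm{before}$) are flagged, never clipped, so downstream averages
  see them.
* Sweep fits require at least 7 points bracketing a maximum; monotone
  spectra are rejected.
* CSV readers validate exact headers and report malformed rows by number;
  the JSON model config rejects unknown keys.

## A worked example

```{r example}
pts <- makeEnsembleExperiment(seed = 1)
fit <- fitReadoutCurve(pts, seed = 1)
fit

k <- cellStiffness(eigenfrequency(fit), 3.14e-12)
signif(k, 1)
```

## Known limitations

* Only the first flexural mode is modelled: no higher modes, no
  hydrodynamic loading, no photothermal transfer function of the drive.
* Shape effects enter only through the user-supplied $F(S)$; the package
  performs no finite-element analysis.
* The ensemble fit returns population averages; per-cell eigenfrequency
  inference and hierarchical modelling of between-cell heterogeneity are
  out of scope.
* Single-ensemble estimates of $(f_\mathrm{cell}, Q_\mathrm{cell})$ at
  realistic noise are intrinsically wide (see the ridge discussion); plan
  replicated ensembles or lower-noise designs when a tight per-dataset
  estimate is needed.
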