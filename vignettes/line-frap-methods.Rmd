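---
title: "Measuring membrane diffusion with line FRAP: models, simulator and design choices"
author: "lineFRAP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring membrane diffusion with line FRAP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineFRAP)
```

## The measurement and the model

Line FRAP bleaches a thin line across a fluorescently labelled membrane
with a focused laser and follows the return of fluorescence in a line ROI
(conventionally 100 x 1 pixels).  For a single species diffusing freely in
two dimensions, with a Gaussian bleaching line of e^-2 radius $r_{0e}$,
peak bleach dose $K_0$, and a Gaussian detection profile of e^-2 radius
$r_{0c}$, the normalized recovery has the closed form

$$\frac{F(t)}{F_0} \;=\; \sum_{n=0}^{\infty} \frac{(-K_0)^n}{n!}\,
  r_{0e}\,\bigl(n\,r_{0c}^2 + (a_n - n)\,r_{0e}^2\bigr)^{-1/2},
  \qquad a_n = 1 + n\Bigl(1 + \frac{8 D t}{r_{0e}^2}\Bigr),$$

so the $n$-th term equals $(-K_0)^n/n! \cdot r_{0e}/\sqrt{r_{0e}^2 +
n\,(r_{0c}^2 + 8 D t)}$.  Useful limits, all of which the test suite
asserts: $K_0 = 0$ gives exactly 1; at $t = 0$ with $r_{0c} = 0$ the sum
is $e^{-K_0}$; and the signal recovers to 1 as $t \to \infty$ with the
characteristic $1/\sqrt{t}$ tail of one-dimensional deficit relaxation.

`frap_recovery()` evaluates the series with a recursive term update (no
explicit factorials, so no overflow) and stops when the next term falls
below `rel_tol` (default `1e-10`) times the partial sum; the alternating
factorial decay certifies the truncation error by the first omitted term.
`n_max = 200` terms cover every practically relevant dose ($K_0 \lesssim
5$); exceeding it raises a classed error carrying the residual bound
rather than returning a silently truncated value.

Mixtures and incomplete recovery are described by
$$F(t) = F_{\mathrm{post},0} + k\,\bigl(M(t) - M(0)\bigr), \qquad
  M(t) = \sum_j w_j F_j(t),$$
where the $w_j$ are constrained to the simplex for identifiability, $k \in
[0,1]$ is the mobile fraction, and $F_{\mathrm{post},0}$ the normalized
fluorescence at the first post-bleach sample.  The printed form of this
relation in the line-FRAP literature is self-referential (the same symbol
appears on both sides); we read the right-hand recovery as the model
prediction and the left side as the observed signal, which is the standard
mobile-fraction interpretation: $k$ scales the recovering part, and the
asymptote is $F_{\mathrm{post},0} + k\,(1 - M(0))$.

Time zero is the first post-bleach sample and bleaching is treated as
instantaneous and irreversible; no reversible photobleaching or
acquisition-bleaching corrections are modelled.

## Fitting

`frap_fit()` performs bounded Levenberg-Marquardt least squares
(minpack.lm) with diffusion coefficients on the log scale, a deterministic
multi-start over a log-spaced grid (crossed pairs for two components,
small seeded jitter), and near-tie resolution toward the smaller total
$|\log D|$.  Standard errors come from the Gauss-Newton curvature at the
optimum.  The beam constants default to calibration inputs; $K_0$ can be
co-fitted (`fix_beam = FALSE`), while $r_{0e}$ and $r_{0c}$ are never
co-fitted from a single curve because they are not separately identifiable
there.  A fitted coefficient resting on its `D_bounds` sets a boundary
flag; the unit-interval parameters ($k$, $F_{\mathrm{post},0}$, weights)
are natural constraints and do not.

Two practical lessons from the synthetic experiments are exposed as
options rather than hidden defaults:

* **Fast-component conditioning.**  When the frame interval barely
  resolves the fast species (free fluorophores in the buffer diffuse at
  tens of um^2/s, so their recovery is over within a frame or two), the
  free two-component fit is ill-conditioned: the fast slot can collapse
  onto the membrane timescale and contaminate the slow estimate.
  `fit_options(fix_D = c(30, NA))` pins the fast coefficient at a
  calibrated value — the in-silico analogue of measuring the free-dye
  coefficient once on a dye-only control — and restores well-behaved
  membrane estimates.
* **QC for batches.**  `run_batch()` excludes non-converged fits, fits
  whose membrane-classified coefficient sits on a bound, and (optionally,
  `require_free_dye = TRUE`) two-component fits that fail to separate a
  known fast contaminant.  Exclusions are logged with reasons and reported
  per condition.

The empirical backend `fit_double_exponential()` implements the
double-exponential description of recovery curves, with tail-then-head
log-linear initialization, a rate-collapse (ratio < 1.5) degeneracy
warning, and `rates_to_diffusion()` converting rates by the model's only
timescale, $D = \lambda\,r_{0e}^2/8$, with an exposed calibration factor.
The closed-form recovery has a $1/\sqrt{t}$ tail, so its
double-exponential description is not unique: the literal slow rate
chases the tail and converts to a roughly 20-fold underestimate of $D$,
while the dominant-amplitude rate is exactly scale-invariant under
acquisition matched to the recovery timescale and recovers $D$ with a
window-dependent calibration factor (1.90 for the window
$8Dt/r_{0e}^2 \in [0, 80]$, established against the closed form and
frozen in the tests).  The two backends describe the same data but are
not numerically interchangeable, which is why both are provided and
compared rather than one presumed canonical.

Components with $D$ above `threshold_D` (default 10 um^2/s, configurable)
are classified `free_dye` and never enter condition summaries; membrane
lipid coefficients sit at a few um^2/s, several-fold below typical
buffer-fluorophore values.

## The synthetic-data generator

The generator is the package's oracle: every analysis stage is validated
against data whose truth is known by construction.

**Dynamics.**  Particles perform 2D Brownian steps (per-axis variance
$2D\,\Delta t$) in a square box with reflecting walls.  Obstacle-free
species are sampled exactly at the frame interval (Brownian increments
are exact at any step).  Gel/liquid-ordered domains are impermeable
reflecting discs laid on a jittered lattice with a randomized global
phase — domains in spin-coated bilayers appear homogeneously distributed,
and the random phase prevents any systematic alignment between disc rows
and the fixed bleach line, which would otherwise bias recovery in a
coverage-dependent way.  Obstructed species are integrated with substeps
(`dt`, validated against `r0e^2/(40 max D)`); a proposal ending inside a
disc is mirrored across the disc boundary, and a proposal whose midpoint
lies inside a disc is rejected, which suppresses step-through at the
0.2-0.8 um disc radii used here.  The obstructed inner loop is compiled
(Rcpp) and uses R's RNG, so every run is a pure function of the
configuration seed.  Free-dye particles are modelled as a fast planar
species that ignores obstacles — a deliberate 2D simplification of
buffer fluorophores.

**Bleach.**  A particle at perpendicular distance $y$ from the line
survives with probability $\exp(-K_0 e^{-2y^2/r_{0e}^2})$, the Gaussian
beam line profile that defines $K_0$ operationally.  Besides Bernoulli
sampling, an `expected` mode carries the exact survival probability as a
continuous brightness weight (Rao-Blackwellization over the bleach draw),
which estimates the same ensemble mean with far less variance.

**Readout.**  `brute_force_recovery()` sums PSF-weighted contributions of
surviving particles in the ROI directly from positions — no closed-form
expression enters.  Two optional variance-reduction devices are exact for
the estimand: `collapse_x` integrates the ROI weight analytically along
the line direction (valid by translation invariance; with obstacles it
corresponds to a full-width line ROI over a statistically homogeneous
disc field), and `normalize = "same_frame"` divides the surviving signal
by the all-particle signal of the same frame, cancelling shared density
fluctuations (the expected all-particle signal equals the pre-bleach
level at every frame).  With both, a $10^5$-particle comparison against
the closed form shows a maximum absolute deviation of 0.004-0.007 —
comfortably inside the 0.02 sampling budget asserted in the acceptance
suite; the plain estimator at the same size fluctuates at the 0.03-0.05
level, which is why these estimators exist.

**Rendering.**  `render_frames()` deposits surviving particles as
pixel-integrated Gaussian spots (e^-2 radius $r_{0c}$, truncated beyond
5.5 sigma where the omitted mass is ~1e-8), in compiled code that
accumulates erf-integrated pixel masses directly, followed by per-pixel
Poisson sampling,
optional Gaussian read noise and 16-bit clipping (saturation above 1% of
pixels is warned about and recorded).  In `"none"` mode the expected-photon
image is returned unquantized, so noiseless renders reproduce the
brute-force curve to machine precision — the pipeline-identity test.

**Finite-box validity.**  The closed form assumes an infinite plane.  In
a box of side $L$ a fraction $\approx K_0 r_{0e}\sqrt{\pi/2}/L$ of each
species is permanently bleached, and a species is "mixed" once
$\sqrt{8Dt} \sim L/2$, after which its signal plateaus below the model.
The scenario defaults keep every simulated species far from this regime
(e.g. the fast-dye experiments use a 40 um box with a 1.6 s horizon); the
fast free-dye component of the batch scenarios is instead injected at
curve level as a closed-form mixture (`inject_fast_component()`), because
at the several-second horizons the slow component requires, no affordable
box keeps a 30 um^2/s species in the valid regime.  The injected
component serves exactly its purpose in those fixtures: a known fast
contaminant that classification must find and discard.

## The condition-series scenarios

`scenario_temperature_series()` emulates a homogeneous
cholesterol-containing membrane imaged at 22, 30 and 38 C: temperature
enters only as a label mapped to a domain area fraction (0.35, 0.20,
0.05), the free-area diffusion coefficient staying at 1 um^2/s, so the
effective coefficient rises with temperature because obstruction falls.
`scenario_gel_membrane()` emulates a heterogeneous gel-forming membrane:
within every temperature label half the line scans sit in a dense (0.5)
and half in a sparse (0.1) obstacle field, producing large
within-condition scatter and no systematic trend.

Design choices that matter here, fixed from pilot runs before the
acceptance checks were frozen:

* **Bleach-line width 2 um** (vs 1 um elsewhere): recovery samples
  diffusion on the scale of the bleach width; with a 1 um line and
  micrometre-scale domains the measurement probes sub-domain-spacing
  displacements, where diffusion is locally free, and almost no
  obstruction is visible.  The wider line averages over many 0.2 um
  domains and reports the effective coefficient.  A 32 um box keeps the
  wide line in the infinite-plane regime.
* **Deep bleach $K_0 = 1$** for all parameter-recovery experiments: at
  $K_0 = 0.5$ and 2% noise the $k$-$D$ trade-off (the $1/\sqrt{t}$ tail
  makes the plateau weakly identified) gives per-curve RMSE near 20%;
  a half-depth dip is ordinary practice and halves it.
* **Sampling**: 0.02 s frames, 3 s horizon, a 2e4-photon budget per
  sample, 4e4 particles per scan; 12 scans per condition.  Pilot means
  (6 scans) were 1.04 / 0.88 / 0.74 for coverage 0.05 / 0.20 / 0.35 with
  SDs of 0.02-0.07 — monotone with multi-sigma gaps at n = 12.

`trend_test()` is deliberately descriptive: it reports the Spearman rank
correlation between temperature and the pooled per-scan membrane
coefficients plus a strictly-increasing-means flag, and returns the
verdict `"increasing"` only when both the correlation is at least 0.5 and
the ordered means increase.  The floor is set from the null standard
deviation of Spearman's rho ($\approx 1/\sqrt{n-1} \approx 0.17$ at 36
scans), keeping the chance of calling a trend in the exchangeable gel
scenario near 0.3% (three iid means are monotone with probability 1/6 on
their own).  No p-value is headlined.

## Image pipeline

Stacks are 16-bit grayscale multi-frame TIFFs with a JSON sidecar for the
frame interval, pixel size and optionally the bleach frame — missing
metadata is an error, never a silent default.  Coordinates are 1-based
with inclusive column ranges (R convention); the bleach line runs along
x, so the bleach profile varies along y (image rows).

`detect_bleach_frame()` takes the largest single-frame ROI drop (earliest
on ties) and fails explicitly if it does not exceed three times the
pre-bleach frame-to-frame noise.  `extract_recovery_curve()` normalizes
by the mean background-subtracted pre-bleach ROI intensity; optional
photofading correction divides by a far-field ROI's relative intensity
(off by default — synthetic validation shows ~5% plateau bias at 10%
linear fading, restored to within 1% with the correction).  For synthetic
validation only, a paired unbleached control stack rendered from the same
particle field (`render_frames_paired()`) can be supplied; the
frame-by-frame ratio cancels shared density fluctuations.  Even so, the
realized bleach pattern itself fluctuates between scans, so the
stack-to-fit check uses a deep bleach ($K_0 = 2$), 2e5 particles and the
average of two replicate line scans to resolve a 2% error budget —
single raw scans at desk-scale particle counts scatter several-fold
wider.  The mobile fraction stays free in that fit: it absorbs the small
finite-field depletion of the fluorescent pool, which would otherwise
bias $D$ (constraining $k = 1$, with or without whole-field pool
normalization, provably biases the recovered coefficient here).

`estimate_bleach_resolution()` recovers $r_{0e}$ from the first
post-bleach frame by fitting the survival profile
$b\,\exp(-K_0 e^{-2(y-y_0)^2/w^2})$ to the pre-bleach-normalized column
profile.  The literal Gaussian-dip form is the small-$K_0$ limit; at
$K_0 = 1$ it overestimates the width by ~18% because the dip bottom
flattens, while the survival-profile fit stays within 5%.  The imaging
profile broadens the dip, so the estimate is deconvolved in quadrature
when $r_{0c}$ is supplied.  The fit also yields a usable $\hat K_0$.

## What passing tests do and do not show

The generator reproduces the statistical structure the analysis assumes:
free and obstructed 2D diffusion, an instantaneous Gaussian line bleach,
an immobile fraction, Poisson detection.  It does not emulate membrane
drift, focus drift, reversible photophysics, bleaching during
acquisition, 3D buffer diffusion of free dye, domain motion or melting,
or detector nonlinearity.  Passing acceptance therefore demonstrates the
correctness of the estimators under the stated model, not robustness to
those artefacts; the fading correction and background ROIs address the
two most common real-data departures, and the rest are out of scope.

Problem sizes throughout (1e5-particle oracle runs, 12-scan conditions,
~200-frame scans) were chosen so each check runs in seconds to a few
minutes on one core while leaving multi-sigma margins at the stated
tolerances; the methods do not depend on these sizes.

## Known limitations

* The closed form has no y-resolved profile prediction; only the
  line-averaged recovery is modelled.
* Obstacles are impermeable discs; partition coefficients and permeable
  domains are not modelled, so "temperature" is purely a morphology knob.
* The rate-to-diffusion conversion for the double-exponential backend is
  a convention (exact only for the model's timescale), to be calibrated
  against reference samples for absolute numbers.
* Standard errors are curvature-based; for strongly correlated parameter
  sets (shallow bleach, free two-component fits) they understate the
  uncertainty that the multi-start scatter reveals.
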