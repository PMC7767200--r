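# lineFRAP

Tools for measuring lateral diffusion in supported lipid bilayers and
other membranes with **line FRAP** — fluorescence recovery after
photobleaching of a thin line — aimed at membrane biophysicists analysing
confocal line-bleach experiments and at method developers who need a
ground-truthed synthetic testbed.

## The model

Bleaching a Gaussian line of e⁻² radius *r₀ₑ* with peak dose *K₀* into a
2D membrane with diffusion coefficient *D*, and imaging through a Gaussian
detection profile of e⁻² radius *r₀c*, gives the closed-form normalized
recovery

    F(t)/F₀ = Σₙ (−K₀)ⁿ/n! · r₀ₑ · [ n·r₀c² + (aₙ − n)·r₀ₑ² ]^(−1/2),
    aₙ = 1 + n·(1 + 8Dt/r₀ₑ²),

an alternating series with factorial decay that the package evaluates with
certified truncation.  Mixtures (e.g. a fast free-dye component over a
slow membrane lipid), a mobile fraction *k* and the post-bleach depth
*F₍post,0₎* enter through

    F(t) = F₍post,0₎ + k·( Σⱼ wⱼ Fⱼ(t) − Σⱼ wⱼ Fⱼ(0) ).

On top of the model the package provides:

* `frap_fit()` — multi-start bounded Levenberg–Marquardt fitting (1 or 2
  components, optional fixed coefficients, mobile fraction), returning a
  classed object with `print`, `summary`, `coef`, `predict`, `plot`,
  `residuals` and `simulate` methods; plus the empirical
  `fit_double_exponential()` backend and `rates_to_diffusion()`.
* `classify_components()` — separates membrane from fast free-dye
  components (default threshold 10 µm²/s) so the free-dye coefficient can
  be discarded from downstream statistics.
* An image pipeline — `read_stack()`/`write_stack()` (16-bit multi-frame
  TIFF + JSON sidecar), `detect_bleach_frame()`,
  `extract_recovery_curve()` (background subtraction, normalization,
  optional photofading correction), `estimate_bleach_resolution()`.
* A Brownian-dynamics synthetic-data generator —
  `simulate_trajectories()`, `apply_line_bleach()`, `render_frames()`,
  `brute_force_recovery()`, `generate_dataset()` — with two diffusing
  species, an immobile fraction, impermeable gel-domain obstacles
  (compiled stepping) and Poisson detection noise; every stage is a pure
  function of the seed.
* Batch analysis — `run_batch()`, `trend_test()`, `write_report()` — with
  per-condition mean ± SD summaries over line scans and a descriptive
  temperature-trend verdict, plus ready-made condition-series scenarios
  (`scenario_temperature_series()`, `scenario_gel_membrane()`).
* A thin command-line wrapper (`inst/cli/linefrap.R`) over `frap_cli()`
  with `simulate`, `extract`, `fit` and `batch` subcommands.

## Worked example

Simulate a noisy single-species line-FRAP measurement, fit it, and read
off the diffusion coefficient:

```r
library(lineFRAP)

beam <- beam_parameters(K0 = 1, r0e = 1, r0c = 0.25)   # calibration
cfg  <- sim_config(box = 10,
                   species = data.frame(D = 1, count = 60000,
                                        label = "membrane"),
                   n_frames = 110, frame_interval = 0.05,
                   beam = beam, bleach_after_frame = 10, seed = 7)
curve <- simulate_recovery_curves(1, cfg, photons_per_point = 2500)[[1]]
fit <- frap_fit(curve, beam)
fit
```

```
Line-FRAP fit (closed_form backend, 100 points)
     D weight stderr_D fixed at_bound    label
 1.073      1   0.1019 FALSE    FALSE membrane
  mobile fraction k = 1.000, F_post0 = 0.378, K0 = 1
  residual RMS = 0.01791
```

The fitted coefficient (here D̂ = 1.07 µm²/s against a ground truth of
1 µm²/s, with a curvature-based standard error of 0.10 — a single noisy
scan; medians over 12 replicate scans land within a few percent) is the
membrane diffusion coefficient; `F_post0` is the normalized fluorescence
right after the bleach (deep bleach: 0.38), and `k` the mobile fraction.  With
`fit_options(n_components = 2)` the same call separates a fast free-dye
component, which `classify_components(fit)` labels for exclusion.

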