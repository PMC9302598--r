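# locusdyn

Simulation and diffusion analysis of chromatin locus tracking data.

`locusdyn` is an R toolkit for single-particle tracking (SPT) studies of
punctate nuclear loci — the kind of experiment in which telomeres (or other
repetitive loci) are labelled with a dCas9–fluorophore system and imaged as
diffraction-limited spots at ~10 frames/s for a couple of minutes, and each
locus trajectory is analysed for its diffusive behaviour. It provides, in one
package:

* a **seeded trajectory and movie generator** for the motion classes such
  data mixes — subdiffusive fractional Brownian motion (fBm), confined
  diffusion, and immobile loci carrying only localisation noise — with
  ground-truth labels and rendered TIFF movie stacks (Gaussian PSF, Poisson
  photon noise, EMCCD-style read noise);
* **spot detection and tracking**: a Laplacian-of-Gaussian (LoG) detector
  with subpixel Gaussian refinement, and frame-to-frame linking by exact
  minimum-cost bipartite assignment with gap closing;
* **MSD analysis**: time-averaged mean squared displacement (TA-MSD),
  ensemble averaging, and anomalous-diffusion fitting;
* **population decomposition**: an anchored Gaussian-mixture fit of the
  per-trajectory apparent diffusion constant distribution into *fast*,
  *slow*, and *fixed* populations, with a 3 → 2 → 1 component fallback;
* a **preset pipeline** that emulates perturbation regimes (transcription
  inhibition, intercalation-induced rigidity, osmotic confinement,
  architectural-protein compaction) as re-weighted motion mixtures and
  compares population fractions across conditions.

## The model

For a 2D trajectory (x(i), y(i)), i = 1..N at frame interval Δt, the
time-averaged MSD at lag nΔt is

    MSD(nΔt) = 1/(N−n) Σ_{i=1}^{N−n} [x(i+n)−x(i)]² + [y(i+n)−y(i)]²

Tracks spanning at least 20 s are averaged into an ensemble curve and fitted
with the anomalous-diffusion law for two-dimensional motion,

    MSD(t) = 4 D t^α + c ,

where D is the generalised diffusion coefficient (µm²/s^α), α the anomalous
exponent (α < 1: subdiffusion), and c a free static offset absorbing the
4σ² localisation-noise floor. Per trajectory, an apparent diffusion constant
D_app is estimated from the first four lags by a linear fit with intercept
(D_app = slope/4). The distribution of log₁₀ D_app across trajectories is
multimodal and is decomposed into up to three Gaussian populations —
immobilised loci (*D_fixed*), local locus motion (*D_slow*), and long-range
chromatin movement (*D_fast*) — with the fixed component's location anchored
at a calibration value d_fix measured from fixed-cell (immobile) control
data under identical imaging settings.

## Worked example

The default preset suite simulates one fixed-cell calibration condition and
five live-cell conditions (300 trajectories each, 1200 frames at 0.1 s),
then runs the full analysis:

```r
library(locusdyn)
pipe <- run_pipeline(seed = 1)
print(pipe)
#> <locusdyn_pipeline> seed 1, d_fix = 0.000503 um^2/s
#> <condition_report> baseline: 300/300 tracks kept
#>   ensemble D = 0.0232 um^2/s^alpha, alpha = 0.430
#>   fractions: fixed 7.6% / slow 56.3% / fast 36.1%
#> <condition_report> released: 300/300 tracks kept
#>   ensemble D = 0.0354 um^2/s^alpha, alpha = 0.439
#>   fractions: fixed 0.0% / slow 46.0% / fast 54.0%
#> <condition_report> rigid: 300/300 tracks kept
#>   ensemble D = 0.00303 um^2/s^alpha, alpha = 0.348
#>   fractions: fixed 33.4% / slow 66.6% / fast 0.0%
#> <condition_report> crowded: 300/300 tracks kept
#>   ensemble D = 0.00257 um^2/s^alpha, alpha = 0.357
#>   fractions: fixed 41.8% / slow 58.2% / fast 0.0%
#> <condition_report> compacted: 300/300 tracks kept
#>   ensemble D = 0.029 um^2/s^alpha, alpha = 0.440
#>   fractions: fixed 11.2% / slow 41.4% / fast 47.3%
```

Reading the output: `d_fix` is the calibrated fixed-population anchor
(µm²/s) from the immobile control condition. Each report gives the ensemble
anomalous fit (D, α) and the mixture fractions. The *released* preset
(transcription-factor inhibition) loses its fixed peak and gains fast
fraction relative to baseline; the *rigid* preset (DNA intercalation) loses
the fast peak while the fixed fraction grows; *crowded* (osmotic pressure)
is dominated by the fixed population; *compacted* (cohesin overexpression)
gains fast fraction. `compare_conditions(pipe)` returns these fractions as
a long table and `plot_fractions()` draws the bar chart.

Individual stages compose with pipes on plain tibbles:

```r
p  <- motion_params("fbm", D = 3e-3, alpha = 0.3, sigma_loc = 0.02)
tr <- simulate_fbm(p, n_tracks = 200, seed = 1)
fit <- tr |> filter_tracks(20) |> ensemble_msd() |> fit_anomalous()
tidy(fit)   # D, alpha, offset with standard errors
```

A movie can be rendered, tracked and analysed the same way
(`render_movie()`, `track_movie()`), and a thin command-line interface over
the same functions lives at `inst/cli/locusdyn.R`
(`simulate | track | msd | mixture | run | compare`).

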