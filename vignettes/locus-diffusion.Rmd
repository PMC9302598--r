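---
title: "Models and methods behind locusdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind locusdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(locusdyn)
```

This vignette is the package's own account of its models, estimators and
design choices: what is computed, under which assumptions, which knobs
matter, and what the synthetic data do and do not establish about real
imaging data.

## The measurement being emulated

The workflow targets live-cell single-particle tracking of punctate nuclear
loci: many diffraction-limited spots per nucleus, imaged every 100 ms for
about 2 minutes (1200 frames), at roughly 0.16 µm/pixel under oblique-sheet
illumination. Each spot is detected per frame, linked into a 2D trajectory,
and summarised by its time-averaged mean squared displacement (TA-MSD),

$$\mathrm{MSD}(n\Delta t) \;=\; \frac{1}{N-n}\sum_{i=1}^{N-n}
  \big[x(i{+}n)-x(i)\big]^2 + \big[y(i{+}n)-y(i)\big]^2 ,$$

where $N$ is the trajectory length and $\Delta t$ the frame interval.
Chromatin loci are polymer segments in a crowded, bounded nucleus, so
ensemble MSD curves are fitted with the two-dimensional anomalous-diffusion
law $\mathrm{MSD}(t) = 4 D t^{\alpha}$ with a generalised coefficient $D$
(µm²/s^α) and exponent $\alpha$; $\alpha < 1$ indicates constrained
(subdiffusive) motion. Per-trajectory apparent diffusion constants
$D_\mathrm{app}$ form a multimodal distribution that is decomposed into
*fast* (long-range chromatin movement), *slow* (local locus motion) and
*fixed* (immobilised loci showing only apparatus-level fluctuation)
populations.

## Synthetic trajectories

`motion_params()` fixes one of four phenomenological motion classes.

**Fractional Brownian motion** (`"fbm"`). Each coordinate is an exact fBm
path with Hurst index $H = \alpha/2$. Increments over one frame are drawn
from the closed-form fractional-Gaussian-noise covariance
(`fgn_covariance()`), scaled so that
$E\big[(x(t)-x(0))^2 + (y(t)-y(0))^2\big] = 4 D t^{\alpha}$, and realised by
multiplying i.i.d. normals with the Cholesky factor of that covariance. The
construction is exact at every $n$ — there is no approximation whose error
would need separate control — and the same covariance serves as the oracle
in the tests (the empirical increment covariance of a large sample is
compared elementwise against the closed form). The factorisation is $O(N^3)$
once per population and is reused across all tracks, which keeps the default
scale (1199 increments, hundreds of tracks) in the tens of seconds.

**Confined diffusion** (`"confined"`). Brownian stepping with per-step
standard deviation $\sqrt{2 D \Delta t}$ per coordinate inside a square of
side $L$ with *reflecting* boundaries, implemented by folding the free path
with the triangle map (method of images; exact in distribution for
symmetric increments). Initial positions are uniform in the square. The
choice of reflecting — rather than periodic or harmonic — boundaries is
deliberate: it is the simplest model with a closed-form long-lag plateau,
$E|r_1 - r_2|^2 = L^2/3$ for two independent uniform points, which makes the
saturation level testable without simulation.

**Immobile loci** (`"immobile"`). The true position is constant; observed
positions add i.i.d. Gaussian localisation noise of standard deviation
$\sigma_\mathrm{loc}$ per coordinate, so the TA-MSD is flat at
$4\sigma_\mathrm{loc}^2$ for every lag $\ge 1$. This is the generative
stand-in for chemically fixed cells imaged under live-cell settings.

Localisation noise is added to *observed* coordinates only, for every
model; the noise-free truth is carried in `x_true_um`/`y_true_um` so
detection and MSD stages can be scored against it.

`sample_population()` draws component membership multinomially from the
specified weights and keeps the generating label per trajectory, which is
what allows every downstream estimate (fractions, component locations) to
be compared with truth.

## Rendering movies

`render_movie()` draws each locus as an isotropic Gaussian PSF integrated
exactly over pixels (differences of normal CDFs, not point sampling), adds
a constant expected background, draws per-pixel Poisson counts, and adds
Gaussian read noise. Defaults (0.16 µm/pixel, PSF σ = 0.12 µm, 2000
photons/spot, background 50, read noise 3) give peak SNR well above 10,
matching bright dCas9-labelled telomere spots on an EMCCD. The pixel-centre
coordinate convention — pixel $(i,j)$, 0-based, has centre
$((j{+}0.5)p, (i{+}0.5)p)$ at pixel size $p$ — is used everywhere;
conversion happens only at I/O.

## Detection, refinement, linking

*Detection* filters each frame with a zero-mean Laplacian-of-Gaussian
kernel at scale $\sigma = r/\sqrt{2}$ for expected spot radius $r$ (the
scale at which the LoG response of a Gaussian blob of that radius peaks),
takes 8-neighbour local maxima above a quality threshold, and suppresses
duplicate maxima closer than $r$, keeping the higher response. The
threshold default is data-driven (`suggest_quality_threshold()`: median +
10 MAD of the first frame's response) because detector settings are
qualitative in practice and any fixed number would be arbitrary across
photon budgets; the threshold is calibrated on synthetic renders, not taken
from any measured data set.

*Refinement* least-squares fits a 2D Gaussian (amplitude, centre, width,
flat background) in an odd window around each detection, falling back to an
intensity-weighted centroid if the optimiser does not converge. Windows
overlapping the border are skipped with a warning and keep the pixel-level
position. On bright synthetic spots this localises to ~0.03 pixel RMSE.

*Linking* is frame-to-frame minimum-total-squared-displacement assignment,
solved exactly with a Jonker–Volgenant-style shortest-augmenting-path
solver (Rcpp) on a padded square cost matrix in which rejection (starting a
new track / leaving a track unmatched) carries a sentinel cost. Exact
assignment was chosen over greedy nearest-neighbour because it is
deterministic, testable against brute-force enumeration, and robust at
moderate spot density. Tracks may bridge up to `max_gap = 2` missing frames
(blinking tolerance at 10 fps without long false bridges), with the
distance gate scaled by $\sqrt{g+1}$ for a gap of $g$ frames. The duration
filter keeps tracks spanning **at least** 20 s — the boundary is inclusive
by this package's convention, so a 201-frame track at 0.1 s is retained.

## MSD computation and anomalous fitting

`compute_tamsd()` evaluates the TA-MSD definition exactly. For gapless
tracks longer than 256 frames the quadratic double loop is rearranged into
cumulative sums and an FFT autocorrelation ($O(N\log N)$), which agrees
with the brute-force loop to ~1e-13 µm²; gapped tracks average only over
index pairs where both frames are present (unbiased under
missingness-at-random blinking). `ensemble_msd()` takes the unweighted mean
over tracks per lag — each track counts once, regardless of length — and
records per-lag standard errors plus the between-track covariance of the
curves.

`fit_anomalous()` fits

$$\mathrm{MSD}(t) = 4 D t^{\alpha} + c$$

over the first 25% of lags by default (long-lag TA-MSD rests on few
displacement pairs and is individually noisy). Two numerical points matter:

1. **The static offset is free by default.** Localisation noise adds a
   constant $4\sigma_\mathrm{loc}^2$ to every observed MSD value. A pure
   power-law fit on the log-log scale absorbs that offset into curvature
   and biases $\alpha$ low — at the package's default generative scale
   ($\alpha = 0.3$, $D = 3\times10^{-3}$, $\sigma_\mathrm{loc} = 0.02$ µm)
   the bias is about $-0.025$, several times the honest standard error.
   The offset term removes it. `offset = "none"` gives the classical
   log-log regression (slope $\alpha$, intercept $\log 4D$), which is also
   used internally for starting values and is exact on noiseless curves.
2. **Standard errors use a sandwich estimator.** TA-MSD values at nearby
   lags within one ensemble curve are strongly correlated, so ordinary
   regression errors understate the seed-to-seed spread of $\hat\alpha$
   roughly tenfold. When the curve carries the between-track covariance
   (any `ensemble_msd()` output), parameter covariance is computed as
   $(J^TWJ)^{-1} J^TW\,\Sigma\,WJ (J^TWJ)^{-1}$ with $\Sigma$ the
   covariance of the mean curve estimated across tracks. In repeated-seed
   checks this makes "within 3 SE" an honest statement.

`estimate_dapp()` is the per-trajectory estimator: ordinary least squares
of the TA-MSD over lags 1–4 against time *with a free intercept*, and
$D_\mathrm{app} = \mathrm{slope}/4$. The intercept again guards against the
localisation-noise offset. No standard per-trajectory estimator exists in
the SPT literature (lag count, intercept handling and linear-vs-anomalous
all vary), so this convention is fixed here and recorded with results. A
consequence worth knowing: for truly immobile loci the short-lag slope
scatters symmetrically around zero, so roughly half of their
$D_\mathrm{app}$ values are non-positive. These are excluded from the
log-domain distribution but counted (`n_excluded_nonpositive`), which also
means mixture fractions for the fixed population are estimated among
positive values and sit below the generating trajectory weight — a known,
reported property of the estimator, not a silent loss.

## Fixed-cell calibration and the anchored mixture

`calibrate_dfix()` fits a single Gaussian to the log₁₀ histogram of
fixed-cell $D_\mathrm{app}$ values; the back-transformed mode $d_\mathrm{fix}$
anchors the fixed component of every subsequent mixture fit acquired under
the same imaging configuration (same optics, same noise, hence the same
thermal/apparatus fluctuation floor).

`fit_mixture()` / `fit_with_fallback()` decompose log₁₀ $D_\mathrm{app}$
into up to three Gaussian components with the fixed component's **mean held
exactly** at $\log_{10} d_\mathrm{fix}$ and its width tied to the
calibration fit's width within a factor of two; slow/fast means, all other
widths, and all weights are free. The log₁₀ axis is the natural choice for
a distribution spanning two to three orders of magnitude — on a linear axis
the fast component would be a tail, not a peak.

Design choices that were genuinely open, and how they were settled:

* **Likelihood, not histogram least squares, by default.** The classical
  presentation fits Gaussian peaks to the binned density. Implemented and
  measured, histogram least squares at a few hundred trajectories leaves
  weight estimates with several-point scatter — too noisy to resolve
  five-percentage-point differences reliably — because binning discards
  information and the residuals are far from homoscedastic. The default is
  therefore maximum likelihood via EM on the raw log₁₀ values (the anchored
  mean simply stays fixed in the M-step), which brings weight noise close
  to the multinomial floor. The histogram variant remains available as
  `method = "histogram"`, and the histogram itself (Freedman–Diaconis bins,
  configurable) is always computed for plotting and metadata.
* **Label-meaningful bands.** Component means are band-constrained (±0.45
  dex) around deterministic initial locations found by density-peak
  picking: the anchor for *fixed*, the nearest substantial peak above the
  anchor for *slow*, the highest such peak for *fast*. Peaks below the
  anchor are ignored — density there belongs to the fixed population's
  left tail. Without the bands, a three-component fit on two-component data
  can relocate a "fast" component onto the slow peak and scramble labels;
  with them, labels are stable and the ordering
  $\mu_\mathrm{fixed} < \mu_\mathrm{slow} < \mu_\mathrm{fast}$ holds in
  every successful fit. Initialisation is deterministic (no random
  restarts), so fits are reproducible without seeds.
* **Component failure and fallback.** A component fails if the fit does not
  converge, its weight falls below 2%, its weight's standard error (from
  the observed information, delta method over a log-ratio weight
  parameterisation) exceeds the weight, the mean ordering breaks, or —
  the decisive criterion in practice — *removing it improves the BIC*.
  The per-component BIC test is what reliably distinguishes "this
  population is absent" from "this population is small": a spurious third
  component can always sculpt a real peak's shoulder, but it cannot pay
  for its three parameters. Failed components are removed and the reduced
  mixture refitted (the anchor is preserved whenever the fixed component
  survives); after at most one removal round a single-component fit is the
  last resort, and `fallback_applied` records what was dropped.

## The perturbation presets

No raw trajectory data accompany the study this package emulates, so the
perturbation conditions are *generative*: each preset re-weights the same
three motion classes (`condition_presets()`), with parameters chosen once
as calibrated, field-plausible values —

* slow: fBm, $\alpha = 0.35$, $D = 6\times10^{-3}$ µm²/s^α,
  $\sigma_\mathrm{loc} = 0.02$ µm;
* fast: fBm, $\alpha = 0.45$, $D = 6\times10^{-2}$ µm²/s^α,
  $\sigma_\mathrm{loc} = 0.02$ µm;
* fixed: immobile with an effective jitter $\sigma_\mathrm{loc} = 0.09$ µm.

The fixed-population jitter deserves a note: published fixed-cell controls
report thermal-fluctuation diffusion constants near $0.7\times10^{-3}$
µm²/s, which constrains but does not determine the localisation noise.
With the package's $D_\mathrm{app}$ estimator, $\sigma_\mathrm{loc} = 0.09$
µm lands the fixed-population mode at $\sim 5$–$7\times10^{-4}$ µm²/s, the
right scale; this value is a **calibration of the preset**, not a measured
localisation precision, and plausibly folds in residual stage drift and
vibration rather than pure photon-limited error.

Baseline weights are (fixed 0.20, slow 0.50, fast 0.30); *released* drops
the fixed class and raises fast (0 / 0.45 / 0.55); *rigid* drops fast and
raises fixed (0.55 / 0.45 / 0); *crowded* makes fixed dominant
(0.60 / 0.40 / 0); *compacted* raises fast (0.15 / 0.40 / 0.45). The
pipeline's regression property is that the *orderings* of fraction changes
across conditions reproduce the perturbation phenomenology by
construction — it validates the pipeline's ability to recover what was put
in, and makes no biological claim.

Problem sizes throughout (300 trajectories per condition, 1200 frames,
500–1000 tracks in recovery tests, 20 replicates in fraction-recovery
checks) were chosen to match the scale of the emulated experiments while
keeping a full run in minutes on one core.

## What the synthetic data do not show

The generator emulates the statistical structure the analysis assumes —
stationary motion classes, homogeneous parameters within a class, Gaussian
localisation noise, constant background, no photobleaching, no drift, no
nuclear boundary, no per-cell heterogeneity. Passing tests therefore
demonstrate estimator correctness and pipeline fidelity *under those
assumptions*, not robustness to the full mess of real nuclei: broad
within-population parameter spread, motion-blur-correlated noise, spot
merging at high density, or cell-to-cell random effects (the package
reports trajectory counts only, with no per-cell model). Real-data peaks in
the $D_\mathrm{app}$ distribution are broader than the near-delta clusters
homogeneous parameters produce; the mixture machinery tolerates both, but
recovery tolerances quoted in the tests are statements about the synthetic
regime.

## Degenerate inputs and tie-breaks

Tracks need ≥ 2 samples for a TA-MSD and ≥ `n_lags + 1` samples for
$D_\mathrm{app}$; empty ensembles raise errors rather than returning empty
curves. Non-finite pixels are rejected by the detector. Equal-quality
duplicate detections are suppressed deterministically (response order). The
assignment solver receives forbidden pairings as large sentinel costs and
never links across them; ties in cost resolve to the first augmenting path,
which is deterministic for a fixed input order. Weight normalisation in
mixture results is exact (weights are ratios of EM responsibilities);
fractions always sum to 100 within 1e-6.
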