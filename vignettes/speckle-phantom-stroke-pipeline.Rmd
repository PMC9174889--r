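---
title: "Temporal speckle contrast analysis of photothrombotic stroke: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal speckle contrast analysis of photothrombotic stroke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckleflow)
```

## The measurement model

Laser speckle contrast imaging infers relative blood flow from the blurring
of laser speckle during a camera exposure.  The package implements the
*temporal* contrast statistic: for a stack of $N$ frames the per-pixel
contrast is

$$K_t(x,y) = \frac{\sigma(x,y)}{\langle I(x,y)\rangle},$$

the standard deviation over frames divided by the mean, and the flow index
is $1/K_t^2$.  Moving scatterers decorrelate the speckle field over a
characteristic time $\tau_c$ inversely related to their speed; integrating
the intensity over an exposure $T$ yields the classical contrast

$$K^2(x) = \frac{e^{-2x} - 1 + 2x}{2x^2}, \qquad x = T/\tau_c,$$

for a single-exponential field autocorrelation
$|g_1(\tau)| = e^{-\tau/\tau_c}$ and unit coherence factor.  For $x \gg 1$
this gives $1/K^2 \approx x + \tfrac12$, so the flow index is linear in
speed up to a small additive constant — the regime in which the analysis is
quantitative.  All flow values are relative; the pipeline never claims
absolute velocities, and relative cerebral blood flow (rCBF) is always the
flow index normalized to a pre-stroke baseline acquisition.

Default acquisition parameters are 40 frames at 20 ms exposure.  The frame
interval is not part of the temporal-contrast definition; we default to
25 ms (a 5 ms readout gap), a typical value for this camera class.  With
baseline $\tau_c$ near 1 ms, frames are effectively independent samples.

## The dynamic-speckle phantom

Because no raw imaging data accompany the study conditions this package
targets, every stage is validated against a synthetic phantom with known
ground truth:

* **Flow maps** (`make_flow_map()`): straight vessel tubes over a uniformly
  perfused parenchyma, each pixel carrying a relative speed $v$, a
  compartment label, and $\tau_c = a/v$.  Since only flow *ratios* matter,
  the calibration constant defaults to $a = 1$ ms per speed unit; baseline
  parenchyma speed is 1, i.e. $\tau_c = 1$ ms and $x = 20$ at the default
  exposure — comfortably inside the linear regime.
* **Speckle synthesis** (`simulate_speckle_stack()`): each pixel is an
  independent complex circular-Gaussian field realized as a first-order
  autoregressive process on a sub-step grid, with step correlation
  $e^{-\delta t/\tau_c}$.  A frame is the mean of $|E|^2$ over the
  sub-steps spanning the exposure; between frames the field is advanced by
  one exact autoregressive jump across the readout gap, so continuity costs
  nothing.  The sub-step defaults to $\min(\tau_c^{\min}/8,\, T/16)$;
  anything coarser than $\tau_c/4$ is refused because undersampled dynamics
  bias the frame statistics.  The Gaussian-field route guarantees that the
  simulated ensembles obey the closed form $K^2(x)$ above, which the test
  suite checks directly at $x \in \{1, 10, 100\}$ — the simulator and its
  oracle share no code.
* **Stroke scenarios** (`stroke_scenario()`, `stroke_scenario_6h()`):
  photothrombosis is represented purely as piecewise-linear, per-compartment
  flow multipliers (irradiated core, large/small vessels inside the spot,
  everything outside), all equal to 1 at time 0.  The built-in node values
  are the published group means for the 6-hour course after a 2-min
  exposure and the 14-day courses at 1-, 2- and 5-min light doses; the
  light-only control stays within 10% of baseline by construction.  The
  day-scale courses apply their depression uniformly across the 2-mm
  evaluation circle, because that is the region in which the published
  means were measured; the acute 6-hour course confines the core multiplier
  to the 1-mm spot.
* **Section stacks** (`make_section_stack()`): coronal neuron-stain images
  with an unstained infarct region per slice whose areas follow an
  ellipsoidal-cap axial profile, scaled so the analytic volume
  $\sum_i S_i \, h$ hits the target to within half a voxel (the pixel
  budget is rounded once, apportioned by largest remainder, and drawn as
  the nearest tissue pixels to the infarct center).  The binary vessel
  channel realizes requested vascular-area fractions exactly at pixel
  resolution inside two 1 mm × 1 mm hemispheric ROIs.
* **Beam scenes** (`make_beam_scene()`): parametric spot images (Gaussian,
  top-hat, Gaussian-plus-halo) with analytically known half-intensity
  radius and total power.  No photon transport or skull scattering is
  modeled; these are measurement phantoms, not optics simulations.

### What the phantom does *not* emulate

Pixels are statistically independent (no speckle grain correlation across
pixels, i.e. unit coherence factor and no camera point-spread function);
there is no static-scattering layer mixed into perfused pixels, no
physiological pulsation, no motion artifacts, and no registration error
between time points.  Passing tests therefore demonstrate correctness of
the estimators under the stated statistical model, not robustness to every
nuisance in vivo.  "No-flow" tissue is deliberately given slow residual
dynamics ($\tau_c = 200$ ms) rather than a frozen field, because a truly
static field has zero temporal contrast and a divergent flow index; a
frozen-field label exists only for artifact testing.

## ROI analysis and the normalization order

Regions of interest are defined in bregma-relative stereotaxic millimetres
(AP negative caudal, mapped downward in the image; ML rightward) and
rasterized by the pixel-center-in-shape rule — simple, deterministic, and
tolerance-tested against analytic areas.  Vessel ROIs average the full
vessel width, not just the centerline.

Two normalization orders exist for ROI summaries, and they differ in a way
that matters:

* `relative_cbf()` divides flow maps pixel by pixel (the exact per-pixel
  contract: `rcbf = flow / baseline_flow`).  Because each pixel's flow
  index is the *inverse* of a noisy 40-frame contrast estimate, the
  per-pixel ratio inherits a Jensen-type upward inflation of a few percent
  ($\mathrm{Var}(\hat K^2)/K^4 \approx 2/N$ dominates), independent of the
  true multiplier.
* `roi_flow_course()` averages the flow index over the ROI first and then
  normalizes by the ROI-mean baseline flow (mean-then-divide).  The
  matched inflation factors of numerator and denominator cancel, so
  recovered multipliers are unbiased to well below the acquisition noise.

The package therefore uses mean-then-divide for all ROI time courses (it is
also the lower-variance statistic); the per-pixel map remains available for
visualization and pixelwise analyses, with the inflation documented.  Group
comparisons use classical one-way ANOVA with the conventional significance
codes (`ns`, `*`, `**`, `***` at 0.05, 0.01, 0.001); no multiple-testing
correction is applied, matching common practice for these group-level
summaries, and replicate aggregation reports mean ± SD.

## Vascular density and infarct volumetry

Vascular density is the fraction of vessel-positive pixels inside a
1 mm × 1 mm ROI — an exact pixel-count ratio.  Binarization defaults to
Otsu's threshold (the choice is recorded in the result); a fixed threshold
is available for reproducibility tests.  No skeletonization or diameter
weighting: the metric is areal fraction only.

Infarct volume follows the rectangular rule
$V = \sum_i S_i \, h$ with $h = 100\ \mu m$ slice spacing.  "Unstained" is
operationalized as intensity below half the median of the tissue (the
published procedure names no threshold; the 50% fraction is exposed as a
parameter and logged).  The tissue median is robust while the infarct
covers less than half the tissue.  Connected components smaller than
0.01 mm² are suppressed and the largest component retained, so isolated
dark pixels do not masquerade as infarct.  No 3-D interpolation between
slices and no edema correction are attempted.

## Beam metrics

The spot center defaults to the intensity centroid of the top-decile
pixels; the radial profile uses 0.02-mm annular bins, and the
half-intensity distance is the first half-crossing of the central value,
linearly interpolated between bins (errors if there is no crossing).
Transmitted power ratios subtract a 10-pixel border median from each image
before summation, so a diffuse background does not leak into the ratio.
The ambiguous published "12% widening" figure has no agreed formula, so
the package reports raw half-distances only.

## Numerical and reproducibility choices

* Population (divide-by-$N$) standard deviation in $K_t$: exact closed-form
  toy cases; at $N = 40$ the difference from the sample form is < 1.3% and
  cancels in baseline-normalized ratios.
* Invalid pixels (zero mean, contrast below $\varepsilon = 10^{-3}$)
  propagate as masks and are excluded from ROI statistics, never imputed;
  thresholding on $K_t$ was preferred over clipping the flow index so that
  static-scatterer artifacts stay visible.
* All maps are carried in floating point; quantization happens only at
  export (16-bit stacks, 32-bit float derived maps, each with a JSON
  sidecar recording the scale, so a read-back stack re-exports
  bit-identically).
* Every stochastic step flows from one explicit integer seed; identical
  configurations are reproducible bit for bit, which the tests assert.
* Detector noise defaults to none (pure speckle); additive-Gaussian and
  scaled-Poisson models are available.

Test and validation problem sizes were chosen for desk-scale runs: 64 × 64
frames for recovery checks (the 1-mm spot ROI then holds ≈ 300 pixels, the
2-mm circle ≈ 1250, giving ROI standard errors well under 0.01 rCBF),
2000-frame single-pixel ensembles for the contrast oracle, and 30-slice
section stacks at 0.02 mm/px for volumetry.

## A worked miniature

```{r example, eval = FALSE}
fm  <- make_flow_map(64, 64, 0.05)              # uniform cortex, tau_c = 1 ms
cal <- calibration(0.05, bregma_pixel = c(32, 32))
sc  <- stroke_scenario_6h(spot_center_ap_ml = c(0, 0))

base <- simulate_speckle_stack(fm, acquisition_config(pixel_size_mm = 0.05,
                                                      seed = 1))
post <- simulate_speckle_stack(apply_scenario(fm, sc, t = 6, cal),
                               acquisition_config(pixel_size_mm = 0.05,
                                                  seed = 2))
spot <- circular_roi(c(0, 0), 1, "spot")
roi_flow_course(list(base, post), spot, cal, times = c(0, 6))
```

The recovered 6-hour spot mean sits a little above the configured 0.30
multiplier: with $x_0 = 20$ the additive $+\tfrac12$ in
$1/K^2 \approx x + \tfrac12$ maps a true multiplier $m$ to
$(m x_0 + \tfrac12)/(x_0 + \tfrac12)$, about $+0.02$ at $m = 0.3$.  This
is a property of the flow index itself, shared by any analysis of this
type, and stays within the ±0.05 recovery tolerance the validation suite
enforces.

## Known limitations

Single-exponential $g_1$ (unordered/Brownian-type motion) is the default
correlation model; a Gaussian-shaped $g_1$ would change the $K^2(x)$
mapping and is not the validated path.  The $\tau_c \propto 1/v$ link is a
modeling convention — adequate for relative comparisons, not a velocimetry
calibration.  Acquisitions across days are assumed co-registered; no
registration is attempted.  Spatial and multi-exposure contrast estimators
are out of scope.
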