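---
title: "Identifying images from visual-cortex fMRI with population receptive fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying images from visual-cortex fMRI with population receptive fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfident)
```

## The method in one paragraph

Every fMRI voxel in early visual cortex aggregates neurons whose receptive
fields cluster in a compact region of the visual field. This package models
that region — the population receptive field (pRF) — as an isotropic 2-D
Gaussian with center $(x_0, y_0)$, size $\sigma$ and amplitude $\beta$,
estimates it from responses to a sweeping-bar mapping stimulus, and then
uses the estimated pRFs as a forward encoding model: for any candidate
image it predicts the response of every voxel, and a presented image is
identified by finding the candidate whose predicted response profile
correlates best (Pearson's $r$) with the measured profile across voxels.
Because the model is generative, the candidate set may contain images that
were never shown, which drives the chance level of correct identification
($100/k$ % for $k$ candidates) arbitrarily low.

## The forward model

The pRF weight of pixel $i$ at visual-field position $(x_i, y_i)$ is

$$w_i = \exp\!\left(-\frac{(x_i - x_0)^2 + (y_i - y_0)^2}{2\sigma^2}\right).$$

During mapping, the neural drive at frame $t$ is the overlap
$\sum_i w_i\,a_{it}$ of the pRF with the binary bar aperture $a_{\cdot t}$.
The BOLD prediction is this drive convolved with a two-gamma hemodynamic
response function (HRF) and scaled by $\beta$. The default kernel uses a
response gamma with delay 6 s and unit dispersion (kernel peak at 5 s) and
an undershoot gamma with delay 16 s at ratio 1/6, sampled at the TR (1.5 s)
over a 32 s window and normalized to unit peak. These canonical values were
chosen so the forward model is fully self-contained; `refit_hrf()`
optionally re-estimates peak delay and undershoot ratio across the whole
data set by grid search, holding fitted pRF geometry fixed.

Prediction for candidate images uses two rules, neither convolved with the
HRF (convolution would only rescale whole profiles):

* **Binary synthetic stimuli** (hexagonal patterns): the normalized overlap
  $\hat r = \sum_i w_i S_i \big/ \sum_i w_i$, with $S_i \in \{0,1\}$. Both
  sums run over the circular stimulus area, so $\hat r \in [0, 1]$ and a
  full-field stimulus maps to exactly 1.
* **Natural images**: the pRF-weighted local contrast energy
  $\hat r = \frac{1}{\sum_i w_i}\sum_i w_i (L_i - \bar L)^2 / \bar L^2$,
  with $\bar L$ the unweighted mean luminance over the window. This is the
  squared RMS contrast weighted by the pRF; the API says "contrast energy"
  deliberately — no square root is taken.

Two readings of the "spatial window" are possible because the numerator
and denominator of the overlap rule could in principle run over different
pixel sets. The default takes both over the entire stimulus area, which
makes the full-field normalization exact and avoids an arbitrary cutoff;
`window_sigma` truncates the numerator window to a disc of $k\sigma$ for
the narrower reading. Likewise `weighted_mean = TRUE` switches $\bar L$ to
the pRF-weighted mean for users who prefer that interpretation; defaults
follow the unweighted reading.

## Estimation

`fit_prf()` minimizes the residual sum of squares between prediction and
measurement per voxel, coarse-to-fine:

1. **Grid stage.** Candidate centers on a square grid covering
   $\pm 1.2 \times$ the aperture radius (so border pRFs are not clamped) at
   0.25° spacing by default, crossed with 12 log-spaced sizes between 0.1°
   and 5°. For every candidate the amplitude and a baseline term are solved
   in closed form, so the grid stage reduces to matrix products.
2. **Refinement.** Nelder–Mead on $(x_0, y_0, \log\sigma)$ from the best
   grid point, with closed-form amplitude inside the objective and a
   relative RSS tolerance of $10^{-9}$. Parameterizing $\log\sigma$ keeps
   the size positive without constraints. A refined point that wanders
   beyond twice the search bound is discarded in favor of the grid
   optimum.

Fit quality is variance explained, $1 - \mathrm{RSS}/\mathrm{TSS}$, floored
at 0. The amplitude's sign is unconstrained: a negative $\beta$ simply
signals an artifactual fit, and such voxels are removed downstream by the
positive-t filter rather than by constraining the optimizer. Constant
time series and all-blank aperture sequences are rejected with errors, not
silently fitted.

## Measured profiles and voxel selection

`build_block_design()` models each image presentation as a 9 s boxcar
(6 frames at TR 1.5 s) followed by 12 s of mean luminance, convolved with
the same HRF, plus an intercept. `fit_glm()` is plain OLS with
homoscedastic per-voxel variance — the block design leaves little serial
structure at this TR, and an optional single-pass Cochrane–Orcutt AR(1)
prewhitening (`ar1 = TRUE`) is available for data where that assumption
bites. Each voxel's response to each image is summarized by the t-value of
its regressor; profiles over voxels feed the identification step.

One numerical guard matters only for simulations: with exactly zero noise
the residual variance is 0 and t-values would be infinite, so the residual
variance is floored at machine epsilon. The floor rescales each profile by
a positive constant, which Pearson correlation ignores.

Voxels enter identification only if they pass three filters: positive
t-value, pRF eccentricity between 0.5° and 4.5° (inside the mapped
aperture, away from fixation-instability and edge artifacts), and variance
explained above 55%. The positive-t rule needs a per-voxel reduction and
the natural choices differ in strictness, so it is configurable:
`"any_image"` (default — a voxel that responds positively to at least one
image carries signal), `"all_images"`, `"localizer"` (positive response to
a designated full-field stimulus; use this when such a regressor exists,
matching the common practice of a localizer-based global drop), or
`"none"`.

## Identification, set-size curves, confidence

`identify_images()` takes the argmax of each row of the measured ×
predicted correlation matrix; ties (measure-zero on real data, common in
toy tests) break deterministically toward the lowest candidate index with
a warning. `set_size_curve()` grows the candidate set: for each size $k$
it draws `n_boot` (default 1000) random sets — the true prediction plus
$k-1$ distractors sampled without replacement — and reports the mean
accuracy with a percentile 95% interval (2.5/97.5). When $k$ equals the
pool size there is exactly one possible set and the interval collapses.
`shuffle = TRUE` re-draws the designated "true" candidate uniformly within
each sampled set, which makes correct identification a Bernoulli trial
with probability exactly $1/k$; this is the package's empirical chance
calibration. Per-image confidence is
$r(i_m, i_p) - \frac{1}{N}\sum_j r(i_m, j_p)$, the margin by which an
image's own prediction beats the average candidate; the $j = i$ term is
included (it is zero), so $N$ is the full set size.

## The synthetic stimuli

The mapping stimulus is the conventional sweeping bar: radius 5.5°, bar
width radius/4 = 1.375°, four orientations × two directions, 20 steps of
0.55° per pass, and a 20-frame mean-luminance block after every
horizontally or vertically oriented pass — 240 frames of 1.5 s. Apertures
are binary contrast masks; the high-contrast carrier inside the bar
(binarized bandpass noise at 1.5 cycles/deg, `bandpass_noise()`) is kept
for rendering demonstration stimuli but deliberately not modeled in the
forward model, which operates on stimulus energy.

Identification stimuli are hexagonal-grid patterns: 60 cells that are
independently filled or left at mean luminance, giving $2^{60}$ possible
images. The tiling geometry is fixed as layout `"hex60"`: a pointy-top
hexagonal lattice with circumradius 0.67°, keeping the 61 cells whose
centers lie within (radius − cell size) of fixation — five complete rings
— and excluding the central cell, which hosts the fixation dot, for
exactly 60. Cell membership of a pixel is its lattice Voronoi cell, which
is precisely the hexagon. Coordinates are degrees of visual angle, x
rightward, y upward; because matrix rows grow downward the renderer
applies an explicit y-axis flip.

Natural-image preprocessing resamples a square luminance matrix to the
grid, fades it into the surround with a raised-cosine circular mask
(weight 1 inside radius − 0.9°, half-cosine ramp to 0 at the radius),
and rescales deviations from mean luminance until the whole-image RMS
contrast reaches 50%. Clipping to [0, 1] can shave the achieved contrast;
the rescaling iterates up to three times and a residual deviation above 2%
relative draws a warning. The normalization is computed after masking, on
the whole image; since the procedure normalizes contrast, the output is
invariant to affine rescalings of the input luminance. Because no image
data set ships with the package, `simulate_natural_texture()` generates
procedural stand-ins (low-pass noise under a spatially varying contrast
envelope) that exercise the natural-image path end to end; they are
synthetic and share only the low-level statistics the contrast-energy
model reads.

## What the simulator emulates — and what it does not

`sample_prf_population()` draws voxels area-uniformly over an eccentricity
annulus (default 0.5–4.5°) with the linear size–eccentricity rule
$\sigma = 0.1\,\mathrm{ecc} + 0.3$ plus 0.05° jitter — values typical of
V1 at these eccentricities — and log-normal amplitudes (sdlog 0.2).
Sessions add independent Gaussian noise per frame (optionally AR(1),
`ar1_rho`), matching the OLS assumptions of the GLM and keeping
chance-level tests clean.

The simulator captures linear spatial summation, hemodynamic convolution,
amplitude heterogeneity and measurement noise. It does **not** capture
draining veins, partial-volume effects, motion, physiological noise,
BOLD nonlinearity, or responses to orientation and spatial-frequency
structure that the contrast-energy model ignores. Passing closure tests
therefore certify the pipeline's internal consistency — that estimation
inverts the generative model and identification is calibrated — not that
real cortex obeys the model; on scanner data the attainable accuracy is an
empirical question.

## Problem sizes and numerical choices in the shipped tests

The test suite and the acceptance script run the full pipeline at desk
scale: grids of 3–4 pixels/degree (33–44 pixels across 11°), populations
of 50–120 voxels, 15-image sessions with pools of 200–250 candidates, and
a coarse search of 0.5° spacing with 8 sizes ahead of refinement. These
sizes were chosen so each stage remains well-resolved (the hex cells span
≥ 4 pixels; the bar spans ≥ 4 pixels across its width) while a complete
run takes minutes on one CPU. Recovery tolerances in the tests — positions
and sizes within 0.05° noiseless, median position error under 0.25° at 10%
noise — hold with large margins (observed noiseless errors are ~10⁻⁵°).

## Known limitations

* The pRF is a single isotropic Gaussian: no surround suppression,
  elliptical shapes, or compressive spatial summation.
* Predictions read contrast energy only; orientation, spatial frequency
  and semantic content are invisible to the model.
* Preprocessing (motion correction, detrending, percent-signal scaling) is
  the caller's responsibility; `beta` absorbs global scale.
* The identification step assumes the candidate pool contains a prediction
  for every presented image; open-set identification is out of scope.
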