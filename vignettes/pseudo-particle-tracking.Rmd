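---
title: "Pseudo-particle tracking of wound-edge dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-particle tracking of wound-edge dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundtrack)
```

## The problem

In a wound-healing scratch assay a confluent cell monolayer is scratched and
the two flanking cell layers migrate back into the gap. Phase-contrast
time-lapse imaging of this process is cheap and non-invasive, but classical
single-particle tracking (SPT) is hard to apply: cells in a dense, cohesive
sheet change shape and density continuously and individual cells are
difficult to follow. `woundtrack` instead treats each wound edge — the free
boundary of a cell layer — as a single elastic membrane, and describes its
dynamics by the motion of *pseudo-particles*: `N` points placed at uniform
arc length along the edge polyline in every frame, like pearls on a
necklace. Particle `i` is always the i-th point from the top endpoint
(arc-length rank identity, not nearest-neighbour linking), so trajectories
may cross when the front develops invaginations or protrusions; that is a
property of the representation, not an error.

## Pipeline

Per frame, in order:

1. **Equalization (CLAHE).** Contrast-limited adaptive histogram
   equalization with 50×50 px tiles and a clip limit of 40 counts per bin.
   Tile size is in *pixels* (not a grid count); partial border tiles are
   equalized as-is and bilinear interpolation between neighbouring tile
   mappings suppresses seams. Equalization maps all frames onto the full
   intensity range, making frames acquired hours apart comparable.
2. **Texture binarization.** Each frame is tessellated into 12×16 px tiles
   (10,000 tiles for a 1200×1600 frame). Every pixel gets a local binary
   pattern (LBP) score: the count, over its 8 neighbours, of comparisons
   where centre ≥ neighbour. This is deliberately the *count* variant
   (range 0–8), with ties scoring 1 — not the classical weighted 0–255
   code. The 9-bin score histogram of each tile is its texture feature;
   PCA reduces the 10,000×9 feature matrix to 5 components, and a
   2-component full-covariance Gaussian mixture (EM, k-means
   initialization under a fixed seed) classifies tiles as cell layer or
   background. Because the count uses only ≥ comparisons it is invariant
   under any increasing intensity transform.
3. **Label resolution.** The mixture does not know which component is the
   cell layer. Phase-contrast background is much smoother than the granular
   cell texture, so the component with the larger mean frequency of the
   all-ties score LBP = 8 is taken as background; a manual override is
   available.
4. **Edge extraction.** Boundaries of connected background regions are
   traced (Moore neighbour tracing); the contour of greatest arc length is
   the wound-gap boundary while the two fronts remain separate. Its points
   on the top and bottom border rows are discarded and the two longest
   remaining arcs are the lateral sides: smaller mean x = left front `L`,
   larger = right front `R`. Fronts are normalized to strictly increasing
   y (mean x per y). Frames in which the contour no longer spans the frame
   vertically (closed wound) truncate the analysis, with a warning.
5. **Tracking and statistics.** Uniform arc-length sampling gives `N`×`M`
   x- and y-coordinate matrices per side (defaults N = 103, M = 40 at
   0.25 h/frame). The right front is mirrored (`x ← width − x`) so both
   fronts advance in +x, and positions are centred so the frame-0 ensemble
   mean of x is zero. The statistics are strictly *ensemble* quantities
   (means, velocity `V(τ) = X(τ+1) − X(τ)`, acceleration, the ACF anchored
   at t₀ = 0, and the mean squared displacement from t₀ = 0), because long
   stationary trajectories are not available in a closing wound. The ACF is
   *not* a time-averaged ACF.
6. **Model fits.** The quiescence-then-drift model `x(t) = v_d (t − τ₁)`
   is fitted by OLS inside a drift window; velocity-increment magnitudes
   within the window are histogrammed (Freedman–Diaconis bins) and fitted
   by Poisson-weighted OLS against the half-Gaussian `2·G(|ΔV|; 0, σ²)`
   and exponential `exp(−|ΔV|/λ)/λ` densities. The larger adjusted R²
   indicates the better-supported tail law; closed-form MLE estimates are
   available as a cross-check. Agreement between two segmentation routes
   is summarized by pooled Pearson correlations of coordinates and of the
   ensemble series.

An Otsu baseline (blur → global Otsu threshold → morphological closing and
opening) and a reader for hand-traced front files (one "x y" pair per line)
provide alternative segmentation routes through the same downstream
machinery.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `clahe_tile_size` | 50×50 | px | reference CLAHE geometry |
| `clahe_clip_limit` | 40 | counts/bin | bounds noise amplification |
| `lbp_tile_height/width` | 12×16 | px | complete tessellation of 1200×1600; small enough for sharp fronts, large enough for stable histograms |
| `pca_n_components` | 5 | — | retains essentially all feature variance |
| `n_particles` | 103 | — | reference ensemble size |
| `frame_interval` | 0.25 | h | 4 frames/hour acquisition |
| `pixel_size` | 1 | μm/px | **defaulted to 1 ⇒ results in px units**; set it to get μm/h drift velocities — the pipeline warns when defaulted |
| `otsu_blur_sigma`, `otsu_morph_radius` | 2, 5 | px | unstated upstream; conventional smoothing scales |
| `drift_window` | auto | h | overridable by eye, see below |

## Drift-window detection

The drift model is fitted between a lower bound τ₁ʹ (onset) and an upper
bound τ₂. For τ₂ the rule is: the first time after onset at which the
ensemble mean velocity, smoothed by a running median of 5 frames, returns
to ≤ 0 for 3 consecutive frames — otherwise the end of the series. For the
onset we found velocity thresholding unusable at tile resolution: the
extracted front moves in steps of a whole tile column, so the per-frame
mean velocity is a spike train. Instead the centred mean position is fitted
by a flat-then-linear piecewise model and the breakpoint minimizing the
total squared error is taken as the window start. Both bounds are reported
in every fit result and can be overridden (`drift_window = c(t_low,
t_high)`).

## Classifier scope: per frame or per sequence

By default the PCA + mixture classifier is fitted independently per frame.
During late closure, however, the class balance shifts (less background,
more cell), and a refitted mixture moves its decision boundary: we measured
boundary tiles being absorbed into the background component at up to half a
tile of systematic front lag late in synthetic sequences, which biases the
fitted lag time upward by ~0.5 h and the drift velocity downward by ~5%.
For trajectory extraction from a time-lapse we therefore recommend — and
the validation suite uses — `fit_on = "first"`: fit the classifier on
frame 0 and apply it to the whole sequence. Per-frame fitting remains the
default because it matches the per-frame feature-matrix description of the
procedure and is the right choice when illumination drifts between frames.

## What the synthetic generator emulates — and what it does not

`synthetic_wound_spec()` renders two cell layers of granular speckle
texture (smoothed seeded noise at a 2 px grain, contrast 35 intensity
units), a thin bright halo hugging each front as phase-contrast optics
produce, and a smooth, low-variance dark gap. Fronts are straight lines
plus a static sinusoid (amplitude ~8 px at the 300×400 test scale, i.e.
about half a tile width, which dithers the tile quantization) plus a
smooth per-frame perturbation (sd 1 px); they are quiescent for
`lag_tau1` frames and then advance at `drift_vd` px/frame, following the
same piecewise-linear law the fit assumes. Defaults mirror the reference
acquisition (1200×1600 px, 4 frames/h, 40 frames, τ₁ = 5 h); the
validation suite scales to 300×400 px for runtime. All randomness flows
from one seed (rendering uses a fixed offset substream), so a spec is a
complete, reproducible description of a dataset.

Not emulated: phase-contrast optics (point-spread function, halo physics),
cell-scale structure (nuclei, lamellipodia), debris is available only as an
option, illumination drift, and closure itself (specs implying closure are
rejected at validation). A green end-to-end test therefore establishes that
the chain *segmentation → front extraction → tracking → fitting* recovers a
known drift law from images with realistic texture statistics — not that
the segmenter handles every real-world artifact.

## Numerical choices and degenerate inputs

- **Quantization.** Front positions from texture masks are quantized to the
  tile width; ensemble means dither this to ~1 px, and OLS over the drift
  window is unbiased under the resulting serially-correlated noise.
- **σ convention.** Ensemble standard deviations use the population divisor
  N, consistent with the moment notation of the ACF; a `sample = TRUE`
  switch exists.
- **ACF at zero spread.** Lags where the ensemble standard deviation
  vanishes (e.g. a tile-straight front) yield `NaN` with a warning, never
  an error.
- **τ₁ uncertainty.** τ₁ = −intercept/slope; its standard error is
  propagated from the OLS (intercept, slope) covariance by the delta
  method.
- **Histogram weights.** Poisson counting uncertainty: weighted OLS on the
  density scale, first with weights 1/count, then one reweighting pass with
  expected counts from the fitted model. Weighting by observed counts alone
  biases scale estimates low, because tail bins that fluctuate downward
  receive the largest weights; expected counts are the consistent Poisson
  variance estimate. Empty bins are excluded.
- **Degenerate inputs.** Constant frames: CLAHE returns a constant; Otsu
  and the texture classifier raise descriptive errors ("degenerate
  features"). Merged fronts raise a frame-indexed error that the pipeline
  converts into truncation of M. Zero-length fronts and single-point
  windows are validation errors.
- **Units.** Everything is computed in px and px/frame; μm/h conversions
  happen only when `pixel_size` is set, preventing silently wrong physical
  numbers.

## Known limitations

- TIFF input is not supported in this installation (no offline TIFF
  reader); use per-frame PNG, PGM or CSV.
- The longest-contour rule assumes the scratch spans the frame vertically;
  horizontal scratch geometries must be rotated first.
- Tile-resolution fronts limit single-frame front accuracy to roughly half
  a tile; statements about sub-tile dynamics rely on ensemble averaging.
- The increment-tail fits compare two candidate laws only; full
  stochastic-process characterization (anomalous exponents, ergodicity) is
  out of scope.
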