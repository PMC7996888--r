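# woundtrack

Single pseudo-particle tracking of wound-edge dynamics in phase-contrast
time-lapse images of the scratch assay.

## The problem

In a wound-healing scratch assay, a confluent cell monolayer is scratched
and the two flanking layers migrate back into the gap. Phase-contrast
time-lapse movies of this process resist classical single-particle
tracking: cells in a dense cohesive sheet deform continuously and are hard
to follow individually. `woundtrack` sidesteps the problem by treating each
wound edge (left `L`, right `R`) as one elastic membrane and tracking *N*
**pseudo-particles** placed at uniform arc length along the edge polyline
in every frame. The resulting N × M coordinate matrices (N particles, M
frames) support standard ensemble SPT statistics and model fits.

The package is aimed at quantitative cell-migration studies: it turns a raw
image stack into drift velocities, velocity-increment distributions,
autocorrelations and cross-method agreement tables, with a fully synthetic
ground-truth generator for validation.

## Method in brief

Per frame: CLAHE contrast equalization (50×50 px tiles, clip limit 40) →
tessellation into 12×16 px tiles → per-pixel local binary pattern score
(count of `centre ≥ neighbour` over the 8-neighbourhood, range 0–8) →
9-bin score histogram per tile → PCA (5 components) → 2-component Gaussian
mixture → binary cell/background mask → longest background-boundary
contour = wound gap → split into `L`/`R` fronts → N points at uniform arc
length. Alternative segmentation routes: global Otsu thresholding after
blurring, or hand-traced front files (ImageJ-style `x y` text).

On the centred x-coordinates (right front mirrored so both advance in +x):

- ensemble mean `E(Y(k)) = (1/N) Σₙ yₙ(k)`,
- velocity `V(τ) = X(τ+1) − X(τ)` and acceleration `A(τ) = V(τ+1) − V(τ)`,
- ensemble ACF anchored at t₀ = 0:
  `ACF(τ) = E[(Y(0) − μ₀)(Y(τ) − μ_τ)] / (σ₀ σ_τ)`,
- mean squared displacement `MS(τ) = E[(Y(τ) − Y(0))²]`,
- drift fit `x(t) = v_d (t − τ₁)` by OLS inside a (detectable, overridable)
  drift window,
- velocity-increment magnitude distribution fitted against the
  half-Gaussian `2·G(|ΔV|; 0, σ²)` and exponential `exp(−|ΔV|/λ)/λ` laws
  with Poisson-weighted histogram OLS,
- Pearson agreement tables between two runs (e.g. texture vs hand-traced).

See `vignettes/pseudo-particle-tracking.Rmd` for assumptions, parameter
rationale and numerical choices.

## Worked example

A synthetic scratch assay (300×400 px, 40 frames at 0.25 h) whose fronts
are quiescent for 5 h and then advance at 2.5 px/frame = 10 px/h:

```r
library(woundtrack)
spec <- synthetic_wound_spec(height = 300, width = 400, n_frames = 40,
                             drift_vd = 2.5, lag_tau1 = 20,
                             waviness_amplitude = 8, waviness_wavelength = 75,
                             seed = 1)
run <- run_pipeline(list(synthetic_spec = spec, method = "texture",
                         fit_on = "first"))
print(run)
#> pipeline_run [texture]: 40 frames, 103 particles, sides L/R
#>   L: vd = 10.4 +/- 0.21 /h, tau1 = 5.23 +/- 0.051 h, adj R^2 = 0.992
#>   R: vd = 10.3 +/- 0.21 /h, tau1 = 5.17 +/- 0.055 h, adj R^2 = 0.991
#>   warnings: 1
```

The fitted drift velocity (10.4 ± 0.2 px/h per side, true 10) and
quiescence lag (5.2 ± 0.05 h, true 5) are recovered from the images alone;
the warning records that `pixel_size` was defaulted, so velocities are in
px/h rather than μm/h. The wound area shrinks once drift starts:

```r
tail(run$area[, c("frame", "time_h", "normalized_area")], 3)
#>    frame time_h normalized_area
#> 38    37   9.25       0.4881783
#> 39    38   9.50       0.4531393
#> 40    39   9.75       0.4161432
```

and the increment-magnitude distribution of the drift regime prefers the
exponential over the half-Gaussian law for this (fluctuation-rich) texture
route:

```r
run$fits$L$tails$exponential
#> fit_result [exponential]: lambda = 7.108 +/- 1.2; adj R^2 = 0.6310 (n = 23)
run$fits$L$tails$half_gaussian
#> fit_result [half_gaussian]: sigma = 9.665 +/- 1.5; adj R^2 = 0.4202 (n = 23)
```

## Command line

```sh
inst/exec/woundtrack generate --spec spec.yaml --out data/
inst/exec/woundtrack run --input data/ --method texture --config cfg.yaml --out results/
inst/exec/woundtrack compare resultsA/ resultsB/ --out table.csv
```

`generate` renders a synthetic sequence (PGM frames + ground-truth fronts +
spec); `run` executes the full pipeline and writes fronts, trajectory /
statistics / fit CSVs and a JSON run report; `compare` emits the
cross-method Pearson table. YAML config keys mirror `pipeline_config()`.

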