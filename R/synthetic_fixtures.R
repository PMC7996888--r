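#' Specification of a synthetic wound-healing sequence
#'
#' Describes a phase-contrast-like scratch-assay time lapse with known ground
#' truth: two textured cell layers separated by a smooth background gap whose
#' fronts are quiescent for `lag_tau1` frames and then advance towards each
#' other at `drift_vd` px/frame -- the piecewise-linear drift law
#' `x(t) = vd * (t - tau1)` for `t > tau1`. Defaults mirror the reference
#' acquisition geometry: 1200 x 1600 px frames at 4 frames/hour, 40 analyzed
#' frames, a quiescence lag of 5 h (20 frames), fronts starting at 30% and
#' 70% of the width. Front waviness and per-frame smooth perturbations give
#' the fronts realistic structure; the rendering emulates granular
#' phase-contrast cell texture, a bright halo along the edge and a smooth
#' low-variance gap.
#'
#' Validation fails (reporting the closure frame) if the chosen parameters
#' would make the fronts touch within `n_frames`.
#'
#' @param height,width frame size in px (defaults 1200, 1600).
#' @param n_frames number of frames (default 40).
#' @param drift_vd front drift in px/frame after the lag (default
#'   `width / 160`, i.e. 10 px/frame at the default width).
#' @param lag_tau1 quiescence lag in frames (default 20, i.e. 5 h).
#' @param gap_fraction initial gap width as a fraction of `width`
#'   (default 0.4, centred).
#' @param front_noise_sd per-frame smooth front perturbation sd in px
#'   (default 1).
#' @param waviness_amplitude,waviness_wavelength static sinusoidal front
#'   modulation in px (defaults `height / 37.5` and `height / 4`).
#' @param cell_contrast speckle contrast of the cell texture, intensity units
#'   (default 35).
#' @param grain_size speckle grain size in px (default 2).
#' @param bg_mean,bg_amp background mean intensity and smooth modulation
#'   amplitude (defaults 40 and 3).
#' @param halo_width,halo_intensity bright phase-contrast halo along the
#'   front: width in px and intensity (defaults 2 and 220).
#' @param noise_sd global additive Gaussian noise sd (default 0.4).
#' @param frame_interval hours per frame (default 0.25).
#' @param seed integer master seed; all generator randomness derives from it.
#' @return object of class `synthetic_wound_spec`.
#' @export
synthetic_wound_spec <- function(height = 1200L, width = 1600L,
                                 n_frames = 40L,
                                 drift_vd = width / 160,
                                 lag_tau1 = 20L,
                                 gap_fraction = 0.4,
                                 front_noise_sd = 1,
                                 waviness_amplitude = height / 37.5,
                                 waviness_wavelength = height / 4,
                                 cell_contrast = 35,
                                 grain_size = 2,
                                 bg_mean = 40, bg_amp = 3,
                                 halo_width = 2, halo_intensity = 220,
                                 noise_sd = 0.4,
                                 frame_interval = 0.25,
                                 seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               n_frames = as.integer(n_frames), drift_vd = drift_vd,
               lag_tau1 = as.integer(lag_tau1), gap_fraction = gap_fraction,
               front_noise_sd = front_noise_sd,
               waviness_amplitude = waviness_amplitude,
               waviness_wavelength = waviness_wavelength,
               cell_contrast = cell_contrast, grain_size = grain_size,
               bg_mean = bg_mean, bg_amp = bg_amp,
               halo_width = halo_width, halo_intensity = halo_intensity,
               noise_sd = noise_sd, frame_interval = frame_interval,
               seed = as.integer(seed))
  class(spec) <- "synthetic_wound_spec"
  # closure check: gap(k) = gap0 - 2 vd max(0, k - lag); must stay positive
  # with margin for waviness + noise
  gap0 <- spec$gap_fraction * spec$width
  margin <- 2 * (spec$waviness_amplitude + 3 * spec$front_noise_sd +
                 spec$halo_width)
  k <- spec$n_frames - 1L
  min_gap <- gap0 - 2 * spec$drift_vd * max(0, k - spec$lag_tau1) - margin
  if (min_gap <= 0) {
    closure <- spec$lag_tau1 + (gap0 - margin) / (2 * spec$drift_vd)
    stop(sprintf(
      "fronts would touch near frame %.0f (< n_frames = %d); reduce drift_vd or n_frames",
      closure, spec$n_frames), call. = FALSE)
  }
  spec
}

#' @export
print.synthetic_wound_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic_wound_spec: %dx%d px, %d frames, vd = %g px/frame after %d frames, seed %d\n",
    x$height, x$width, x$n_frames, x$drift_vd, x$lag_tau1, x$seed))
  invisible(x)
}

# smooth random curve over y: Gaussian control points every `step` px,
# linearly interpolated
smooth_noise_curve <- function(y, sd, step = 25) {
  if (sd <= 0) return(rep(0, length(y)))
  knots <- seq(min(y) - step, max(y) + step, by = step)
  vals <- stats::rnorm(length(knots), sd = sd)
  stats::approx(knots, vals, xout = y)$y
}

#' Generate ground-truth wound fronts for a synthetic sequence
#'
#' Deterministic given the spec seed. Front centrelines are vertical lines at
#' 30%/70% of the width (for the default `gap_fraction` 0.4), static for
#' `lag_tau1` frames and then advancing towards each other at `drift_vd`
#' px/frame, modulated by a static sinusoid plus a smooth per-frame Gaussian
#' perturbation. Fronts span the full vertical extent of the frame.
#'
#' @param spec a [synthetic_wound_spec()].
#' @return list of length `n_frames`; element `k` has [wound_front()]
#'   members `L` and `R` for frame `k - 1`.
#' @export
generate_ground_truth_fronts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_wound_spec"))
  set.seed(spec$seed)
  y <- seq(0, spec$height - 1L)
  x0_L <- spec$width * (0.5 - spec$gap_fraction / 2)
  x0_R <- spec$width * (0.5 + spec$gap_fraction / 2)
  phase_L <- stats::runif(1, 0, 2 * pi)
  phase_R <- stats::runif(1, 0, 2 * pi)
  wav <- function(phase)
    spec$waviness_amplitude * sin(2 * pi * y / spec$waviness_wavelength + phase)
  lapply(seq_len(spec$n_frames), function(kk) {
    k <- kk - 1L
    disp <- spec$drift_vd * max(0, k - spec$lag_tau1)
    xl <- x0_L + disp + wav(phase_L) +
      smooth_noise_curve(y, spec$front_noise_sd)
    xr <- x0_R - disp - wav(phase_R) +
      smooth_noise_curve(y, spec$front_noise_sd)
    list(L = wound_front(cbind(xl, y), "L", frame_index = k),
         R = wound_front(cbind(xr, y), "R", frame_index = k))
  })
}

# seeded speckle texture: white noise smoothed at the grain scale, unit sd
speckle_field <- function(H, W, grain) {
  z <- matrix(stats::rnorm(H * W), H, W)
  if (grain > 0) z <- gaussian_blur(z, grain)
  z / stats::sd(as.vector(z))
}

#' Render synthetic phase-contrast frames from ground-truth fronts
#'
#' Pixels left of the left front and right of the right front are filled with
#' bright granular speckle texture emulating a confluent cell layer, with a
#' thin bright halo hugging the front on the cell side as phase-contrast
#' optics produce; the gap is a smooth, low-variance dark background. Mild
#' global Gaussian noise is added and intensities are quantized to 8 bit.
#' Rendering randomness derives from `spec$seed` (offset substream), so the
#' whole dataset is reproducible from the spec alone.
#'
#' @param fronts result of [generate_ground_truth_fronts()].
#' @param spec the generating [synthetic_wound_spec()].
#' @return a [frame_stack()].
#' @export
render_frames <- function(fronts, spec) {
  stopifnot(inherits(spec, "synthetic_wound_spec"))
  H <- spec$height; W <- spec$width
  set.seed((spec$seed + 77003L) %% .Machine$integer.max)  # render substream
  xs <- matrix(seq_len(W) - 1L, H, W, byrow = TRUE)
  frames <- lapply(seq_along(fronts), function(kk) {
    fl <- fronts[[kk]]$L$points; fr <- fronts[[kk]]$R$points
    y <- seq(0, H - 1L)
    xl <- stats::approx(fl[, 2L], fl[, 1L], xout = y, rule = 2)$y
    xr <- stats::approx(fr[, 2L], fr[, 1L], xout = y, rule = 2)$y
    xlm <- matrix(xl, H, W); xrm <- matrix(xr, H, W)
    cell <- xs <= xlm | xs >= xrm
    halo <- (xs > xlm - spec$halo_width & xs <= xlm) |
            (xs < xrm + spec$halo_width & xs >= xrm)
    tex <- 128 + spec$cell_contrast * speckle_field(H, W, spec$grain_size)
    bg <- spec$bg_mean +
      spec$bg_amp * sin(2 * pi * matrix(y, H, W) / (H / 2)) *
      sin(2 * pi * xs / (W / 2))
    img <- ifelse(cell, tex, bg)
    img[halo] <- spec$halo_intensity
    img <- img + stats::rnorm(H * W, sd = spec$noise_sd)
    matrix(as.integer(pmax(pmin(round(img), 255), 0)), H, W)
  })
  frame_stack(frames, frame_interval = spec$frame_interval)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: ground-truth fronts plus rendered frames, with the
#' spec attached.
#'
#' @param spec a [synthetic_wound_spec()].
#' @return list with `spec`, `fronts` (ground truth) and `stack`.
#' @export
generate_synthetic_wound <- function(spec) {
  fronts <- generate_ground_truth_fronts(spec)
  list(spec = spec, fronts = fronts, stack = render_frames(fronts, spec))
}
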