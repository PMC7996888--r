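#' Sample points at uniform arc length along a front
#'
#' The front polyline is parameterized by cumulative chord length
#' `s in [0, L]`; x(s) and y(s) are linearly interpolated and evaluated at the
#' `n` uniformly spaced targets `s_i = i * L / (n - 1)`, `i = 0..n-1`
#' (endpoints included). These are the pseudo-particles: points "threaded"
#' on the wound-edge membrane at equal spacing, like pearls on a necklace.
#'
#' @param front a [wound_front()] (or an n x 2 (x, y) matrix).
#' @param n number of points, >= 2 (default 103).
#' @return n x 2 matrix of (x, y) coordinates.
#' @export
sample_uniform_points <- function(front, n = 103L) {
  pts <- if (inherits(front, "wound_front")) front$points else as.matrix(front)
  if (n < 2L) stop("need n >= 2 sample points", call. = FALSE)
  if (nrow(pts) < 2L) stop("front needs at least 2 points", call. = FALSE)
  seg <- sqrt(diff(pts[, 1L])^2 + diff(pts[, 2L])^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) stop("degenerate front: total arc length is 0", call. = FALSE)
  target <- seq(0, L, length.out = n)
  x <- stats::approx(s, pts[, 1L], xout = target, ties = "ordered")$y
  y <- stats::approx(s, pts[, 2L], xout = target, ties = "ordered")$y
  cbind(x = x, y = y)
}

#' Trajectory matrices of pseudo-particles across frames
#'
#' Samples `n` uniform arc-length points on each per-frame front and stacks
#' them column-wise: entry `[i, k]` is the position of pseudo-particle `i` in
#' frame `k`. Particle identity is the arc-length rank (particle `i` is always
#' the i-th point from the top endpoint); trajectories may cross, reflecting
#' invaginations and protrusions of the membrane.
#'
#' @param fronts list of [wound_front()] objects for consecutive frames,
#'   all of the same side.
#' @param n number of pseudo-particles (default 103).
#' @param frame_interval hours per frame (default 0.25).
#' @param pixel_size micrometres per pixel (default 1 = px units).
#' @return object of class `trajectory_matrix`: `x` and `y` (`n` x `M`
#'   matrices, px), `side`, `n_particles`, `n_frames`, `frame_interval`,
#'   `pixel_size`, `mirrored`, `centered`.
#' @export
build_trajectories <- function(fronts, n = 103L, frame_interval = 0.25,
                               pixel_size = 1.0) {
  if (!length(fronts)) stop("no fronts supplied", call. = FALSE)
  if (!all(vapply(fronts, inherits, logical(1), "wound_front")))
    stop("`fronts` must be a list of wound_front objects", call. = FALSE)
  sides <- vapply(fronts, `[[`, character(1), "side")
  if (length(unique(sides)) != 1L)
    stop("all fronts must be the same side (got ",
         paste(unique(sides), collapse = ", "), ")", call. = FALSE)
  idx <- vapply(fronts, `[[`, integer(1), "frame_index")
  expected <- seq(min(idx), max(idx))
  if (!setequal(idx, expected) || length(idx) != length(expected))
    stop("missing frames in range: ",
         paste(setdiff(expected, idx), collapse = ", "), call. = FALSE)
  fronts <- fronts[order(idx)]
  M <- length(fronts)
  xs <- matrix(NA_real_, n, M)
  ys <- matrix(NA_real_, n, M)
  for (k in seq_len(M)) {
    p <- sample_uniform_points(fronts[[k]], n)
    xs[, k] <- p[, 1L]; ys[, k] <- p[, 2L]
  }
  structure(list(x = xs, y = ys, side = sides[1L], n_particles = n,
                 n_frames = M, frame_interval = frame_interval,
                 pixel_size = pixel_size, mirrored = FALSE, centered = FALSE),
            class = "trajectory_matrix")
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat(sprintf(
    "trajectory_matrix %s: N = %d particles x M = %d frames (dt = %g h)%s%s\n",
    x$side, x$n_particles, x$n_frames, x$frame_interval,
    if (x$mirrored) ", mirrored" else "",
    if (x$centered) ", centered" else ""))
  invisible(x)
}

#' Time axis of a trajectory matrix
#'
#' @param traj a [build_trajectories()] result.
#' @return numeric vector of frame times in hours (frame 0 at t = 0).
#' @export
trajectory_times <- function(traj) {
  (seq_len(traj$n_frames) - 1L) * traj$frame_interval
}

#' Wound area between the two fronts over time
#'
#' Per frame, integrates `max(0, x_R(y) - x_L(y))` over the y-range common to
#' both fronts by the trapezoid rule on a fine y grid (step 0.25 px); negative
#' gaps from crossing fronts contribute zero. Optionally normalized by the
#' frame-0 area, giving the classic normalized wound-closure curve.
#'
#' @param fronts_L,fronts_R per-frame lists of [wound_front()] objects (same
#'   length, frame-aligned).
#' @param normalize divide by the frame-0 area (default TRUE).
#' @param frame_interval hours per frame for the time column (default 0.25).
#' @return data.frame with columns `frame`, `time_h`, `area`,
#'   and `normalized_area` when `normalize` is TRUE.
#' @export
wound_area_series <- function(fronts_L, fronts_R, normalize = TRUE,
                              frame_interval = 0.25) {
  stopifnot(length(fronts_L) == length(fronts_R))
  area1 <- function(fl, fr) {
    yl <- fl$points[, 2L]; yr <- fr$points[, 2L]
    lo <- max(min(yl), min(yr)); hi <- min(max(yl), max(yr))
    if (hi <= lo) return(0)
    yg <- seq(lo, hi, by = 0.25)
    xl <- stats::approx(yl, fl$points[, 1L], xout = yg, ties = "ordered")$y
    xr <- stats::approx(yr, fr$points[, 1L], xout = yg, ties = "ordered")$y
    g <- pmax(xr - xl, 0)
    sum((g[-1L] + g[-length(g)]) / 2 * diff(yg))
  }
  a <- mapply(area1, fronts_L, fronts_R)
  out <- data.frame(frame = seq_along(a) - 1L,
                    time_h = (seq_along(a) - 1L) * frame_interval,
                    area = a)
  if (normalize) {
    if (a[1L] <= 0)
      stop("cannot normalize: frame-0 wound area is zero", call. = FALSE)
    out$normalized_area <- a / a[1L]
  }
  out
}
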