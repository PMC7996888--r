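#' Centre trajectories at the initial ensemble position
#'
#' Subtracts one scalar -- the frame-0 ensemble mean of x -- from every x
#' entry, so that `<X(t=0)> = 0`; y is untouched. All downstream position
#' statistics assume this centering.
#'
#' @param traj a [build_trajectories()] result.
#' @return the centred `trajectory_matrix` (`centered = TRUE`).
#' @export
center_initial_position <- function(traj) {
  stopifnot(inherits(traj, "trajectory_matrix"))
  traj$x <- traj$x - mean(traj$x[, 1L])
  traj$centered <- TRUE
  traj
}

#' Mirror a right-front trajectory matrix
#'
#' Reflects x about the frame width (`x <- frame_width - x`) so that the
#' right front, which physically advances in -x, advances in +x like the left
#' front and the two sides are directly comparable. Applying it twice is the
#' identity.
#'
#' @param traj a right-side (`side == "R"`) `trajectory_matrix`.
#' @param frame_width frame width in px.
#' @return the mirrored `trajectory_matrix` (mirrored flag toggled).
#' @export
mirror_right_front <- function(traj, frame_width) {
  stopifnot(inherits(traj, "trajectory_matrix"))
  if (traj$side != "R")
    stop("mirroring is defined for the right front only (side = 'R')",
         call. = FALSE)
  traj$x <- frame_width - traj$x
  traj$mirrored <- !traj$mirrored
  traj
}

as_values_matrix <- function(values) {
  if (inherits(values, "trajectory_matrix")) values <- values$x
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  stopifnot(is.matrix(values), is.numeric(values))
  values
}

#' Ensemble mean series
#'
#' Column means of an N (particles) x K (times) matrix:
#' `E(Y(k)) = (1/N) sum_n y_n(k)`.
#'
#' @param values N x K numeric matrix (or a `trajectory_matrix`, whose x is
#'   used).
#' @return numeric vector of length K.
#' @export
ensemble_mean <- function(values) {
  v <- as_values_matrix(values)
  if (nrow(v) < 1L || ncol(v) < 1L) stop("empty matrix", call. = FALSE)
  colMeans(v)
}

#' Per-particle velocity (first position differences)
#'
#' `V(tau) = X(tau + 1) - X(tau)`, in px per frame (one frame = the sampling
#' interval, 0.25 h by default). Multiply by `pixel_size / frame_interval`
#' for um/h.
#'
#' @param traj_x N x M position matrix (or a `trajectory_matrix`).
#' @return N x (M - 1) matrix of increments.
#' @export
velocity <- function(traj_x) {
  v <- as_values_matrix(traj_x)
  if (ncol(v) < 2L) stop("need at least 2 frames for velocity", call. = FALSE)
  v[, -1L, drop = FALSE] - v[, -ncol(v), drop = FALSE]
}

#' Per-particle acceleration (velocity increments)
#'
#' `A(tau) = V(tau + 1) - V(tau)`; equals the second differences of position.
#'
#' @param vel N x (M - 1) velocity matrix (or an N x M position
#'   `trajectory_matrix`, differentiated twice).
#' @return N x (M - 2) matrix.
#' @export
acceleration <- function(vel) {
  if (inherits(vel, "trajectory_matrix")) vel <- velocity(vel)
  v <- as_values_matrix(vel)
  if (ncol(v) < 2L)
    stop("need at least 3 frames (2 velocity columns) for acceleration",
         call. = FALSE)
  v[, -1L, drop = FALSE] - v[, -ncol(v), drop = FALSE]
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Ensemble autocorrelation anchored at the initial time
#'
#' Non-stationary ensemble ACF: for each lag `tau`,
#' `ACF(tau) = E[(Y(0) - mu_0)(Y(tau) - mu_tau)] / (sigma_0 sigma_tau)`,
#' where the mean and standard deviation (population convention) are taken
#' across particles at the fixed times 0 and `tau`. This is the ensemble
#' quantity appropriate when long stationary trajectories are unavailable; it
#' is not a time-averaged ACF. `ACF(0) = 1`; lags with zero ensemble spread
#' yield `NaN` with a warning.
#'
#' @param values N x K matrix (or `trajectory_matrix`).
#' @return numeric vector of length K (lags 0..K-1).
#' @export
ensemble_acf <- function(values) {
  v <- as_values_matrix(values)
  if (nrow(v) < 2L) stop("need at least 2 particles for the ensemble ACF",
                         call. = FALSE)
  mu <- colMeans(v)
  sd <- apply(v, 2L, pop_sd)
  y0 <- v[, 1L] - mu[1L]
  out <- vapply(seq_len(ncol(v)), function(k) {
    denom <- sd[1L] * sd[k]
    if (denom == 0) return(NaN)
    mean(y0 * (v[, k] - mu[k])) / denom
  }, numeric(1))
  if (anyNA(out))
    warning("ensemble ACF undefined (zero spread) at lag(s) ",
            paste(which(is.nan(out)) - 1L, collapse = ", "), call. = FALSE)
  out
}

#' Ensemble mean squared displacement from the initial time
#'
#' `MSY(tau) = E[(Y(tau) - Y(0))^2]`, the ensemble mean across particles of
#' the squared displacement from time 0; `MSY(0) = 0`.
#'
#' @param values N x K matrix (or `trajectory_matrix`).
#' @return numeric vector of length K (lags 0..K-1).
#' @export
mean_squared_displacement <- function(values) {
  v <- as_values_matrix(values)
  colMeans((v - v[, 1L])^2)
}

#' Ensemble standard deviation series
#'
#' Per-column standard deviation across particles, population convention
#' (divisor N), e.g. the spread of the pseudo-particle acceleration at each
#' time.
#'
#' @param values N x K matrix (or `trajectory_matrix`).
#' @param sample use the sample convention (divisor N - 1) instead.
#' @return numeric vector of length K.
#' @export
ensemble_std_series <- function(values, sample = FALSE) {
  v <- as_values_matrix(values)
  if (nrow(v) < 2L) stop("need at least 2 particles", call. = FALSE)
  if (sample) return(apply(v, 2L, stats::sd))
  apply(v, 2L, pop_sd)
}
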