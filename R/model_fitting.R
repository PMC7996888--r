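#' Adjusted R-squared
#'
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)` with `R^2` the fraction of variance
#' of `observed` explained by `fitted` and `p = n_params` the number of fitted
#' parameters.
#'
#' @param observed,fitted numeric vectors of equal length `n >= n_params + 2`.
#' @param n_params number of fitted model parameters.
#' @return adjusted R-squared (<= 1).
#' @export
adjusted_r_squared <- function(observed, fitted, n_params) {
  stopifnot(length(observed) == length(fitted))
  n <- length(observed); p <- n_params
  if (n <= p + 1L)
    stop("need n > n_params + 1 points for adjusted R-squared", call. = FALSE)
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- 1 - ss_res / ss_tot
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

new_fit_result <- function(model, params, std_errors, adj_r_squared, window,
                           n_points) {
  structure(list(model = model, params = params, std_errors = std_errors,
                 adj_r_squared = adj_r_squared, window = window,
                 n_points = n_points),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  est <- paste(sprintf("%s = %.4g +/- %.2g", names(x$params), x$params,
                       x$std_errors), collapse = ", ")
  cat(sprintf("fit_result [%s]: %s; adj R^2 = %.4f (n = %d)\n",
              x$model, est, x$adj_r_squared, x$n_points))
  invisible(x)
}

#' Fit the constant-drift model to the mean front position
#'
#' OLS fit of `x(t) = vd * (t - tau1)` over the samples with
#' `t_low < t < t_high` (the intermediate, constant-drift regime of wound
#' closure). Equivalently a straight line with slope `vd` and intercept
#' `-vd * tau1`; `tau1` -- the quiescence lag before the front starts moving
#' -- is recovered as minus intercept over slope, with its standard error
#' propagated from the (intercept, slope) covariance by the delta method.
#' Assumes `mean_x` was centred so that `<X(0)> = 0`.
#'
#' @param mean_x ensemble mean position series.
#' @param time_h matching time axis in hours.
#' @param window numeric `c(t_low, t_high)` in hours; the fit uses strict
#'   inequalities.
#' @return a `fit_result` with params `vd` (units of `mean_x` per hour) and
#'   `tau1` (hours).
#' @export
fit_drift <- function(mean_x, time_h, window) {
  stopifnot(length(mean_x) == length(time_h), length(window) == 2L)
  if (!(window[1L] < window[2L]))
    stop("window must satisfy t_low < t_high", call. = FALSE)
  sel <- time_h > window[1L] & time_h < window[2L]
  if (sum(sel) < 3L)
    stop("need at least 3 samples inside the fit window (got ", sum(sel), ")",
         call. = FALSE)
  t <- time_h[sel]; x <- mean_x[sel]
  if (stats::var(t) == 0) stop("zero time variance in window", call. = FALSE)
  fit <- stats::lm(x ~ t)
  b <- stats::coef(fit)                  # (intercept, slope)
  V <- suppressWarnings(stats::vcov(fit))  # "perfect fit" warning is benign
  vd <- unname(b[2L]); b0 <- unname(b[1L])
  tau1 <- -b0 / vd
  # delta method: tau1 = -b0/b1, J = (-1/b1, b0/b1^2)
  J <- c(-1 / vd, b0 / vd^2)
  se_tau1 <- sqrt(drop(t(J) %*% V %*% J))
  adj <- adjusted_r_squared(x, stats::fitted(fit), n_params = 2L)
  new_fit_result("drift_linear",
                 params = c(vd = vd, tau1 = tau1),
                 std_errors = c(vd = sqrt(V[2L, 2L]), tau1 = se_tau1),
                 adj_r_squared = adj,
                 window = unname(window), n_points = sum(sel))
}

#' Detect the constant-drift time window from the mean position
#'
#' Heuristic defaults for the fit window of [fit_drift()], meant to be
#' overridable by eye.
#'
#' Lower bound (drift onset): wound closure follows quiescence-then-drift, so
#' the centred mean position is fitted by a piecewise model -- constant up to
#' a breakpoint, straight line after it -- and the breakpoint minimizing the
#' total squared error over all candidates is taken as `t_low`. This is far
#' more robust than thresholding the per-frame velocity, which at tile
#' resolution is spiky (whole tile columns flip at once).
#'
#' Upper bound (drift end): the first time after onset at which the mean
#' velocity, smoothed with a running median of width `smooth` to suppress
#' isolated segmentation glitches, returns to <= 0 for `sustain` consecutive
#' frames (stalling/closure); otherwise the end of the series.
#'
#' @param mean_x centred ensemble mean position series (length M).
#' @param time_h matching time axis in hours (length M).
#' @param sustain number of consecutive frames required for the upper bound
#'   (default 3).
#' @param smooth running-median width in frames, odd (default 5; 1 = no
#'   smoothing).
#' @return numeric `c(t_low, t_high)` in hours.
#' @export
detect_drift_window <- function(mean_x, time_h, sustain = 3L, smooth = 5L) {
  stopifnot(length(mean_x) == length(time_h))
  n <- length(mean_x)
  if (n < 8L) stop("need at least 8 samples to detect the drift window",
                   call. = FALSE)
  line_sse <- function(t, x) {
    b <- sum((t - mean(t)) * (x - mean(x))) / sum((t - mean(t))^2)
    sum((x - mean(x) - b * (t - mean(t)))^2)
  }
  cand <- 2L:(n - 4L)                   # leave >= 5 points for the line
  sse <- vapply(cand, function(j) {
    sum((mean_x[1:j] - mean(mean_x[1:j]))^2) +
      line_sse(time_h[j:n], mean_x[j:n])
  }, numeric(1))
  on <- cand[which.min(sse)]
  t_low <- time_h[on] - 1e-9
  # upper bound from the (smoothed) velocity returning to <= 0
  v <- diff(mean_x)
  if (smooth > 1L && length(v) > smooth)
    v <- as.numeric(stats::runmed(v, smooth, endrule = "median"))
  nv <- length(v)
  hit <- which(vapply(seq_len(nv - sustain + 1L), function(i)
    i > on && all(v[i:(i + sustain - 1L)] <= 0), logical(1)))
  t_high <- if (length(hit)) time_h[hit[1L]] else time_h[n] + 1e-9
  if (sum(time_h > t_low & time_h < t_high) < 5L) t_high <- time_h[n] + 1e-9
  c(t_low, t_high)
}

#' Fit half-Gaussian and exponential laws to velocity-increment magnitudes
#'
#' Histograms `|dV|` with density normalization and fits, by weighted OLS on
#' the non-empty bins, the two candidate tail laws for the increment
#' distribution:
#' half-Gaussian `P(|dV|) = 2 G(|dV|; 0, sigma^2)` and exponential
#' `P(|dV|) = (1/lambda) exp(-|dV|/lambda)`. Bin weights follow Poisson
#' counting uncertainty (variance proportional to the bin count). The fit
#' with the larger adjusted R-squared indicates the better-supported law.
#' `method = "mle"` instead returns the closed-form maximum-likelihood
#' estimates (`lambda = mean`, `sigma = sqrt(mean of squares)`) with their
#' asymptotic standard errors, as a cross-check on the histogram route.
#'
#' @param abs_dv non-negative sample of increment magnitudes (>= 50 values).
#' @param n_bins number of histogram bins; default Freedman-Diaconis.
#' @param method `"ols"` (histogram fit, primary) or `"mle"`.
#' @return list with `fit_result` elements `half_gaussian` and `exponential`.
#' @export
fit_increment_tails <- function(abs_dv, n_bins = NULL,
                                method = c("ols", "mle")) {
  method <- match.arg(method)
  v <- as.vector(abs_dv)
  if (length(v) < 50L) stop("need at least 50 samples", call. = FALSE)
  if (any(v < 0)) stop("increment magnitudes must be >= 0", call. = FALSE)
  if (min(v) == max(v))
    stop("degenerate histogram: all samples identical", call. = FALSE)
  if (method == "mle") {
    n <- length(v)
    lam <- mean(v); sig <- sqrt(mean(v^2))
    return(list(
      half_gaussian = new_fit_result("half_gaussian",
        c(sigma = sig), c(sigma = sig / sqrt(2 * n)), NA_real_,
        range(v), n),
      exponential = new_fit_result("exponential",
        c(lambda = lam), c(lambda = lam / sqrt(n)), NA_real_,
        range(v), n)))
  }
  breaks <- if (is.null(n_bins)) {
    bw <- 2 * stats::IQR(v) / length(v)^(1 / 3)   # Freedman-Diaconis
    if (bw <= 0) bw <- diff(range(v)) / 30
    seq(min(v), max(v) + bw, by = bw)
  } else seq(min(v), max(v), length.out = n_bins + 1L)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  keep <- h$counts > 0L
  x <- h$mids[keep]; dens <- h$density[keep]; cnt <- h$counts[keep]
  if (sum(keep) < 4L) stop("too few occupied histogram bins", call. = FALSE)
  bw <- diff(h$breaks[1:2]); n_total <- length(v)
  w <- 1 / cnt                                    # var(density) ~ count
  fit_one <- function(formula, start, name, par_name) {
    df <- data.frame(x = x, dens = dens, wts = w)
    fit <- stats::nls(formula, data = df, start = start, weights = wts,
                      algorithm = "port", lower = 1e-12)
    # one reweighting pass with expected counts: weighting by observed
    # counts biases the scale estimates low (downward-fluctuating tail bins
    # get the largest weights); expected counts are the consistent Poisson
    # variance estimate
    df$wts <- 1 / pmax(stats::predict(fit) * n_total * bw, 0.5)
    fit <- stats::nls(formula, data = df,
                      start = as.list(stats::coef(fit)), weights = wts,
                      algorithm = "port", lower = 1e-12)
    co <- summary(fit)$coefficients
    fitted_d <- stats::predict(fit)
    params <- stats::setNames(co[1L, 1L], par_name)
    se <- stats::setNames(co[1L, 2L], par_name)
    new_fit_result(name, params, se,
                   adjusted_r_squared(dens, fitted_d, 1L),
                   range(v), length(x))
  }
  hg <- fit_one(dens ~ sqrt(2 / pi) / sigma * exp(-x^2 / (2 * sigma^2)),
                list(sigma = sqrt(mean(v^2))), "half_gaussian", "sigma")
  ex <- fit_one(dens ~ exp(-x / lambda) / lambda,
                list(lambda = mean(v)), "exponential", "lambda")
  list(half_gaussian = hg, exponential = ex)
}

#' Pearson agreement between two estimates of the same quantity
#'
#' Pools the paired values of two same-shaped objects (e.g. the full N x M
#' coordinate collections, or an ensemble mean series, estimated by two
#' segmentation methods) and reports the Pearson correlation with its
#' two-sided p-value.
#'
#' @param a,b numeric vectors/matrices of identical shape (>= 3 values), or
#'   `trajectory_matrix` objects (x coordinates are compared).
#' @param variable label recorded in the result (e.g. `"x_coords"`).
#' @return object of class `comparison_result`: `variable`, `pearson_r`,
#'   `p_value`, `n`.
#' @export
compare_methods <- function(a, b, variable = "x_coords") {
  if (inherits(a, "trajectory_matrix")) a <- a$x
  if (inherits(b, "trajectory_matrix")) b <- b$x
  av <- as.vector(as.matrix(a)); bv <- as.vector(as.matrix(b))
  if (length(av) != length(bv))
    stop("inputs must have identical shapes", call. = FALSE)
  if (length(av) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (stats::var(av) == 0 || stats::var(bv) == 0)
    stop("undefined correlation: zero variance input", call. = FALSE)
  ct <- stats::cor.test(av, bv, method = "pearson")
  structure(list(variable = variable, pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, n = length(av)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("compare[%s]: r = %.3f, p = %.3g (n = %d)\n",
              x$variable, x$pearson_r, x$p_value, x$n))
  invisible(x)
}
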