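# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own code paths.

# plain histogram equalization of one tile by an explicit CDF transform
oracle_hist_equalize <- function(frame, maxval = 255L) {
  n <- length(frame)
  out <- frame
  for (i in seq_along(frame)) {
    v <- frame[i]
    cdf_v <- sum(frame <= v) / n
    out[i] <- round(cdf_v * maxval)
  }
  out
}

# naive per-pixel LBP counting loop (interior pixels of a padded copy)
oracle_lbp <- function(frame) {
  H <- nrow(frame); W <- ncol(frame)
  p <- frame[c(1, 1:H, H), c(1, 1:W, W)]
  out <- matrix(0L, H, W)
  for (r in 1:H) for (c in 1:W) {
    ctr <- p[r + 1, c + 1]
    s <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (ctr >= p[r + 1 + dr, c + 1 + dc]) s <- s + 1L
    }
    out[r, c] <- s
  }
  out
}

# naive LBP histogram by counting loop
oracle_lbp_hist <- function(tile) {
  counts <- numeric(9)
  for (v in as.vector(tile)) counts[v + 1] <- counts[v + 1] + 1
  counts / length(tile)
}

# dense-resampling oracle for uniform arc-length sampling: resample the
# polyline at `dense` points, pick the ones nearest the target arc lengths
oracle_uniform_points <- function(pts, n, dense = 1e5) {
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  sd <- seq(0, L, length.out = dense)
  xd <- approx(s, pts[, 1], xout = sd)$y
  yd <- approx(s, pts[, 2], xout = sd)$y
  target <- seq(0, L, length.out = n)
  idx <- vapply(target, function(t) which.min(abs(sd - t)), integer(1))
  cbind(xd[idx], yd[idx])
}

# exhaustive Otsu: scan every candidate threshold, maximize between-class
# variance computed from first principles
oracle_otsu <- function(values) {
  v <- round(as.vector(values))
  cands <- sort(unique(v))
  cands <- cands[-length(cands)]
  best <- -Inf; best_t <- NA
  for (t in cands) {
    g0 <- v[v <= t]; g1 <- v[v > t]
    w0 <- length(g0) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (bcv > best + 1e-12) { best <- bcv; best_t <- t }
  }
  best_t
}

# naive ensemble covariance/ACF between column 1 and column k
oracle_acf <- function(m) {
  K <- ncol(m); N <- nrow(m)
  mu <- colSums(m) / N
  sd <- sqrt(colSums(sweep(m, 2, mu)^2) / N)
  vapply(1:K, function(k) {
    s <- 0
    for (i in 1:N) s <- s + (m[i, 1] - mu[1]) * (m[i, k] - mu[k])
    (s / N) / (sd[1] * sd[k])
  }, numeric(1))
}

# two-pass population standard deviation per column
oracle_col_sd <- function(m) {
  vapply(seq_len(ncol(m)), function(k) {
    mu <- sum(m[, k]) / nrow(m)
    sqrt(sum((m[, k] - mu)^2) / nrow(m))
  }, numeric(1))
}

# small synthetic two-texture frame: left half granular speckle, right half
# smooth quantized gradient; returns frame plus the true tile labels
two_texture_frame <- function(H = 120, W = 160, seed = 42) {
  set.seed(seed)
  left <- matrix(sample(0:255, H * (W / 2), replace = TRUE), H, W / 2)
  right <- matrix(rep(round(seq(40, 44, length.out = W / 2)), each = H),
                  H, W / 2)
  cbind(left, right)
}

# default small-scale synthetic world used across tests (40 frames of
# 300 x 400 px; truth vd = 2.5 px/frame = 10 px/h, tau1 = 20 frames = 5 h)
small_spec <- function(seed = 1, ...) {
  synthetic_wound_spec(height = 300, width = 400, n_frames = 40,
                       drift_vd = 2.5, lag_tau1 = 20,
                       waviness_amplitude = 8, waviness_wavelength = 75,
                       seed = seed, ...)
}
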