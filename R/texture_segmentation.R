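#' Local binary pattern score image
#'
#' Computes, for every pixel, the count over its 8-neighbourhood of
#' comparisons in which the centre intensity is greater than or equal to the
#' neighbour intensity. Scores therefore range from 0 (strict local minimum)
#' to 8 (centre >= all neighbours, including the all-ties case of a constant
#' patch). This count variant -- not the classical weighted 0..255 LBP code --
#' is the texture primitive used throughout the package: its distribution over
#' a small tile separates the granular cell-layer texture from the smooth
#' wound background. Border pixels are scored against a replicate-padded
#' frame so the output has the same dimensions as the input.
#'
#' The score depends only on `>=` comparisons, so it is invariant under any
#' strictly increasing intensity transform.
#'
#' @param frame numeric matrix, at least 3x3.
#' @return integer matrix of the same dimensions with values in 0..8.
#' @export
lbp_image <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("`frame` must be a numeric matrix", call. = FALSE)
  H <- nrow(frame); W <- ncol(frame)
  if (H < 3L || W < 3L)
    stop(sprintf("frame must be at least 3x3 (got %dx%d)", H, W),
         call. = FALSE)
  p <- frame[c(1L, seq_len(H), H), c(1L, seq_len(W), W)]  # replicate pad
  ctr <- p[2:(H + 1L), 2:(W + 1L)]
  out <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- p[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc]
    out <- out + (ctr >= nb)
  }
  storage.mode(out) <- "integer"
  out
}

#' Tile grid for frame tessellation
#'
#' Divides a frame into a row-major grid of non-overlapping `tile_height` x
#' `tile_width` pixel tiles. When the frame dimensions are not multiples of
#' the tile size the remainder strip is dropped (floor grid) and the covered
#' extent is recorded. The reference geometry -- a 1200x1600 frame with 12x16
#' tiles -- tessellates exactly into 10,000 tiles.
#'
#' @param frame matrix, or `dim` attribute-like integer vector `c(H, W)`.
#' @param tile_height,tile_width tile size in pixels (defaults 12 and 16).
#' @return object of class `tile_grid`: `tile_height`, `tile_width`,
#'   `n_rows`, `n_cols`, `n_tiles`, `covered_height`, `covered_width`.
#' @export
tessellate <- function(frame, tile_height = 12L, tile_width = 16L) {
  d <- if (is.matrix(frame)) dim(frame) else as.integer(frame)
  H <- d[1L]; W <- d[2L]
  th <- as.integer(tile_height); tw <- as.integer(tile_width)
  if (th <= 0L || tw <= 0L) stop("tile size must be positive", call. = FALSE)
  if (th > H || tw > W)
    stop(sprintf("tile %dx%d larger than frame %dx%d", th, tw, H, W),
         call. = FALSE)
  n_rows <- H %/% th; n_cols <- W %/% tw
  structure(list(tile_height = th, tile_width = tw,
                 n_rows = n_rows, n_cols = n_cols, n_tiles = n_rows * n_cols,
                 covered_height = n_rows * th, covered_width = n_cols * tw),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile_grid: %d x %d tiles of %d x %d px (%d tiles)\n",
              x$n_rows, x$n_cols, x$tile_height, x$tile_width, x$n_tiles))
  invisible(x)
}

#' LBP score histogram of one tile
#'
#' @param lbp_tile matrix (or vector) of LBP scores in 0..8.
#' @return numeric vector of length 9; entry `b + 1` is the fraction of pixels
#'   with score `b`. Sums to 1.
#' @export
lbp_histogram <- function(lbp_tile) {
  v <- as.vector(lbp_tile)
  if (length(v) == 0L) stop("empty tile", call. = FALSE)
  if (anyNA(v) || any(v < 0L | v > 8L | v != round(v)))
    stop("LBP scores must be integers in 0..8", call. = FALSE)
  tabulate(v + 1L, nbins = 9L) / length(v)
}

#' Per-tile LBP texture feature matrix
#'
#' Row `i` is the 9-bin LBP score histogram of tile `i` in row-major tile
#' order; for the reference 1200x1600 geometry this is the 10,000 x 9 texture
#' matrix characterizing one frame.
#'
#' @param lbp LBP score image from [lbp_image()].
#' @param grid [tessellate()] grid consistent with `lbp`'s dimensions.
#' @return `n_tiles` x 9 matrix; every row is a probability vector.
#' @export
extract_features <- function(lbp, grid) {
  stopifnot(inherits(grid, "tile_grid"))
  if (nrow(lbp) < grid$covered_height || ncol(lbp) < grid$covered_width)
    stop("grid does not fit the LBP image dimensions", call. = FALSE)
  sub <- lbp[seq_len(grid$covered_height), seq_len(grid$covered_width)]
  tr <- (seq_len(grid$covered_height) - 1L) %/% grid$tile_height
  tc <- (seq_len(grid$covered_width) - 1L) %/% grid$tile_width
  tile_id <- outer(tr, tc, function(r, c) r * grid$n_cols + c) + 1L # row-major
  counts <- tabulate((as.vector(tile_id) - 1L) * 9L + as.vector(sub) + 1L,
                     nbins = grid$n_tiles * 9L)
  m <- matrix(counts, ncol = 9L, byrow = TRUE)
  m / (grid$tile_height * grid$tile_width)
}

# ---- two-component full-covariance Gaussian mixture (EM) -------------------

mvn_logdens <- function(X, mean, cov) {
  p <- ncol(X)
  ch <- chol(cov)
  z <- forwardsolve(t(ch), t(X) - mean)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

# EM for a k-component Gaussian mixture with full covariances; k-means init
# under the given seed, ridge 1e-6 on covariance diagonals.
fit_gmm <- function(X, k = 2L, seed = 0L, max_iter = 200L, tol = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (nrow(unique(X)) < k)
    stop("degenerate features: fewer than ", k, " distinct points",
         call. = FALSE)
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(X, centers = k, nstart = 5L,
                                       iter.max = 50L))
  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), km$cluster)] <- 1
  loglik_old <- -Inf
  weights <- numeric(k); means <- vector("list", k); covs <- vector("list", k)
  for (iter in seq_len(max_iter)) {
    nk <- colSums(resp) + 1e-10
    weights <- nk / n
    for (j in seq_len(k)) {
      mu <- colSums(resp[, j] * X) / nk[j]
      Xc <- sweep(X, 2L, mu)
      S <- crossprod(Xc * resp[, j], Xc) / nk[j] + diag(1e-6, p)
      means[[j]] <- mu; covs[[j]] <- S
    }
    ld <- vapply(seq_len(k),
                 function(j) mvn_logdens(X, means[[j]], covs[[j]]) +
                   log(weights[j]),
                 numeric(n))
    m <- apply(ld, 1L, max)
    lse <- m + log(rowSums(exp(ld - m)))
    resp <- exp(ld - lse)
    loglik <- sum(lse)
    if (is.finite(loglik_old) && abs(loglik - loglik_old) < tol * abs(loglik))
      break
    loglik_old <- loglik
  }
  list(weights = weights, means = means, covs = covs, resp = resp,
       loglik = loglik, n_iter = iter)
}

gmm_posterior <- function(gmm, X) {
  k <- length(gmm$weights)
  ld <- vapply(seq_len(k),
               function(j) mvn_logdens(X, gmm$means[[j]], gmm$covs[[j]]) +
                 log(gmm$weights[j]),
               numeric(nrow(X)))
  m <- apply(ld, 1L, max)
  exp(ld - (m + log(rowSums(exp(ld - m)))))
}

#' Fit the tile texture classifier (PCA + Gaussian mixture)
#'
#' Principal component analysis is fitted on the 9-dimensional LBP-histogram
#' features; a 2-component full-covariance Gaussian mixture is then fitted on
#' the first `n_pca` principal scores and its components are mapped to
#' cell-layer (1/`TRUE`) versus background (0/`FALSE`) labels. The default
#' label heuristic exploits phase-contrast geometry: the background gap is
#' smoother than the cell layer, so the component whose tiles have the larger
#' mean frequency of the all-ties score LBP = 8 is taken as background.
#'
#' @param features `n_tiles` x 9 feature matrix from [extract_features()].
#' @param n_pca number of retained principal components (default 5).
#' @param seed integer seed making the k-means initialization (and hence the
#'   whole fit) deterministic.
#' @param labeling `"auto"` (flat-texture heuristic above),
#'   `"component0_is_cell"` or `"component1_is_cell"` for manual override.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @return object of class `texture_classifier` holding the PCA rotation,
#'   the mixture parameters and `cell_component` (1 or 2).
#' @export
fit_texture_classifier <- function(features, n_pca = 5L, seed = 0L,
                                   labeling = c("auto", "component0_is_cell",
                                                "component1_is_cell"),
                                   max_iter = 200L, tol = 1e-4) {
  labeling <- match.arg(labeling)
  features <- as.matrix(features)
  if (!all(is.finite(features)))
    stop("features must be finite", call. = FALSE)
  if (nrow(features) < 2L * n_pca)
    stop("need at least ", 2L * n_pca, " tiles to fit the classifier",
         call. = FALSE)
  if (all(apply(features, 2L, stats::var) < 1e-18))
    stop("degenerate features: zero variance in all 9 LBP bins ",
         "(is the frame textureless?)", call. = FALSE)
  pca <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  n_pca <- min(n_pca, ncol(pca$rotation))
  scores <- pca$x[, seq_len(n_pca), drop = FALSE]
  gmm <- fit_gmm(scores, k = 2L, seed = seed, max_iter = max_iter, tol = tol)
  hard <- max.col(gmm$resp)
  cell_component <- switch(labeling,
    component0_is_cell = 1L,
    component1_is_cell = 2L,
    auto = {
      # larger mean frequency of LBP=8 (flat texture) => background
      f8 <- vapply(1:2, function(j) {
        if (!any(hard == j)) return(Inf)
        mean(features[hard == j, 9L])
      }, numeric(1))
      which.min(f8)
    })
  structure(list(center = pca$center,
                 rotation = pca$rotation[, seq_len(n_pca), drop = FALSE],
                 n_pca = n_pca, gmm = gmm[c("weights", "means", "covs")],
                 cell_component = cell_component, seed = seed),
            class = "texture_classifier")
}

#' @export
print.texture_classifier <- function(x, ...) {
  cat(sprintf(
    "texture_classifier: %d PCs, 2-component GMM (weights %.3f/%.3f), cell = component %d\n",
    x$n_pca, x$gmm$weights[1], x$gmm$weights[2], x$cell_component))
  invisible(x)
}

classifier_labels <- function(classifier, features) {
  scores <- sweep(as.matrix(features), 2L, classifier$center) %*%
    classifier$rotation
  post <- gmm_posterior(classifier$gmm, scores)
  max.col(post) == classifier$cell_component
}

#' Binarize a frame by tile texture classification
#'
#' Scores each tile of `frame` with the LBP histogram features, classifies it
#' with the fitted mixture (posterior argmax in PCA space) and broadcasts the
#' tile label to its pixels. `TRUE` = cell layer, `FALSE` = background.
#'
#' @param frame equalized grayscale matrix.
#' @param classifier a fitted [fit_texture_classifier()] object.
#' @param grid the [tessellate()] grid (defaults to 12x16 px tiles on
#'   `frame`'s dimensions).
#' @param frame_index frame number recorded in the mask (default 0).
#' @return object of class `binary_mask`: logical matrix `mask` at the grid's
#'   covered extent plus `frame_index` and the grid.
#' @export
binarize_frame <- function(frame, classifier, grid = NULL, frame_index = 0L) {
  if (!inherits(classifier, "texture_classifier"))
    stop("`classifier` must be a fitted texture_classifier", call. = FALSE)
  if (is.null(grid)) grid <- tessellate(frame)
  feats <- extract_features(lbp_image(frame), grid)
  lab <- classifier_labels(classifier, feats)
  tile_lab <- matrix(lab, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  mask <- tile_lab[rep(seq_len(grid$n_rows), each = grid$tile_height),
                   rep(seq_len(grid$n_cols), each = grid$tile_width)]
  binary_mask(mask, frame_index = frame_index, grid = grid)
}

#' Binary cell/background mask
#'
#' @param mask logical matrix, `TRUE` = cell layer.
#' @param frame_index frame number.
#' @param grid optional generating `tile_grid`.
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(mask, frame_index = 0L, grid = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(list(mask = mask, frame_index = as.integer(frame_index),
                 grid = grid),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d px, frame %d, %.1f%% cell\n",
              nrow(x$mask), ncol(x$mask), x$frame_index,
              100 * mean(x$mask)))
  invisible(x)
}
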