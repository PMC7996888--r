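#' Wound-front polyline
#'
#' An ordered polyline of (x, y) pixel coordinates describing one wound edge
#' (left `L` or right `R`) in one frame. On construction the polyline is
#' normalized to strictly increasing y: points are ordered by y and, where
#' several x values share one y (staircase contours), their mean x is kept,
#' making x a single-valued function of y.
#'
#' @param points numeric matrix or data.frame with two columns (x, y), at
#'   least two distinct points.
#' @param side `"L"` or `"R"`.
#' @param frame_index frame number (default 0).
#' @param normalize normalize to strictly increasing y (default TRUE).
#' @return object of class `wound_front` with fields `points` (n x 2 matrix,
#'   columns `x`, `y`), `side`, `frame_index`.
#' @export
wound_front <- function(points, side = c("L", "R"), frame_index = 0L,
                        normalize = TRUE) {
  side <- match.arg(side)
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("`points` must have two columns (x, y)",
                            call. = FALSE)
  if (!is.numeric(pts) || anyNA(pts))
    stop("front points must be finite numbers", call. = FALSE)
  if (normalize) pts <- normalize_front_points(pts)
  if (nrow(pts) < 2L)
    stop("a front needs at least 2 points with distinct y", call. = FALSE)
  dimnames(pts) <- list(NULL, c("x", "y"))
  structure(list(points = pts, side = side,
                 frame_index = as.integer(frame_index)),
            class = "wound_front")
}

normalize_front_points <- function(pts) {
  o <- order(pts[, 2L], pts[, 1L])
  pts <- pts[o, , drop = FALSE]
  y <- pts[, 2L]
  ys <- unique(y)
  x <- vapply(ys, function(v) mean(pts[y == v, 1L]), numeric(1))
  cbind(x, ys)
}

#' @export
print.wound_front <- function(x, ...) {
  cat(sprintf("wound_front %s (frame %d): %d points, y in [%g, %g]\n",
              x$side, x$frame_index, nrow(x$points),
              min(x$points[, 2L]), max(x$points[, 2L])))
  invisible(x)
}

#' Extract boundary contours of a binary mask and flag the wound contour
#'
#' Traces the boundary of every connected background (`FALSE`) region of the
#' mask and flags the contour of greatest total arc length: while the two
#' cellular fronts remain separate, that longest contour is the boundary of
#' the central wound gap, delineating both fronts at once. Contours touching
#' the frame border are closed along the border for the length computation.
#'
#' @param mask a [binary_mask()] or logical matrix (`TRUE` = cell layer).
#' @return object of class `wound_contours`: list with `contours` (list of
#'   k x 2 (x, y) matrices in traversal order), `lengths` (arc lengths) and
#'   `wound_index` (index of the longest contour).
#' @export
extract_wound_contour <- function(mask) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  stopifnot(is.matrix(m), is.logical(m))
  if (all(m)) stop("no wound detected: mask is entirely cell layer",
                   call. = FALSE)
  if (!any(m)) stop("no wound detected: mask is entirely background",
                    call. = FALSE)
  lab <- label_components(!m)
  ks <- sort(unique(lab[lab > 0L]))
  contours <- lapply(ks, function(k) trace_boundary(lab == k))
  lens <- vapply(contours, polyline_length, numeric(1), closed = TRUE)
  structure(list(contours = contours, lengths = lens,
                 wound_index = which.max(lens), dims = dim(m)),
            class = "wound_contours")
}

#' @export
print.wound_contours <- function(x, ...) {
  cat(sprintf("wound_contours: %d contour(s); wound = #%d (arc length %.1f px)\n",
              length(x$contours), x$wound_index,
              x$lengths[x$wound_index]))
  invisible(x)
}

#' Split the wound contour into left and right fronts
#'
#' The wound-gap contour of a scratch spans the frame from the top row to the
#' bottom row. Its points lying on those two border rows (the runs closing the
#' contour along the frame border) are discarded; the remaining traversal
#' splits into contiguous arcs, of which the two longest are the lateral
#' sides. The side with the smaller mean x becomes the left front `L`, the
#' other the right front `R`; both are normalized to increasing y.
#'
#' @param contours a [extract_wound_contour()] result, or a k x 2 contour
#'   matrix.
#' @param dims frame dimensions `c(height, width)`; taken from `contours`
#'   when available.
#' @param frame_index recorded in the fronts.
#' @return list with elements `L` and `R`, both [wound_front()] objects.
#' @export
split_fronts <- function(contours, dims = NULL, frame_index = 0L) {
  if (inherits(contours, "wound_contours")) {
    pts <- contours$contours[[contours$wound_index]]
    if (is.null(dims)) dims <- contours$dims
  } else pts <- as.matrix(contours)
  if (is.null(dims)) stop("`dims` (height, width) required", call. = FALSE)
  H <- dims[1L]
  y <- pts[, 2L]
  if (min(y) > 0 || max(y) < H - 1L)
    stop(sprintf(
      "fronts merged or detached at frame %d: wound contour spans y %g..%g, not 0..%d",
      frame_index, min(y), max(y), H - 1L), call. = FALSE)
  keep <- y > 0 & y < H - 1L
  if (!any(keep))
    stop(sprintf("fronts merged or detached at frame %d: no lateral contour points",
                 frame_index), call. = FALSE)
  # contiguous runs of kept points along the (cyclic) traversal
  n <- nrow(pts)
  run_id <- cumsum(c(TRUE, diff(which(keep)) > 1L))
  runs <- split(which(keep), run_id)
  # cyclic wrap: merge last run with first if adjacent through the seam
  if (length(runs) > 1L && keep[1L] && keep[n] &&
      runs[[1L]][1L] == 1L && runs[[length(runs)]][length(runs[[length(runs)]])] == n) {
    runs[[1L]] <- c(runs[[length(runs)]], runs[[1L]])
    runs[[length(runs)]] <- NULL
  }
  if (length(runs) < 2L)
    stop(sprintf("fronts merged or detached at frame %d: only one lateral arc",
                 frame_index), call. = FALSE)
  arc_len <- vapply(runs, function(i)
    polyline_length(pts[i, , drop = FALSE], closed = FALSE), numeric(1))
  top2 <- order(arc_len, decreasing = TRUE)[1:2]
  a <- pts[runs[[top2[1L]]], , drop = FALSE]
  b <- pts[runs[[top2[2L]]], , drop = FALSE]
  if (mean(a[, 1L]) > mean(b[, 1L])) { tmp <- a; a <- b; b <- tmp }
  list(L = wound_front(a, "L", frame_index),
       R = wound_front(b, "R", frame_index))
}

#' Otsu threshold of an intensity sample
#'
#' Exhaustive maximizer of the between-class variance over all integer
#' thresholds: returns `t` such that the split `v <= t` / `v > t` maximizes
#' `w0 * w1 * (mu0 - mu1)^2`.
#'
#' @param values numeric vector or matrix of integer intensities.
#' @return the threshold `t` (class 0 is `v <= t`).
#' @export
otsu_threshold <- function(values) {
  v <- as.vector(values)
  if (min(v) == max(v))
    stop("Otsu threshold undefined for a constant image", call. = FALSE)
  lev <- sort(unique(round(v)))
  h <- tabulate(match(round(v), lev))
  p <- h / sum(h)
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[length(mu)]
  k <- seq_len(length(lev) - 1L)
  bcv <- (mu_t * w0[k] - mu[k])^2 / (w0[k] * (1 - w0[k]))
  lev[which.max(bcv)]
}

#' Segment a frame by blurring + Otsu thresholding + morphology
#'
#' Baseline segmentation alternative to the texture classifier: the (already
#' CLAHE-equalized) frame is Gaussian-blurred, thresholded globally at the
#' Otsu optimum, and smoothed by a morphological closing followed by an
#' opening with a disk structuring element. Mask polarity is fixed so that
#' `TRUE` = cell layer, using the scratch geometry (the lateral image borders
#' lie in the cell layers).
#'
#' @param frame equalized grayscale matrix.
#' @param blur_sigma Gaussian blur standard deviation in px (default 2).
#' @param morph_radius disk radius in px for closing/opening (default 5).
#' @param frame_index recorded in the mask.
#' @return a [binary_mask()].
#' @export
otsu_segment <- function(frame, blur_sigma = 2, morph_radius = 5L,
                         frame_index = 0L) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  if (min(frame) == max(frame))
    stop("Otsu segmentation undefined for a constant frame", call. = FALSE)
  b <- gaussian_blur(frame, blur_sigma)
  thr <- otsu_threshold(round(b))
  mask <- round(b) > thr
  # polarity: the outer fifth of columns on each side is cell layer
  w <- ncol(mask)
  edge <- c(seq_len(max(1L, w %/% 5)), (w - max(1L, w %/% 5) + 1L):w)
  if (mean(mask[, edge]) < 0.5) mask <- !mask
  mask <- morph_open(morph_close(mask, morph_radius), morph_radius)
  binary_mask(mask, frame_index = frame_index)
}

# separable Gaussian blur with replicate padding
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  blur_axis <- function(m, along_rows) {
    H <- nrow(m); W <- ncol(m)
    out <- matrix(0, H, W)
    for (i in seq_along(k)) {
      off <- i - r - 1L
      if (along_rows) {
        rows <- pmin(pmax(seq_len(H) + off, 1L), H)
        out <- out + k[i] * m[rows, , drop = FALSE]
      } else {
        cols <- pmin(pmax(seq_len(W) + off, 1L), W)
        out <- out + k[i] * m[, cols, drop = FALSE]
      }
    }
    out
  }
  blur_axis(blur_axis(m, TRUE), FALSE)
}

disk_offsets <- function(r) {
  d <- expand.grid(dr = -r:r, dc = -r:r)
  d[d$dr^2 + d$dc^2 <= r^2, , drop = FALSE]
}

shift_mask <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  rows <- pmin(pmax(seq_len(H) - dr, 1L), H)
  cols <- pmin(pmax(seq_len(W) - dc, 1L), W)
  m[rows, cols, drop = FALSE]
}

morph_dilate <- function(mask, r) {
  out <- mask
  off <- disk_offsets(r)
  for (i in seq_len(nrow(off)))
    out <- out | shift_mask(mask, off$dr[i], off$dc[i])
  out
}

morph_erode <- function(mask, r) !morph_dilate(!mask, r)
morph_close <- function(mask, r) morph_erode(morph_dilate(mask, r), r)
morph_open <- function(mask, r) morph_dilate(morph_erode(mask, r), r)

#' Read a hand-traced front coordinate file
#'
#' Parses the plain-text dialect exported when tracing fronts by hand in
#' ImageJ: one `x y` pair per line, whitespace- or comma-separated; blank
#' lines ignored.
#'
#' @param path text file path.
#' @param side `"L"` or `"R"`.
#' @param frame_index frame number recorded in the front.
#' @return a [wound_front()] (normalized to increasing y).
#' @export
read_imagej_front <- function(path, side = c("L", "R"), frame_index = 0L) {
  side <- match.arg(side)
  if (!file.exists(path)) stop("front file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  pts <- matrix(numeric(0), ncol = 2L)
  for (i in nonblank) {
    tok <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(vals) != 2L || anyNA(vals))
      stop(sprintf("parse error in %s at line %d: %s", path, i, lines[i]),
           call. = FALSE)
    pts <- rbind(pts, vals)
  }
  if (nrow(pts) < 2L)
    stop(path, ": a front needs at least 2 coordinate pairs", call. = FALSE)
  wound_front(pts, side, frame_index)
}

#' Write a front in the plain-text x/y dialect
#'
#' @param front a [wound_front()].
#' @param path output file.
#' @export
write_front <- function(front, path) {
  stopifnot(inherits(front, "wound_front"))
  writeLines(sprintf("%g %g", front$points[, 1L], front$points[, 2L]), path)
  invisible(path)
}
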