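#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Per-tile histogram equalization with contrast limiting. The frame is tiled
#' into blocks of `tile_size` pixels (partial tiles at the right/bottom border
#' are equalized as-is); within each tile the intensity histogram is clipped at
#' `clip_limit` counts per bin, the clipped excess is redistributed uniformly
#' over all bins, and the resulting CDF defines the tile's equalization
#' mapping. Pixel values are then remapped by bilinear interpolation between
#' the mappings of the four nearest tile centres, which suppresses visible
#' tile seams.
#'
#' Equalizing all frames of an experiment to a common full intensity range is
#' what makes frames acquired hours apart comparable for texture scoring.
#'
#' @param frame integer matrix of intensities (8- or 16-bit range).
#' @param tile_size integer vector `(rows, cols)` of the tile size in pixels
#'   (default `c(50, 50)`).
#' @param clip_limit histogram clip limit in counts per bin (default 40);
#'   `Inf` disables clipping (plain adaptive equalization).
#' @param nbins number of histogram bins; defaults to the full depth for 8-bit
#'   input and 4096 for deeper input.
#' @return integer matrix of the same dimensions, spanning (up to clipping
#'   redistribution) the full representable range of the input depth.
#' @export
equalize_frame <- function(frame, tile_size = c(50L, 50L), clip_limit = 40,
                           nbins = NULL) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("`frame` must be a numeric matrix", call. = FALSE)
  H <- nrow(frame); W <- ncol(frame)
  th <- as.integer(tile_size[1L]); tw <- as.integer(tile_size[2L])
  if (th <= 0L || tw <= 0L) stop("tile_size must be positive", call. = FALSE)
  if (th > H || tw > W)
    stop(sprintf("tile_size %dx%d larger than frame %dx%d", th, tw, H, W),
         call. = FALSE)
  maxval <- if (max(frame) <= 255L) 255L else 65535L
  if (is.null(nbins)) nbins <- if (maxval == 255L) 256L else 4096L
  # bin index (1-based) of every pixel
  bin <- pmin(frame %/% ((maxval + 1L) / nbins), nbins - 1L) + 1L
  storage.mode(bin) <- "integer"

  n_rows <- as.integer(ceiling(H / th)); n_cols <- as.integer(ceiling(W / tw))
  row_lo <- (seq_len(n_rows) - 1L) * th + 1L
  row_hi <- pmin(row_lo + th - 1L, H)
  col_lo <- (seq_len(n_cols) - 1L) * tw + 1L
  col_hi <- pmin(col_lo + tw - 1L, W)

  # per-tile lookup tables: nbins x (n_rows*n_cols), column-major tile index
  lut <- matrix(0, nrow = nbins, ncol = n_rows * n_cols)
  for (tc in seq_len(n_cols)) {
    for (tr in seq_len(n_rows)) {
      b <- bin[row_lo[tr]:row_hi[tr], col_lo[tc]:col_hi[tc]]
      h <- tabulate(b, nbins = nbins)
      if (is.finite(clip_limit)) {
        excess <- sum(pmax(h - clip_limit, 0))
        h <- pmin(h, clip_limit) + excess / nbins
      }
      cdf <- cumsum(h) / sum(h)
      lut[, (tc - 1L) * n_rows + tr] <- round(cdf * maxval)
    }
  }

  # bilinear interpolation between tile-centre mappings (clamped at borders)
  centers_r <- (row_lo + row_hi) / 2
  centers_c <- (col_lo + col_hi) / 2
  interp_axis <- function(pos, centers) {
    lo <- findInterval(pos, centers)           # 0..n
    lo_cl <- pmax(lo, 1L)
    hi_cl <- pmin(lo + 1L, length(centers))
    w_hi <- ifelse(lo_cl == hi_cl, 0,
                   (pos - centers[lo_cl]) / (centers[hi_cl] - centers[lo_cl]))
    list(lo = lo_cl, hi = hi_cl, w = pmin(pmax(w_hi, 0), 1))
  }
  ry <- interp_axis(seq_len(H), centers_r)
  cx <- interp_axis(seq_len(W), centers_c)

  # expand per-pixel tile indices and weights
  r_lo <- matrix(ry$lo, H, W); r_hi <- matrix(ry$hi, H, W)
  wy   <- matrix(ry$w,  H, W)
  c_lo <- matrix(cx$lo, H, W, byrow = TRUE); c_hi <- matrix(cx$hi, H, W, byrow = TRUE)
  wx   <- matrix(cx$w,  H, W, byrow = TRUE)
  g <- function(tr, tc) lut[cbind(as.vector(bin),
                                  as.vector((tc - 1L) * n_rows + tr))]
  out <- (1 - wy) * (1 - wx) * g(r_lo, c_lo) +
         (1 - wy) * wx       * g(r_lo, c_hi) +
         wy       * (1 - wx) * g(r_hi, c_lo) +
         wy       * wx       * g(r_hi, c_hi)
  out <- matrix(as.integer(round(out)), H, W)
  out
}

#' Equalize all frames of a stack
#'
#' Applies [equalize_frame()] to every frame, preserving stack metadata.
#'
#' @param stack a [frame_stack()].
#' @inheritParams equalize_frame
#' @return a new `frame_stack` of equalized frames.
#' @export
equalize_stack <- function(stack, tile_size = c(50L, 50L), clip_limit = 40) {
  stopifnot(inherits(stack, "frame_stack"))
  frame_stack(lapply(stack$frames, equalize_frame, tile_size = tile_size,
                     clip_limit = clip_limit),
              frame_interval = stack$frame_interval,
              pixel_size = stack$pixel_size)
}
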