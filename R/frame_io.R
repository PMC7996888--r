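#' Time-lapse frame stack
#'
#' Container for an ordered sequence of single-channel grayscale frames with
#' acquisition metadata. All frames must share the same dimensions; intensities
#' are stored as integer matrices (row = y, column = x, image convention with y
#' increasing downwards).
#'
#' @param frames list of integer matrices, one per frame, identical dimensions.
#' @param frame_interval sampling interval in hours per frame (default 0.25,
#'   i.e. 4 frames/hour).
#' @param pixel_size physical pixel size in micrometres per pixel. Defaults to
#'   1, in which case all downstream positions are in pixels.
#' @return An object of class `frame_stack` with elements `frames`,
#'   `frame_interval`, `pixel_size`, `height`, `width`.
#' @export
frame_stack <- function(frames, frame_interval = 0.25, pixel_size = 1.0) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0)
    stop("`frame_interval` must be a single positive number of hours",
         call. = FALSE)
  frames <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    f <- to_grayscale(f, what = sprintf("frame %d", i))
    storage.mode(f) <- "integer"
    f
  })
  d0 <- dim(frames[[1L]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d0))
      stop(sprintf(
        "frame %d has dimensions %dx%d, expected %dx%d (all frames must match)",
        i, nrow(frames[[i]]), ncol(frames[[i]]), d0[1L], d0[2L]), call. = FALSE)
  }
  structure(
    list(frames = frames, frame_interval = frame_interval,
         pixel_size = pixel_size, height = d0[1L], width = d0[2L]),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("frame_stack: %d frame(s) of %d x %d px, dt = %g h, px = %g um\n",
              length(x$frames), x$height, x$width, x$frame_interval,
              x$pixel_size))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

# Reduce a 3D (H x W x C) array to grayscale by Rec.601 luminance; pass
# matrices through. Values in [0,1] (png convention) are rescaled to 0..255.
to_grayscale <- function(f, what = "frame") {
  if (is.array(f) && length(dim(f)) == 3L) {
    nc <- dim(f)[3L]
    if (nc >= 3L) {
      f <- 0.299 * f[, , 1L] + 0.587 * f[, , 2L] + 0.114 * f[, , 3L]
    } else {
      f <- f[, , 1L]
    }
  }
  if (!is.matrix(f) || !is.numeric(f))
    stop(sprintf("%s is not a 2D numeric matrix or 3D array", what),
         call. = FALSE)
  if (anyNA(f)) stop(sprintf("%s contains NA intensities", what), call. = FALSE)
  mx <- max(f)
  if (mx <= 1 && min(f) >= 0 && !all(f == round(f))) f <- f * 255
  round(f)
}

#' Load a time-lapse image sequence
#'
#' Reads either a single frame file or a directory of frames; in a directory,
#' lexicographic filename order is taken as acquisition (time) order. Supported
#' formats are PNG (8/16-bit, RGB reduced to grayscale by luminance), PGM
#' (ASCII `P2` or binary `P5`) and CSV matrices of integer intensities. TIFF is
#' not readable in this installation; convert stacks to per-frame PNG first
#' (e.g. with ImageJ or `tifffile` in Python).
#'
#' @param path file or directory path.
#' @param frame_interval hours per frame (default 0.25).
#' @param pixel_size micrometres per pixel (default 1 = positions in px).
#' @param frame_range optional integer vector of frame indices (after sorting)
#'   to retain, e.g. `1:40`; supports the common case of truncating a longer
#'   acquisition before analysis.
#' @return a [frame_stack()].
#' @export
load_time_lapse <- function(path, frame_interval = 0.25, pixel_size = 1.0,
                            frame_range = NULL) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|pgm|csv)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (any(grepl("\\.tiff?$", list.files(path), ignore.case = TRUE)) &&
        length(files) == 0L)
      stop("TIFF frames found but no TIFF reader is available; ",
           "convert to PNG or PGM first", call. = FALSE)
    if (length(files) == 0L)
      stop("no readable frames (.png/.pgm/.csv) in directory ", path,
           call. = FALSE)
    files <- sort(files)
  } else {
    if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      stop("TIFF input is not supported offline; convert to PNG or PGM",
           call. = FALSE)
    files <- path
  }
  if (!is.null(frame_range)) files <- files[frame_range]
  frames <- lapply(files, read_frame)
  names(frames) <- basename(files)
  frame_stack(frames, frame_interval = frame_interval, pixel_size = pixel_size)
}

read_frame <- function(file) {
  ext <- tolower(tools::file_ext(file))
  f <- switch(ext,
    png = {
      a <- png::readPNG(file)
      a <- to_grayscale(if (length(dim(a)) == 3L) a else a * 255,
                        what = basename(file))
      a
    },
    pgm = read_pgm(file),
    csv = as.matrix(utils::read.csv(file, header = FALSE)),
    stop("unsupported frame format: ", file, call. = FALSE))
  if (!is.matrix(f)) stop("could not read ", file, " as a 2D frame",
                          call. = FALSE)
  f
}

# Minimal NetPBM grayscale reader (P2 ASCII / P5 binary, maxval <= 65535).
read_pgm <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5"))
    stop(file, ": not a PGM file (magic ", magic, ")", call. = FALSE)
  # header tokens (width height maxval), '#' comments allowed
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop(file, ": truncated PGM header", call. = FALSE)
    if (ch == "#") { # skip comment to end of line
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf)) {
      tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- tokens[1L]; h <- tokens[2L]; maxval <- tokens[3L]
  n <- w * h
  if (magic == "P5") {
    if (maxval < 256) {
      v <- as.integer(readBin(con, "raw", n))
    } else {
      raw2 <- readBin(con, "raw", 2L * n)
      v <- as.integer(raw2[c(TRUE, FALSE)]) * 256L +
           as.integer(raw2[c(FALSE, TRUE)])
    }
  } else {
    txt <- readChar(con, file.size(file), useBytes = TRUE)
    v <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1L]])[seq_len(n)]
  }
  if (length(v) < n || anyNA(v))
    stop(file, ": truncated or malformed PGM pixel data", call. = FALSE)
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale frame as ASCII PGM (P2)
#'
#' @param frame integer matrix of intensities.
#' @param file output path.
#' @param maxval maximum representable intensity (default 255).
#' @export
write_pgm <- function(frame, file, maxval = 255L) {
  frame <- pmax(pmin(round(frame), maxval), 0)
  header <- sprintf("P2\n%d %d\n%d", ncol(frame), nrow(frame), maxval)
  body <- apply(frame, 1L, paste, collapse = " ")
  writeLines(c(header, body), file)
  invisible(file)
}
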