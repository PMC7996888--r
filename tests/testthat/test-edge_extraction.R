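# build a mask with a background stripe whose edges follow analytic curves
# x_L(y), x_R(y): pixel (row, col) is background iff x_L(y) < x < x_R(y)
stripe_mask <- function(H, W, xl, xr) {
  xs <- matrix(0:(W - 1), H, W, byrow = TRUE)
  !(xs > matrix(xl, H, W) & xs < matrix(xr, H, W))
}

test_that("extract_wound_contour flags the stripe boundary as longest", {
  m <- stripe_mask(40, 60, rep(19.5, 40), rep(40.5, 40))
  wc <- extract_wound_contour(m)
  expect_s3_class(wc, "wound_contours")
  expect_length(wc$contours, 1L)
  pts <- wc$contours[[wc$wound_index]]
  expect_setequal(unique(pts[, "x"]) , 20:40)

  # add a small background hole inside the cell layer: stripe stays longest
  m2 <- m; m2[5:7, 3:5] <- FALSE
  wc2 <- extract_wound_contour(m2)
  expect_length(wc2$contours, 2L)
  longest <- wc2$contours[[wc2$wound_index]]
  expect_gte(min(longest[, "x"]), 20)

  expect_error(extract_wound_contour(matrix(TRUE, 5, 5)), "no wound")
  expect_error(extract_wound_contour(matrix(FALSE, 5, 5)), "no wound")
})

test_that("split_fronts recovers straight stripe edges", {
  m <- stripe_mask(40, 60, rep(19.5, 40), rep(40.5, 40))
  sp <- split_fronts(extract_wound_contour(m))
  expect_equal(sp$L$side, "L"); expect_equal(sp$R$side, "R")
  # background-side boundary pixels of the stripe: x = 20 and x = 40
  expect_true(all(sp$L$points[, "x"] == 20))
  expect_true(all(sp$R$points[, "x"] == 40))
  expect_true(all(diff(sp$L$points[, "y"]) > 0))
})

test_that("split_fronts recovers sinusoidal edges within 1 px RMS", {
  H <- 200; W <- 160
  y <- 0:(H - 1)
  xl <- 50 + 10 * sin(2 * pi * y / 60)
  xr <- 110 + 8 * cos(2 * pi * y / 45)
  sp <- split_fronts(extract_wound_contour(stripe_mask(H, W, xl, xr)))
  # compare on the fronts' own y support (borders trimmed); boundary pixels
  # sit ~0.5 px outside the analytic curve, so subtract that offset
  check_rms <- function(front, truth_fun, sign) {
    yy <- front$points[, "y"]
    err <- front$points[, "x"] - sign * 0.5 - truth_fun(yy)
    sqrt(mean(err^2))
  }
  expect_lt(check_rms(sp$L, function(yy) 50 + 10 * sin(2 * pi * yy / 60), +1), 1)
  expect_lt(check_rms(sp$R, function(yy) 110 + 8 * cos(2 * pi * yy / 45), -1), 1)
  # Hausdorff-style bound: every front point within 2 px of the curve
  expect_lt(max(abs(sp$L$points[, "x"] - 0.5 -
                    (50 + 10 * sin(2 * pi * sp$L$points[, "y"] / 60)))), 2)
})

test_that("merged or non-spanning wounds raise the dedicated error", {
  # stripe pinched shut in the middle
  H <- 40; W <- 60
  xl <- rep(25, H); xr <- rep(35, H); xr[20] <- 25.5
  m <- stripe_mask(H, W, xl, xr)
  expect_error(split_fronts(extract_wound_contour(m), frame_index = 7L),
               "merged|detached")
  # island of background not touching top/bottom
  m2 <- matrix(TRUE, 30, 30); m2[10:20, 12:18] <- FALSE
  expect_error(split_fronts(extract_wound_contour(m2)), "merged or detached")
})

test_that("otsu_threshold equals the exhaustive between-class-variance maximizer", {
  # bimodal: threshold strictly between the modes
  v <- c(rep(10, 120), rep(200, 80))
  t0 <- otsu_threshold(v)
  expect_gte(t0, 10); expect_lt(t0, 200)
  set.seed(21)
  for (i in 1:20) {
    v <- sample(0:7, 300, replace = TRUE,
                prob = runif(8))
    expect_equal(otsu_threshold(v), oracle_otsu(v))
  }
  expect_error(otsu_threshold(rep(3, 10)), "constant")
})

test_that("otsu_segment recovers a clean synthetic wound within 2 px RMS", {
  set.seed(6)
  H <- 120; W <- 200
  y <- 0:(H - 1)
  xl <- 70 + 5 * sin(2 * pi * y / 50); xr <- 130 - 5 * cos(2 * pi * y / 40)
  cell <- !stripe_mask(H, W, xl, xr)  # TRUE = background gap here
  frame <- ifelse(!cell, 170 + matrix(rnorm(H * W, sd = 25), H, W),
                  40 + matrix(rnorm(H * W, sd = 5), H, W))
  frame <- matrix(as.integer(pmax(pmin(round(frame), 255), 0)), H, W)
  mask <- otsu_segment(frame, blur_sigma = 2, morph_radius = 3)
  sp <- split_fronts(extract_wound_contour(mask))
  rms <- function(front, truth) {
    yy <- front$points[, "y"]
    tv <- approx(y, truth, xout = yy)$y
    sqrt(mean((front$points[, "x"] - tv)^2))
  }
  expect_lt(rms(sp$L, xl), 2)
  expect_lt(rms(sp$R, xr), 2)
  expect_error(otsu_segment(matrix(9L, 20, 20)), "constant")
})

test_that("read_imagej_front parses both dialects and reports bad lines", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.txt")
  writeLines(c("0 0", "0 100"), f1)
  fr <- read_imagej_front(f1, "L", 3L)
  expect_equal(nrow(fr$points), 2L)
  expect_equal(fr$frame_index, 3L)

  f2 <- file.path(dir, "b.txt")
  writeLines(c("1.5,2", "3,4.25", "5, 6"), f2)
  fr2 <- read_imagej_front(f2, "R")
  expect_equal(fr2$points[, "x"], c(1.5, 3, 5), ignore_attr = TRUE)

  f3 <- file.path(dir, "c.txt")
  writeLines(c("1 2", "3 4", "bad token", "5 6"), f3)
  expect_error(read_imagej_front(f3, "L"), "line 3")

  f4 <- file.path(dir, "d.txt")
  writeLines("1 2", f4)
  expect_error(read_imagej_front(f4, "L"), "at least 2")

  # round trip through write_front
  f5 <- file.path(dir, "e.txt")
  write_front(fr2, f5)
  expect_equal(read_imagej_front(f5, "R")$points, fr2$points)
})

test_that("front normalization makes y strictly increasing", {
  pts <- cbind(c(5, 6, 6, 4, 7), c(3, 1, 2, 2, 0))
  fr <- wound_front(pts, "L")
  expect_true(all(diff(fr$points[, "y"]) > 0))
  # duplicate-y rows averaged
  expect_equal(fr$points[fr$points[, "y"] == 2, "x"], 5, ignore_attr = TRUE)
})
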