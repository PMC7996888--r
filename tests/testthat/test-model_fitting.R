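test_that("adjusted_r_squared follows the penalized formula", {
  y <- c(1, 3, 2, 5, 4, 6)
  expect_equal(adjusted_r_squared(y, y, 1), 1)
  # fitted = mean: R^2 = 0, adjusted <= 0
  expect_lte(adjusted_r_squared(y, rep(mean(y), 6), 1), 0)
  # small worked case against the direct formula
  f <- c(1.2, 2.8, 2.2, 4.6, 4.2, 5.8)
  r2 <- 1 - sum((y - f)^2) / sum((y - mean(y))^2)
  expect_equal(adjusted_r_squared(y, f, 2), 1 - (1 - r2) * 5 / 3)
  expect_error(adjusted_r_squared(y[1:3], f[1:3], 2), "n_params")
})

test_that("fit_drift recovers a noiseless drift line exactly", {
  t <- seq(0, 10, by = 0.25)
  x <- ifelse(t > 4.5, 20 * (t - 4.5), 0)
  f <- fit_drift(x, t, window = c(4.5, 8))
  expect_equal(unname(f$params["vd"]), 20, tolerance = 1e-10)
  expect_equal(unname(f$params["tau1"]), 4.5, tolerance = 1e-10)
  expect_equal(f$adj_r_squared, 1, tolerance = 1e-10)
  expect_equal(f$n_points, sum(t > 4.5 & t < 8))
  expect_error(fit_drift(x, t, window = c(4.5, 5.1)), "at least 3")
  expect_error(fit_drift(x, t, window = c(8, 4.5)), "t_low < t_high")
})

test_that("fit_drift is unbiased under noise (mean within 2 SE over replicates)", {
  t <- seq(0, 10, by = 0.25)
  mu <- 20 * (t - 4.5)
  ests <- t(vapply(1:100, function(i) {
    set.seed(i)
    x <- mu + rnorm(length(t), sd = 0.5)
    f <- fit_drift(x, t, window = c(4.5, 8))
    c(f$params, f$std_errors)
  }, numeric(4)))
  se_mean_vd <- sd(ests[, 1]) / 10
  se_mean_tau <- sd(ests[, 2]) / 10
  expect_lt(abs(mean(ests[, 1]) - 20), 2 * se_mean_vd)
  expect_lt(abs(mean(ests[, 2]) - 4.5), 2 * se_mean_tau)
  # reported SEs are calibrated against the replicate spread
  expect_equal(mean(ests[, 3]), sd(ests[, 1]), tolerance = 0.3)
  expect_equal(mean(ests[, 4]), sd(ests[, 2]), tolerance = 0.3)
})

test_that("fit_drift equivariance: time shift moves tau1, scaling x scales vd", {
  set.seed(12)
  t <- seq(0, 10, by = 0.25)
  x <- ifelse(t > 3, 7 * (t - 3), 0) + rnorm(length(t), sd = 0.2)
  f0 <- fit_drift(x, t, c(3, 9))
  f_shift <- fit_drift(x, t + 2, c(5, 11))
  expect_equal(unname(f_shift$params["tau1"]),
               unname(f0$params["tau1"]) + 2, tolerance = 1e-9)
  expect_equal(f_shift$params["vd"], f0$params["vd"], tolerance = 1e-9)
  f_scale <- fit_drift(3 * x, t, c(3, 9))
  expect_equal(unname(f_scale$params["vd"]), 3 * unname(f0$params["vd"]),
               tolerance = 1e-9)
})

test_that("detect_drift_window finds quiescence-then-drift breakpoints", {
  t <- seq(0, 10, by = 0.25)
  set.seed(3)
  x <- ifelse(t > 5, 10 * (t - 5), 0) + rnorm(length(t), sd = 0.4)
  w <- detect_drift_window(x, t)
  expect_lt(abs(w[1] - 5), 0.75)
  expect_gte(w[2], 9.5)  # no stalling: window runs to the end
  # drift that stalls (noiseless): upper bound at the stall
  x2 <- ifelse(t > 3, 8 * (pmin(t, 7) - 3), 0)
  w2 <- detect_drift_window(x2, t)
  expect_lt(abs(w2[1] - 3), 0.75)
  expect_lt(abs(w2[2] - 7), 0.75)
  # the auto window feeds a successful drift fit
  f <- fit_drift(x, t, w)
  expect_equal(unname(f$params["vd"]), 10, tolerance = 0.1)
})

test_that("fit_increment_tails identifies the generating law", {
  # exponential data: lambda within 3%, exponential beats half-Gaussian
  set.seed(1)
  v <- rexp(1e5, rate = 1 / 30)
  f <- fit_increment_tails(v)
  expect_equal(unname(f$exponential$params["lambda"]), 30, tolerance = 0.03)
  expect_gt(f$exponential$adj_r_squared, f$half_gaussian$adj_r_squared)
  # half-Gaussian data: sigma within 3%, half-Gaussian wins
  set.seed(2)
  v2 <- abs(rnorm(1e5, sd = 25))
  f2 <- fit_increment_tails(v2)
  expect_equal(unname(f2$half_gaussian$params["sigma"]), 25, tolerance = 0.03)
  expect_gt(f2$half_gaussian$adj_r_squared, f2$exponential$adj_r_squared)
  expect_error(fit_increment_tails(rep(1, 100)), "degenerate")
  expect_error(fit_increment_tails(c(-1, v[1:99])), ">= 0")
})

test_that("fitted tail models integrate to ~1 over the histogram support", {
  set.seed(5)
  v <- rexp(2e4, rate = 1 / 10)
  f <- fit_increment_tails(v)
  lam <- f$exponential$params["lambda"]
  sig <- f$half_gaussian$params["sigma"]
  xg <- seq(0, max(v), length.out = 1e5)
  int_exp <- sum(exp(-xg / lam) / lam) * diff(xg[1:2])
  int_hg <- sum(sqrt(2 / pi) / sig * exp(-xg^2 / (2 * sig^2))) * diff(xg[1:2])
  expect_equal(unname(int_exp), 1, tolerance = 0.05)
  expect_equal(unname(int_hg), 1, tolerance = 0.05)
})

test_that("MLE route gives the closed-form estimates", {
  set.seed(9)
  v <- rexp(5000, 1 / 4)
  f <- fit_increment_tails(v, method = "mle")
  expect_equal(unname(f$exponential$params["lambda"]), mean(v))
  expect_equal(unname(f$half_gaussian$params["sigma"]), sqrt(mean(v^2)))
})

test_that("model selection is reliable across seeds (scaled-down property)", {
  wins <- vapply(1:20, function(sd) {
    set.seed(sd)
    f <- fit_increment_tails(rexp(1e4, 1 / 15))
    f$exponential$adj_r_squared > f$half_gaussian$adj_r_squared
  }, logical(1))
  expect_gte(sum(wins), 19)
})

test_that("compare_methods reports pooled Pearson correlation", {
  set.seed(4)
  a <- matrix(rnorm(60), 6, 10)
  self <- compare_methods(a, a)
  expect_equal(self$pearson_r, 1)
  expect_equal(compare_methods(a, -a)$pearson_r, -1)
  # noisy copy at known SNR: r ~ 1/sqrt(1 + 1/SNR^2), and matches naive loop
  b <- a + matrix(rnorm(60, sd = 0.5), 6, 10)
  got <- compare_methods(a, b, variable = "mean_X")
  av <- as.vector(a); bv <- as.vector(b)
  num <- sum((av - mean(av)) * (bv - mean(bv)))
  den <- sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(got$pearson_r, num / den)
  expect_equal(got$variable, "mean_X")
  expect_error(compare_methods(a, a[, 1:3]), "identical shapes")
  expect_error(compare_methods(rep(1, 5), 1:5), "zero variance")
})
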