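test_that("preprocess_config validates its parameters", {
  cfg <- preprocess_config()
  expect_equal(cfg$sg_window, 9L)
  expect_equal(cfg$sg_order, 2L)
  expect_error(preprocess_config(sg_window = 8), "odd")
  expect_error(preprocess_config(sg_window = 3, sg_order = 3), "sg_window > sg_order")
  expect_error(preprocess_config(airpls_lambda = 0), "> 0")
})

test_that("airPLS reproduces a pure baseline and preserves peaks", {
  # constant spectrum: the baseline is the signal itself
  s <- new_spectrum(1:300, rep(5, 300) + 0)
  res <- baseline_airpls(s)
  expect_lt(max(abs(res$corrected$intensity)), 1e-6 * 5)
  expect_equal(res$corrected$intensity + res$baseline$intensity, s$intensity)

  # a single Gaussian on a zero baseline keeps its apex within 1%
  ax <- 1:500
  peak <- exp(-0.5 * ((ax - 250) / 10)^2)
  res2 <- baseline_airpls(new_spectrum(ax, peak))
  expect_lt(abs(max(res2$corrected$intensity) - 1), 0.01)

  # Gaussian + linear ramp: corrected matches the peak-only signal to 5% apex
  ramp <- 0.5 + 0.004 * ax
  res3 <- baseline_airpls(new_spectrum(ax, peak + ramp))
  expect_lt(max(abs(res3$corrected$intensity - peak)), 0.05)

  expect_error(baseline_airpls(s, lambda = -1), "lambda")
})

test_that("airPLS is approximately idempotent", {
  ax <- 1:500
  y <- exp(-0.5 * ((ax - 200) / 8)^2) + 0.8 * exp(-0.5 * ((ax - 350) / 12)^2) +
    0.3 + 0.002 * ax
  once <- baseline_airpls(new_spectrum(ax, y))$corrected
  twice <- baseline_airpls(once)$corrected
  apex <- max(once$intensity)
  expect_lt(max(abs(twice$intensity - once$intensity)), 0.01 * apex)
})

test_that("Savitzky-Golay smoothing reproduces polynomials and damps noise", {
  ax <- 1:200
  quad <- new_spectrum(ax, 3 + 0.5 * ax - 0.01 * ax^2)
  expect_equal(smooth_savgol(quad, 9, 2)$intensity, quad$intensity,
               tolerance = 1e-10)

  set.seed(5)
  noisy <- new_spectrum(ax, rnorm(200))
  sm <- smooth_savgol(noisy, 9, 2)
  expect_lt(var(sm$intensity), var(noisy$intensity))

  expect_error(smooth_savgol(noisy, 4, 2), "odd")
  expect_error(smooth_savgol(noisy, 5, 5), "exceed")
  expect_error(smooth_savgol(new_spectrum(1:4, 1:4), 9, 2), "length")
})

test_that("average_replicates takes the pointwise mean", {
  a <- new_spectrum(1:2, c(0, 2))
  b <- new_spectrum(1:2, c(2, 0))
  expect_equal(average_replicates(list(a, b))$intensity, c(1, 1))
  expect_equal(average_replicates(list(a))$intensity, a$intensity)
  expect_error(average_replicates(list(a, new_spectrum(2:3, c(1, 1)))),
               "identical axis")
  expect_error(average_replicates(list()), "at least one")

  # averaging n noisy copies shrinks the error roughly by sqrt(n)
  truth <- toy_spectrum()
  set.seed(9)
  reps <- lapply(1:6, function(i)
    new_spectrum(truth$axis, truth$intensity + rnorm(length(truth$axis), sd = 0.1)))
  avg <- average_replicates(reps)
  rmse <- sqrt(mean((avg$intensity - truth$intensity)^2))
  expect_lt(rmse, 0.1 / sqrt(6) * 1.5)
})

test_that("screen_outliers drops replicates uncorrelated with the median", {
  base <- toy_spectrum()
  six <- replicate(6, base, simplify = FALSE)
  res <- screen_outliers(six)
  expect_length(res$kept, 6)
  expect_length(res$dropped, 0)

  # a sign-flipped replicate correlates at -1 and is dropped
  flipped <- new_spectrum(base$axis, -base$intensity)
  res2 <- screen_outliers(c(six[1:5], list(flipped)))
  expect_length(res2$kept, 5)
  expect_length(res2$dropped, 1)
  expect_equal(res2$dropped[[1]]$intensity, flipped$intensity)

  # a spurious giant artifact peak pushes r below 0.95
  set.seed(21)
  noisy <- lapply(1:5, function(i)
    new_spectrum(base$axis, base$intensity + rnorm(length(base$axis), sd = 0.02)))
  spiky <- noisy[[1]]
  spiky$intensity[50:70] <- spiky$intensity[50:70] + 8
  res3 <- screen_outliers(c(noisy, list(spiky)), min_r = 0.95)
  expect_length(res3$dropped, 1)
  expect_equal(res3$dropped[[1]]$intensity, spiky$intensity)

  # never drops more than half
  res4 <- screen_outliers(c(six[1:3], list(flipped, flipped, flipped)))
  expect_gte(length(res4$kept), 3)

  # fewer than 3 replicates pass through with a warning
  expect_warning(res5 <- screen_outliers(six[1:2]), "skipped")
  expect_length(res5$kept, 2)
})

test_that("normalize_spectrum scales to [0, 1] and errors on constants", {
  s <- new_spectrum(1:3, c(1, 3, 5))
  expect_equal(normalize_spectrum(s)$intensity, c(0, 0.5, 1))

  # idempotent on already-normalized input
  n1 <- normalize_spectrum(toy_spectrum())
  expect_equal(normalize_spectrum(n1)$intensity, n1$intensity)
  expect_equal(range(n1$intensity), c(0, 1))

  u <- normalize_spectrum(s, method = "unit")
  expect_equal(sum(u$intensity^2), 1)

  expect_error(normalize_spectrum(new_spectrum(1:3, rep(2, 3))), "constant")
})

test_that("the preprocessing chain composes and preserves axis order", {
  fx <- synthetic_fixture("identity", seed = 4)
  reps <- make_replicates(fx$spec, 6)
  out <- preprocess_replicates(reps, preprocess_config())
  expect_s3_class(out, "raman_spectrum")
  expect_true(all(diff(out$axis) > 0))
  expect_true(all(out$axis >= 300 & out$axis <= 1700))
})
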