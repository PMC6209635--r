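test_that("window_config validates its geometry", {
  cfg <- window_config()
  expect_equal(cfg$window, 70L)
  expect_equal(cfg$max_lag, 23L)
  expect_error(window_config(window = 3), "window")
  expect_error(window_config(hop = 0), "hop")
  expect_error(window_config(hop = 80), "hop")
  expect_error(window_config(max_lag = 70), "max_lag")
})

test_that("identical spectra give an all-zero shift matrix", {
  fx <- synthetic_fixture("identity", seed = 2, noise_sd = 0)
  s <- fx$pair$primary
  m <- build_shift_matrix(spectrum_pair(s, s))
  expect_true(all(m$lags[!is.na(m$lags)] == 0L))
  expect_error(build_shift_matrix(spectrum_pair(
    new_spectrum(1:10, rnorm(10)), new_spectrum(1:10, rnorm(10)))),
    "shorter than the window")
})

test_that("a global displacement fills every informative column unanimously", {
  # noiseless constructed displacement: every kept window sees the truth
  fx0 <- synthetic_fixture("global-small", seed = 2, noise_sd = 0)
  m0 <- build_shift_matrix(fx0$pair)
  expect_true(all(m0$lags[!is.na(m0$lags)] == 5L))

  # with noise, a column under a band apex still collects only the truth
  fx <- synthetic_fixture("global-small", seed = 2, noise_sd = 0.01)
  m <- build_shift_matrix(fx$pair)
  apex_idx <- which.max(fx$pair$primary$intensity)
  cl <- column_lags(m, apex_idx)
  expect_true(length(cl) > 30)
  expect_true(all(cl == 5L))
})

test_that("column modes follow the majority with spec'd tie-breaks", {
  # unanimous column {5,5,5} -> 5
  m1 <- structure(list(starts = 1:3, lags = c(5L, 5L, 5L), window = 4L,
                       n = 6L, max_lag = 10L, hop = 1L),
                  class = "shift_matrix")
  expect_identical(column_lags(m1, 4L), c(5L, 5L, 5L))
  expect_true(all(profile_from_matrix(m1)$shift == 5L))

  # majority column {2,2,8} -> 2
  m2 <- structure(list(starts = 1:3, lags = c(2L, 2L, 8L), window = 4L,
                       n = 6L, max_lag = 10L, hop = 1L),
                  class = "shift_matrix")
  expect_identical(sort(column_lags(m2, 4L)), c(2L, 2L, 8L))
  expect_true(all(profile_from_matrix(m2)$shift == 2L))

  # all-empty matrix errors
  m3 <- structure(list(starts = 1:3, lags = rep(NA_integer_, 3), window = 4L,
                       n = 6L, max_lag = 10L, hop = 1L),
                  class = "shift_matrix")
  expect_error(profile_from_matrix(m3), "empty")
})

test_that("change points are discontinuities after flicker suppression", {
  expect_identical(find_change_points(shift_profile(rep(2L, 10))), integer(0))
  # single discontinuity: first index of the new regime
  expect_identical(find_change_points(shift_profile(c(2L, 2L, 2L, 8L, 8L))), 4L)
  # an isolated one-point flicker is removed by the width-5 median filter
  expect_identical(find_change_points(shift_profile(c(2L, 2L, 8L, 2L, 2L))),
                   integer(0))
})

test_that("change points relocate to the nearest valley of the secondary", {
  n <- 100L
  p <- shift_profile(rep(c(0L, 3L), c(49L, 51L)))  # change point at 50
  # double-well intensity: local minima at 44 and 62, apex between
  i <- 1:n
  y <- ((i - 44)^2) * ((i - 62)^2) / 1e5
  s <- new_spectrum(i, y)
  p2 <- relocate_change_points(p, s)
  expect_identical(p2$change_points, 44L)
  expect_identical(p2$shift, rep(c(0L, 3L), c(43L, 57L)))

  # already at a valley: unchanged
  p3 <- shift_profile(rep(c(0L, 3L), c(43L, 57L)))
  expect_identical(relocate_change_points(p3, s)$change_points, 44L)

  # flat spectrum: no valley, position stands and is flagged
  flat <- new_spectrum(i, rep(1, n))
  p4 <- relocate_change_points(p, flat)
  expect_identical(p4$change_points, 50L)
  expect_identical(p4$diagnostics$unrelocated, 50L)
})

test_that("synchronize translates regions and keeps N fixed", {
  fx <- synthetic_fixture("identity", seed = 5)
  pair <- fx$pair
  out <- synchronize(pair, shift_profile(rep(0L, 2048)))
  expect_identical(out$intensity, pair$secondary$intensity)

  # a recovered global shift reproduces the unwarped signal bit-for-bit
  spec <- synth_spec(peaks = data.frame(center = seq(400, 2400, by = 200),
                                        height = 1, width = 5),
                     warp = list(type = "regions", breaks = integer(0),
                                 shifts = 5L))
  g <- make_pair(spec)   # noiseless
  out2 <- synchronize(g$pair, g$truth)
  n <- length(out2$intensity)
  expect_identical(out2$intensity[1:(n - 5)], g$clean[1:(n - 5)])

  # a shift as large as its region is rejected
  bad <- shift_profile(rep(c(0L, 12L, 0L), c(1000L, 5L, 1043L)))
  expect_error(synchronize(fx$pair, bad), "exceeds region")
  expect_error(synchronize(fx$pair, shift_profile(rep(0L, 10))), "length")
})

test_that("with one global window MWFFT reduces to the global lag estimate", {
  fx <- synthetic_fixture("global-small", seed = 6, noise_sd = 0.01)
  pair <- fx$pair
  N <- length(pair$primary$axis)
  cfg <- window_config(window = N, hop = N, max_lag = 128L)
  prof <- profile_from_matrix(build_shift_matrix(pair, cfg))
  global <- estimate_lag(pair$primary$intensity, pair$secondary$intensity, 128L)
  expect_true(all(prof$shift == global))
  expect_equal(global, 5L)
})

test_that("an identical pair passes through mwfft_correct untouched", {
  s <- synthetic_fixture("identity", seed = 7)$pair$primary
  res <- mwfft_correct(spectrum_pair(s, s))
  expect_identical(res$corrected$intensity, s$intensity)
  expect_length(res$profile$change_points, 0)
  expect_equal(res$report$r, 1)
  expect_equal(res$report$R, 1)
  expect_true(res$report$passed)
  expect_equal(res$report$d_mean_after, 0)
})

test_that("region interiors are copied without resampling (shape preservation)", {
  fx <- synthetic_fixture("two-regime", seed = 1)
  pair <- workflow_pair(fx)
  res <- mwfft_correct(pair)
  sec <- pair$secondary$intensity
  out <- res$corrected$intensity
  N <- length(out)
  cps <- c(res$profile$change_points, fx$truth$change_points)
  for (i in seq(100, N - 100, by = 7)) {
    k <- res$profile$shift[i]
    if (k != fx$truth$shift[i]) next
    if (length(cps) && min(abs(i - cps)) <= 70) next
    if (i + k >= 1 && i + k <= N)
      expect_identical(out[i], sec[i + k])
  }
})

test_that("correction improves similarity on warped pairs", {
  for (sd in 1:5) {
    fx <- synthetic_fixture("two-regime", seed = sd)
    res <- mwfft_correct(workflow_pair(fx))
    expect_gt(res$report$R, res$report$r)
    expect_lt(res$report$d_mean_after, res$report$d_mean_before)
  }
})
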