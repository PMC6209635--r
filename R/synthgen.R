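#' Specification of a synthetic Raman spectrum (pair)
#'
#' Describes a synthetic acquisition: a 2048-point axis over 175-2700
#' cm^-1 by default (a typical portable-spectrometer CCD and range), a
#' set of band profiles, a polynomial baseline, additive Gaussian noise,
#' and an optional ground-truth warp used by [make_pair()].
#'
#' @param n_points Axis length (default 2048).
#' @param axis_range Axis range in cm^-1 (default `c(175, 2700)`).
#' @param peaks data.frame with columns `center` (cm^-1), `height`,
#'   `width` (Gaussian sd or Lorentzian half-width, cm^-1), and
#'   optionally `shape` (`"gaussian"` default, or `"lorentzian"`).
#' @param baseline Polynomial coefficients (increasing powers of the
#'   axis); default 0.
#' @param noise_sd Additive Gaussian noise sd; default 0. The
#'   signal-to-noise ratio is the tallest peak height over `noise_sd`.
#' @param warp `NULL`, or `list(type = "regions", breaks =, shifts =)`
#'   for a piecewise-constant integer point-shift (breaks are the 1-based
#'   first indices of the 2nd..last regions; shifts has one entry per
#'   region), or `list(type = "linear", intercept =, slope =)` for a
#'   displacement in cm^-1, `d(x) = intercept + slope * x`.
#' @param seed RNG seed for the noise (default 1).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_points = 2048L, axis_range = c(175, 2700),
                       peaks = NULL, baseline = 0, noise_sd = 0,
                       warp = NULL, seed = 1L) {
  n_points <- as.integer(n_points)
  stopifnot(n_points >= 2L, axis_range[1] < axis_range[2], noise_sd >= 0)
  if (!is.null(peaks)) {
    if (is.null(peaks$shape)) peaks$shape <- "gaussian"
    if (any(peaks$center < axis_range[1] | peaks$center > axis_range[2]))
      stop("peak centers must lie inside the axis range", call. = FALSE)
    stopifnot(all(peaks$width > 0))
  }
  if (!is.null(warp)) {
    if (identical(warp$type, "regions")) {
      breaks <- as.integer(warp$breaks)
      shifts <- as.integer(warp$shifts)
      if (length(shifts) != length(breaks) + 1L)
        stop("need one shift per region (length(breaks) + 1)", call. = FALSE)
      if (is.unsorted(breaks, strictly = TRUE) ||
          any(breaks < 2L) || any(breaks > n_points))
        stop("breaks must be strictly increasing inside the axis", call. = FALSE)
      min_region <- 2L * (if (is.null(warp$window)) 70L else as.integer(warp$window))
      lens <- diff(c(1L, breaks, n_points + 1L))
      if (any(lens < min_region))
        stop(sprintf("warp regions must each span >= %d points", min_region),
             call. = FALSE)
      warp$breaks <- breaks; warp$shifts <- shifts
    } else if (!identical(warp$type, "linear")) {
      stop("warp$type must be 'regions' or 'linear'", call. = FALSE)
    }
  }
  structure(list(n_points = n_points, axis_range = axis_range,
                 peaks = peaks, baseline = baseline, noise_sd = noise_sd,
                 warp = warp, seed = as.integer(seed)),
            class = "synth_spec")
}

synth_axis <- function(spec)
  seq(spec$axis_range[1], spec$axis_range[2], length.out = spec$n_points)

peak_signal <- function(axis, peaks) {
  y <- numeric(length(axis))
  if (is.null(peaks)) return(y)
  for (k in seq_len(nrow(peaks))) {
    c0 <- peaks$center[k]; h <- peaks$height[k]; w <- peaks$width[k]
    y <- y + if (identical(peaks$shape[k], "lorentzian"))
      h * w^2 / ((axis - c0)^2 + w^2)
    else
      h * exp(-0.5 * ((axis - c0) / w)^2)
  }
  y
}

clean_intensity <- function(spec) {
  axis <- synth_axis(spec)
  y <- peak_signal(axis, spec$peaks)
  for (p in seq_along(spec$baseline))
    y <- y + spec$baseline[p] * axis^(p - 1L)
  y
}

#' Render a synthetic spectrum
#'
#' Sum of the band profiles, the polynomial baseline, and seeded
#' Gaussian noise. Deterministic given the spec's seed.
#'
#' @param spec A [synth_spec()].
#' @return A `raman_spectrum`.
#' @export
make_spectrum <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  y <- clean_intensity(spec)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    y <- y + stats::rnorm(spec$n_points, sd = spec$noise_sd)
  }
  new_spectrum(synth_axis(spec), y,
               list(synthetic = TRUE, seed = spec$seed))
}

# ground-truth per-point shift vector of a regions warp
warp_shift_vector <- function(spec) {
  w <- spec$warp
  if (is.null(w)) return(rep(0L, spec$n_points))
  stopifnot(identical(w$type, "regions"))
  rep(w$shifts, diff(c(1L, w$breaks, spec$n_points + 1L)))
}

# translate each region of y by its shift (+k = toward higher index),
# clipping source indices to the ends (endpoint fill)
apply_region_warp <- function(y, shift) {
  n <- length(y)
  src <- pmin(pmax(seq_len(n) - shift, 1L), n)
  y[src]
}

#' Generate a primary/secondary pair with a known warp
#'
#' The primary spectrum is the unwarped signal plus seeded noise; the
#' secondary is the warped signal (each constant-shift region translated
#' by its ground-truth shift, ends held) plus independent seeded noise.
#' For a linear warp the clean signal is evaluated at `x - d(x)` instead.
#' The true shift profile (or linear model) is returned for recovery
#' tests.
#'
#' @param spec A [synth_spec()] with a `warp` (use zero shifts for an
#'   identity pair).
#' @return List with `pair` (a [spectrum_pair()]), `truth` (a
#'   [shift_profile()] for region warps, or the linear warp list), and
#'   `clean` (the noise-free unwarped intensity).
#' @export
make_pair <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  axis <- synth_axis(spec)
  clean <- clean_intensity(spec)
  w <- spec$warp
  if (!is.null(w) && identical(w$type, "linear")) {
    d <- w$intercept + w$slope * axis
    warped <- stats::approx(axis, clean, xout = axis - d, rule = 2)$y
    truth <- w
  } else {
    sh <- warp_shift_vector(spec)
    warped <- apply_region_warp(clean, sh)
    truth <- shift_profile(sh)
  }
  set.seed(spec$seed)
  y_p <- clean + if (spec$noise_sd > 0)
    stats::rnorm(spec$n_points, sd = spec$noise_sd) else 0
  set.seed(spec$seed + 1L)
  y_s <- warped + if (spec$noise_sd > 0)
    stats::rnorm(spec$n_points, sd = spec$noise_sd) else 0
  primary <- new_spectrum(axis, y_p, list(synthetic = TRUE, role = "primary"))
  secondary <- new_spectrum(axis, y_s, list(synthetic = TRUE, role = "secondary"))
  list(pair = spectrum_pair(primary, secondary), truth = truth,
       clean = clean)
}

#' Generate replicate acquisitions of one synthetic sample
#'
#' Same clean signal (optionally warped), independent noise per
#' replicate with seeds `seed, seed + 1, ...`.
#'
#' @param spec A [synth_spec()].
#' @param n Number of replicates (default 6, the usual acquisition
#'   scheme).
#' @param warped Render the warped (secondary-instrument) signal.
#' @param seed_offset Added to the spec's seed so the two instruments'
#'   replicate sets carry independent noise (use e.g. 0 for the primary
#'   and `n` for the secondary).
#' @return List of `raman_spectrum`s.
#' @export
make_replicates <- function(spec, n = 6L, warped = FALSE, seed_offset = 0L) {
  axis <- synth_axis(spec)
  y0 <- clean_intensity(spec)
  if (warped) y0 <- apply_region_warp(y0, warp_shift_vector(spec))
  lapply(seq_len(n), function(i) {
    set.seed(spec$seed + seed_offset + i - 1L)
    y <- y0 + if (spec$noise_sd > 0)
      stats::rnorm(spec$n_points, sd = spec$noise_sd) else 0
    new_spectrum(axis, y, list(synthetic = TRUE, replicate = i))
  })
}

# deterministic random band set: >= n_per_region peaks in each warp
# region, kept clear of region boundaries and spectrum ends. One band is
# placed within about a window-width on each side of every regime
# boundary: a change point is only identifiable where signal exists near
# it, and physically a shift regime cannot change in the middle of a band
seeded_peaks <- function(axis, breaks, n_points, n_per_region = 12L,
                         seed = 1L, margin_pts = 25L) {
  set.seed(seed)
  step <- (axis[length(axis)] - axis[1]) / (n_points - 1L)
  margin <- margin_pts * step
  bounds <- c(1L, breaks, n_points + 1L)
  centers <- numeric(0)
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- axis[bounds[k]] + margin
    hi <- axis[bounds[k + 1L] - 1L] - margin
    ct <- stats::runif(n_per_region - 2L, lo, hi)
    # flanking bands near the region edges (25-60 points away)
    ct <- c(ct, lo + stats::runif(1, 0, 35L * step),
            hi - stats::runif(1, 0, 35L * step))
    centers <- c(centers, sort(ct))
  }
  h <- stats::runif(length(centers), 0.4, 1)
  h <- h / max(h)                       # tallest band defines SNR
  data.frame(center = centers, height = h,
             width = stats::runif(length(centers), 3, 7),
             shape = "gaussian")
}

#' Named synthetic fixture battery
#'
#' Deterministic study-condition fixtures covering the cases the method
#' must handle: an identity pair, small and large global displacements,
#' and two- and three-regime non-linear warps (the latter on a sloped
#' baseline). All use the 2048-point, 175-2700 cm^-1 axis, 12 Gaussian
#' bands per warp region with the tallest apex at 1, and noise sd 0.05
#' (SNR 20).
#'
#' @param name One of `"identity"`, `"global-small"`, `"global-90"`,
#'   `"two-regime"`, `"three-regime-sloped"`.
#' @param seed Seed controlling band placement and noise (default 1).
#' @param noise_sd Noise level (default 0.05).
#' @return As [make_pair()], plus the `spec` used.
#' @export
synthetic_fixture <- function(name = c("identity", "global-small",
                                       "global-90", "two-regime",
                                       "three-regime-sloped"),
                              seed = 1L, noise_sd = 0.05) {
  name <- match.arg(name)
  n <- 2048L
  cfgs <- list(
    "identity"     = list(breaks = integer(0), shifts = 0L, base = 0),
    "global-small" = list(breaks = integer(0), shifts = 5L, base = 0),
    "global-90"    = list(breaks = integer(0), shifts = 90L, base = 0),
    "two-regime"   = list(breaks = 1025L, shifts = c(2L, 8L), base = 0),
    "three-regime-sloped" = list(breaks = c(700L, 1400L),
                                 shifts = c(4L, -6L, 10L),
                                 base = c(0.15, 1e-4))
  )
  cfg <- cfgs[[name]]
  axis <- seq(175, 2700, length.out = n)
  peaks <- seeded_peaks(axis, cfg$breaks, n, n_per_region = 12L, seed = seed)
  spec <- synth_spec(n_points = n, axis_range = c(175, 2700), peaks = peaks,
                     baseline = cfg$base, noise_sd = noise_sd,
                     warp = list(type = "regions", breaks = cfg$breaks,
                                 shifts = cfg$shifts),
                     seed = seed * 101L)
  c(make_pair(spec), list(spec = spec))
}
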