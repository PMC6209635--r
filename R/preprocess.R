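#' Preprocessing configuration
#'
#' Bundles the parameters of the standard preprocessing chain applied
#' before shift estimation and metric computation.
#'
#' @param sg_window Savitzky-Golay window, odd point count (default 9).
#' @param sg_order Savitzky-Golay polynomial order (default 2).
#' @param airpls_lambda Whittaker smoothness penalty (default 1e5).
#' @param airpls_maxiter airPLS iteration cap (default 15).
#' @param crop_lo,crop_hi Working region in cm^-1 (defaults 300, 1700).
#' @param outlier_min_r Replicate-correlation threshold below which a
#'   replicate is screened out (default 0.95).
#' @param normalization `"minmax"` (default) or `"unit"` (unit-vector).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window = 9L, sg_order = 2L,
                              airpls_lambda = 1e5, airpls_maxiter = 15L,
                              crop_lo = 300, crop_hi = 1700,
                              outlier_min_r = 0.95,
                              normalization = c("minmax", "unit")) {
  sg_window <- as.integer(sg_window); sg_order <- as.integer(sg_order)
  if (sg_window %% 2L == 0L) stop("sg_window must be odd", call. = FALSE)
  if (!(sg_window > sg_order && sg_order >= 1L))
    stop("need sg_window > sg_order >= 1", call. = FALSE)
  if (airpls_lambda <= 0) stop("airpls_lambda must be > 0", call. = FALSE)
  structure(list(sg_window = sg_window, sg_order = sg_order,
                 airpls_lambda = airpls_lambda,
                 airpls_maxiter = as.integer(airpls_maxiter),
                 crop_lo = crop_lo, crop_hi = crop_hi,
                 outlier_min_r = outlier_min_r,
                 normalization = match.arg(normalization)),
            class = "preprocess_config")
}

# Whittaker smoother: minimize ||W^(1/2)(x - z)||^2 + lambda ||D2 z||^2,
# solved as a sparse banded system.
whittaker_smooth <- function(x, w, lambda) {
  n <- length(x)
  D <- Matrix::bandSparse(n - 2L, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2L),
                                           rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  A <- Matrix::Diagonal(n, w) + lambda * Matrix::crossprod(D)
  as.numeric(Matrix::solve(A, w * x))
}

#' airPLS baseline correction
#'
#' Estimates a slowly varying background (fluorescence and detector
#' drift) with adaptive iteratively reweighted penalized least squares:
#' repeated Whittaker smoothing where points lying above the current
#' baseline estimate are given zero weight and points below are
#' up-weighted exponentially by iteration. Iteration stops when the sum
#' of the negative-residual magnitudes falls below 0.1% of the total
#' signal magnitude, or at `maxiter`.
#'
#' @param s A `raman_spectrum`.
#' @param lambda Smoothness penalty (> 0); larger gives a stiffer
#'   baseline. Default 1e5.
#' @param maxiter Iteration cap, default 15.
#' @return A list with `corrected` and `baseline`, both `raman_spectrum`s
#'   on the input axis, satisfying
#'   `corrected$intensity == s$intensity - baseline$intensity`.
#' @references Zhang, Chen and Liang (2010), Analyst 135, 1138-1146.
#' @export
baseline_airpls <- function(s, lambda = 1e5, maxiter = 15L) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  x <- s$intensity
  n <- length(x)
  w <- rep(1, n)
  z <- x
  total <- sum(abs(x))
  for (t in seq_len(maxiter)) {
    z <- whittaker_smooth(x, w, lambda)
    d <- x - z
    neg <- d < 0
    dssn <- sum(abs(d[neg]))
    if (dssn < 0.001 * total || !any(neg)) break
    w[!neg] <- 0
    w[neg] <- exp(t * abs(d[neg]) / dssn)
    # pin the two ends so the baseline cannot peel away there
    w[1] <- exp(t * max(abs(d[neg])) / dssn)
    w[n] <- w[1]
  }
  meta <- s$meta
  meta$baseline <- "airPLS"
  list(
    corrected = structure(list(axis = s$axis, intensity = x - z, meta = meta),
                          class = "raman_spectrum"),
    baseline = structure(list(axis = s$axis, intensity = z, meta = s$meta),
                         class = "raman_spectrum")
  )
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing; the 9-point, second-order
#' configuration is the default used throughout the pipeline.
#'
#' @param s A `raman_spectrum`.
#' @param window Odd window width in points (default 9).
#' @param order Polynomial order, `order < window` (default 2).
#' @return Smoothed `raman_spectrum`, same length.
#' @export
smooth_savgol <- function(s, window = 9L, order = 2L) {
  stopifnot(inherits(s, "raman_spectrum"))
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (window <= order) stop("window must exceed order", call. = FALSE)
  if (window > length(s$axis))
    stop("window exceeds spectrum length", call. = FALSE)
  y <- signal::sgolayfilt(s$intensity, p = order, n = window)
  structure(list(axis = s$axis, intensity = y, meta = s$meta),
            class = "raman_spectrum")
}

#' Average replicate spectra
#'
#' Pointwise mean intensity across replicates on an identical axis; the
#' averaged spectrum of the primary instrument is the usual reference.
#'
#' @param replicates List of `raman_spectrum`s with identical axes.
#' @return A `raman_spectrum` with the mean intensity.
#' @export
average_replicates <- function(replicates) {
  if (length(replicates) < 1L) stop("need at least one replicate", call. = FALSE)
  ax <- replicates[[1]]$axis
  for (r in replicates)
    if (!identical(r$axis, ax))
      stop("replicates must share an identical axis", call. = FALSE)
  m <- rowMeans(vapply(replicates, function(r) r$intensity,
                       numeric(length(ax))))
  new_spectrum(ax, m, list(n_replicates = length(replicates)))
}

#' Screen replicate spectra for outliers
#'
#' Drops any replicate whose Pearson correlation with the median
#' spectrum of the remaining replicates falls below `min_r`. With fewer
#' than three replicates screening does not apply and all are kept. At
#' most half of the replicates are ever dropped (worst first).
#'
#' @param replicates List of `raman_spectrum`s with identical axes.
#' @param min_r Correlation threshold, default 0.95.
#' @return List with `kept` and `dropped` lists of spectra.
#' @export
screen_outliers <- function(replicates, min_r = 0.95) {
  n <- length(replicates)
  if (n < 3L) {
    if (n > 0L) warning("fewer than 3 replicates; screening skipped")
    return(list(kept = replicates, dropped = list()))
  }
  ax <- replicates[[1]]$axis
  Y <- vapply(replicates, function(r) r$intensity, numeric(length(ax)))
  max_drop <- n %/% 2L
  keep <- rep(TRUE, n)
  repeat {
    idx <- which(keep)
    r_med <- numeric(n)
    r_med[] <- NA_real_
    for (i in idx) {
      others <- setdiff(idx, i)
      med <- apply(Y[, others, drop = FALSE], 1L, stats::median)
      r <- suppressWarnings(stats::cor(Y[, i], med))
      r_med[i] <- if (is.na(r)) 0 else  # constant median: no evidence
        r
    }
    worst <- idx[which.min(r_med[idx])]
    if (r_med[worst] >= min_r || sum(!keep) >= max_drop) break
    keep[worst] <- FALSE
  }
  list(kept = replicates[keep], dropped = replicates[!keep])
}

#' Normalize a spectrum's intensity
#'
#' Min-max scaling to \[0, 1\] (default) or unit-vector scaling. Applied
#' before Euclidean-distance comparisons, which are scale-sensitive;
#' correlation coefficients do not need it.
#'
#' @param s A `raman_spectrum`.
#' @param method `"minmax"` or `"unit"`.
#' @return Normalized `raman_spectrum`.
#' @export
normalize_spectrum <- function(s, method = c("minmax", "unit")) {
  stopifnot(inherits(s, "raman_spectrum"))
  method <- match.arg(method)
  y <- s$intensity
  rng <- range(y)
  if (rng[1] == rng[2])
    stop("cannot normalize a constant spectrum", call. = FALSE)
  y <- switch(method,
              minmax = (y - rng[1]) / (rng[2] - rng[1]),
              unit = y / sqrt(sum(y^2)))
  structure(list(axis = s$axis, intensity = y, meta = s$meta),
            class = "raman_spectrum")
}

#' Run the standard preprocessing chain on one replicate set
#'
#' Outlier screen, replicate average, airPLS baseline correction,
#' Savitzky-Golay smoothing, and crop to the working region, in that
#' order.
#'
#' @param replicates List of `raman_spectrum`s on one axis.
#' @param cfg A [preprocess_config()].
#' @return A preprocessed `raman_spectrum`.
#' @export
preprocess_replicates <- function(replicates, cfg = preprocess_config()) {
  scr <- screen_outliers(replicates, cfg$outlier_min_r)
  avg <- average_replicates(scr$kept)
  bl <- baseline_airpls(avg, cfg$airpls_lambda, cfg$airpls_maxiter)
  sm <- smooth_savgol(bl$corrected, cfg$sg_window, cfg$sg_order)
  crop_spectrum(sm, cfg$crop_lo, cfg$crop_hi)
}
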