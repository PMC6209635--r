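#' Reference peak positions of chemical shift standards
#'
#' Certified Raman shift positions (ASTM E1840-96) of acetaminophen
#' (4-acetamidophenol) and cyclohexane, the usual pair of shift
#' standards: together they cover the 300-1700 cm^-1 working region
#' densely. Shipped as a plain-text table in `extdata`.
#'
#' @param path Optional path to a CSV with columns `compound`, `shift`,
#'   `sd`; defaults to the packaged table.
#' @return A data.frame of class `standard_peak_table` with columns
#'   `compound` (character), `shift` (cm^-1), `sd` (cm^-1).
#' @export
standard_peak_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "standard_raman_shifts.csv",
                        package = "ramansync", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "shift", "sd")
  if (!all(need %in% names(tab)))
    stop("standard table needs columns compound, shift, sd", call. = FALSE)
  if (anyDuplicated(tab[c("compound", "shift")]))
    stop("duplicated reference shift within a compound", call. = FALSE)
  class(tab) <- c("standard_peak_table", "data.frame")
  tab
}

#' Match standard peaks in a measured spectrum
#'
#' For each reference position in the table, finds the local intensity
#' maximum within `+/- tol` and refines the apex with a 3-point
#' parabolic fit. Entries with no interior local maximum in range are
#' omitted. The spectrum should be baseline-corrected and smoothed first.
#'
#' @param s A preprocessed `raman_spectrum`.
#' @param expected A [standard_peak_table()] (or data.frame with a
#'   `shift` column).
#' @param tol Matching half-window in cm^-1 (default 10, about 3x the
#'   typical system resolution).
#' @return data.frame with columns `reference` and `measured` (cm^-1),
#'   one row per matched peak.
#' @export
pick_peaks <- function(s, expected, tol = 10) {
  stopifnot(inherits(s, "raman_spectrum"))
  refs <- expected$shift
  x <- s$axis; y <- s$intensity
  N <- length(x)
  out_ref <- numeric(0); out_meas <- numeric(0)
  for (r0 in refs) {
    ii <- which(x >= r0 - tol & x <= r0 + tol)
    ii <- ii[ii > 1L & ii < N]           # need both neighbours
    if (length(ii) == 0L) next
    is_max <- y[ii] >= y[ii - 1L] & y[ii] >= y[ii + 1L] &
      (y[ii] > y[ii - 1L] | y[ii] > y[ii + 1L])
    cand <- ii[is_max]
    if (!length(cand)) next
    i <- cand[which.max(y[cand])]
    # parabola through (i-1, i, i+1); vertex offset in index units
    y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (denom < 0) 0.5 * (y1 - y3) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    step <- (x[i + 1L] - x[i - 1L]) / 2
    out_ref <- c(out_ref, r0)
    out_meas <- c(out_meas, x[i] + delta * step)
  }
  if (length(out_ref) < 2L)
    stop("fewer than 2 standard peaks matched", call. = FALSE)
  data.frame(reference = out_ref, measured = out_meas)
}

#' Fit a linear shift-displacement model
#'
#' Ordinary least squares of the displacement (measured - reference)
#' against the reference position, giving
#' `displacement(x) = intercept + slope * x`.
#'
#' @param pairs data.frame with columns `reference` and `measured`
#'   (from [pick_peaks()]).
#' @return An object of class `linear_shift_model` with `slope`,
#'   `intercept`, `residuals`, `n_peaks`.
#' @export
fit_shift_model <- function(pairs) {
  if (nrow(pairs) < 2L)
    stop("need at least 2 matched peaks", call. = FALSE)
  if (length(unique(pairs$reference)) < 2L)
    stop("degenerate input: a single unique reference position", call. = FALSE)
  disp <- pairs$measured - pairs$reference
  fit <- stats::lm(disp ~ reference, data = pairs)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residuals = unname(stats::residuals(fit)),
                 n_peaks = nrow(pairs)),
            class = "linear_shift_model")
}

#' @export
print.linear_shift_model <- function(x, ...) {
  cat(sprintf("<linear_shift_model> displacement(x) = %.4g + %.4g * x (%d peaks, RMS resid %.3g cm^-1)\n",
              x$intercept, x$slope, x$n_peaks, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Apply a standard-scattering-shift correction
#'
#' Each axis value x is mapped to `x - displacement(x)` under the fitted
#' linear model, then the intensity is linearly re-interpolated onto the
#' master axis.
#'
#' @param s A `raman_spectrum` from the secondary instrument.
#' @param model A [fit_shift_model()] result.
#' @param master_axis Strictly increasing axis to interpolate onto
#'   (default: the spectrum's own axis).
#' @return The corrected `raman_spectrum` on `master_axis`.
#' @export
sss_correct <- function(s, model, master_axis = s$axis) {
  stopifnot(inherits(s, "raman_spectrum"),
            inherits(model, "linear_shift_model"))
  x_corr <- s$axis - (model$intercept + model$slope * s$axis)
  if (any(diff(x_corr) <= 0))
    stop("corrected axis is non-monotone (|slope| too large)", call. = FALSE)
  meta <- s$meta
  meta$sss_corrected <- TRUE
  resample_to_master(structure(list(axis = x_corr, intensity = s$intensity,
                                    meta = meta),
                               class = "raman_spectrum"),
                     master_axis)
}
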