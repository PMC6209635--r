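#' Correlation coefficient between two spectra
#'
#' Pearson coefficient of the intensity vectors on a common axis: the
#' similarity measure used before (r) and after (R) shift correction.
#' Scale- and offset-invariant, so no normalization is required.
#'
#' @param a,b `raman_spectrum`s on an identical axis.
#' @return A value in \[-1, 1\].
#' @export
spectral_correlation <- function(a, b) {
  stopifnot(inherits(a, "raman_spectrum"), inherits(b, "raman_spectrum"))
  if (!identical(a$axis, b$axis))
    stop("spectra must share a common axis", call. = FALSE)
  if (stats::var(a$intensity) == 0 || stats::var(b$intensity) == 0)
    stop("constant spectrum: correlation undefined", call. = FALSE)
  stats::cor(a$intensity, b$intensity)
}

#' Mean Euclidean distance between paired spectra
#'
#' `D_mean = (1/n) * sum_i sqrt(sum_j (P[i,j] - S[i,j])^2)` over `n`
#' primary/secondary pairs on a common k-point axis. Distances are
#' scale-sensitive: normalize the spectra first (see
#' [normalize_spectrum()]).
#'
#' @param primaries,others Equal-length lists of `raman_spectrum`s on one
#'   common axis.
#' @return Non-negative scalar.
#' @export
mean_euclidean_distance <- function(primaries, others) {
  if (length(primaries) != length(others) || length(primaries) == 0L)
    stop("need equal, non-zero numbers of spectra", call. = FALSE)
  ax <- primaries[[1]]$axis
  d <- vapply(seq_along(primaries), function(i) {
    p <- primaries[[i]]; s <- others[[i]]
    if (!identical(p$axis, ax) || !identical(s$axis, ax))
      stop("all spectra must share one common axis", call. = FALSE)
    sqrt(sum((p$intensity - s$intensity)^2))
  }, numeric(1))
  mean(d)
}

#' Evaluate synchronization quality of one pair
#'
#' Computes the pre-correction correlation r (primary vs secondary), the
#' post-correction correlation R (primary vs corrected), the mean
#' Euclidean distances before/after on min-max normalized copies, and a
#' pass flag (`R >= threshold`; 0.95 is the conventional hit-quality
#' pass cut-off).
#'
#' @param pair A [spectrum_pair()].
#' @param corrected The shift-corrected secondary `raman_spectrum`.
#' @param threshold Pass threshold, default 0.95.
#' @return An object of class `sync_report` with fields `r`, `R`,
#'   `d_mean_before`, `d_mean_after`, `passed`, `n_spectra`.
#' @export
evaluate_pair <- function(pair, corrected, threshold = 0.95) {
  stopifnot(inherits(pair, "spectrum_pair"))
  r <- spectral_correlation(pair$primary, pair$secondary)
  R <- spectral_correlation(pair$primary, corrected)
  np <- normalize_spectrum(pair$primary)
  d_before <- mean_euclidean_distance(list(np),
                                      list(normalize_spectrum(pair$secondary)))
  d_after <- mean_euclidean_distance(list(np),
                                     list(normalize_spectrum(corrected)))
  structure(list(r = r, R = R,
                 d_mean_before = d_before, d_mean_after = d_after,
                 passed = R >= threshold, threshold = threshold,
                 n_spectra = 1L),
            class = "sync_report")
}

#' @export
print.sync_report <- function(x, ...) {
  cat(sprintf("<sync_report> r = %.4f -> R = %.4f (%s at %.2f); D_mean %.4f -> %.4f\n",
              x$r, x$R, if (x$passed) "PASS" else "FAIL", x$threshold,
              x$d_mean_before, x$d_mean_after))
  invisible(x)
}
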