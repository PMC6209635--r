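#' Construct a Raman spectrum
#'
#' A `raman_spectrum` is the basic container of the package: a strictly
#' increasing Raman-shift axis (cm^-1) and an intensity vector of equal
#' length, plus free-form provenance metadata (instrument id, sample id,
#' replicate index, processing flags).
#'
#' @param axis Numeric vector of Raman shift values in cm^-1, strictly
#'   increasing, length >= 2.
#' @param intensity Numeric vector of detector counts (arbitrary units),
#'   same length as `axis`.
#' @param meta Named list of provenance fields.
#' @return An object of class `raman_spectrum`.
#' @export
new_spectrum <- function(axis, intensity, meta = list()) {
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  validate_spectrum_parts(axis, intensity)
  structure(list(axis = axis, intensity = intensity, meta = meta),
            class = "raman_spectrum")
}

validate_spectrum_parts <- function(axis, intensity) {
  if (length(axis) != length(intensity))
    stop("axis and intensity must have equal length", call. = FALSE)
  if (length(axis) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (anyNA(axis) || anyNA(intensity) ||
      any(!is.finite(axis)) || any(!is.finite(intensity)))
    stop("axis and intensity must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (any(diff(axis) <= 0))
    stop("axis must be strictly increasing", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f cm^-1\n",
              length(x$axis), x$axis[1], x$axis[length(x$axis)]))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Number of points in a spectrum
#' @param s A `raman_spectrum`.
#' @return Integer point count.
#' @export
n_points <- function(s) length(s$axis)

#' Read a spectrum from a two-column delimited text file
#'
#' Accepts comma- or tab-delimited text (autodetected unless `sep` is
#' given) with two numeric columns: Raman shift (cm^-1) and intensity.
#' Lines starting with the comment character are skipped; an optional
#' non-numeric header line is tolerated. Rows are sorted by axis;
#' duplicated axis values are rejected.
#'
#' @param path Path to the file.
#' @param sep Column separator; `NULL` (default) autodetects comma vs tab
#'   vs whitespace from the first data line.
#' @param comment_char Comment prefix, default `"#"`.
#' @param meta Extra metadata to attach.
#' @return A `raman_spectrum`.
#' @export
read_spectrum <- function(path, sep = NULL, comment_char = "#", meta = list()) {
  if (!file.exists(path))
    stop(sprintf("spectrum file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), comment_char) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L)
    stop(sprintf("%s: no data lines", path), call. = FALSE)
  if (is.null(sep)) {
    first <- lines[[1]]
    sep <- if (grepl(",", first, fixed = TRUE)) "," else
           if (grepl("\t", first, fixed = TRUE)) "\t" else ""
  }
  split1 <- if (identical(sep, "")) strsplit(trimws(lines), "[[:space:]]+")
            else strsplit(lines, sep, fixed = TRUE)
  ncols <- lengths(split1)
  bad <- which(ncols < 2L)
  if (length(bad))
    stop(sprintf("%s: line %d does not have two columns", path,
                 line_no[bad[1]]), call. = FALSE)
  ax <- suppressWarnings(as.numeric(vapply(split1, `[[`, "", 1L)))
  iy <- suppressWarnings(as.numeric(vapply(split1, `[[`, "", 2L)))
  # tolerate a single header line of column names
  if (is.na(ax[1]) && is.na(iy[1]) && length(ax) > 1L) {
    ax <- ax[-1]; iy <- iy[-1]; line_no <- line_no[-1]
  }
  nonnum <- which(is.na(ax) | is.na(iy))
  if (length(nonnum))
    stop(sprintf("%s: non-numeric value on line %d", path,
                 line_no[nonnum[1]]), call. = FALSE)
  if (length(ax) < 2L)
    stop(sprintf("%s: fewer than 2 data rows", path), call. = FALSE)
  o <- order(ax)
  ax <- ax[o]; iy <- iy[o]
  dup <- which(diff(ax) == 0)
  if (length(dup))
    stop(sprintf("%s: duplicated axis value %.6g", path, ax[dup[1]]),
         call. = FALSE)
  meta$source <- path
  new_spectrum(ax, iy, meta)
}

#' Write a spectrum to a two-column delimited text file
#'
#' Metadata is written as `#`-prefixed header comments so the file
#' round-trips through [read_spectrum()].
#'
#' @param s A `raman_spectrum`.
#' @param path Output path.
#' @param sep Column separator, default comma.
#' @param digits Significant digits to print, default 12.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, sep = ",", digits = 12) {
  stopifnot(inherits(s, "raman_spectrum"))
  hdr <- character(0)
  scalars <- s$meta[vapply(s$meta, function(v)
    is.atomic(v) && length(v) == 1L, logical(1))]
  if (length(scalars))
    hdr <- sprintf("# %s: %s", names(scalars), vapply(scalars, format, ""))
  body <- paste(formatC(s$axis, digits = digits, format = "g"),
                formatC(s$intensity, digits = digits, format = "g"),
                sep = sep)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Resample a spectrum onto a master axis
#'
#' Intensity is linearly re-interpolated at the master Raman-shift
#' positions so spectra from different instruments share one axis.
#' Points of the master axis outside the source range are filled with
#' the nearest endpoint value (no extrapolated signal is invented) and
#' the spectrum is flagged in `meta$extrapolated`.
#'
#' @param s A `raman_spectrum`.
#' @param master_axis Strictly increasing numeric vector (cm^-1).
#' @return A `raman_spectrum` on `master_axis`.
#' @export
resample_to_master <- function(s, master_axis) {
  stopifnot(inherits(s, "raman_spectrum"))
  master_axis <- as.numeric(master_axis)
  if (any(diff(master_axis) <= 0))
    stop("master_axis must be strictly increasing", call. = FALSE)
  lo <- s$axis[1]; hi <- s$axis[length(s$axis)]
  if (master_axis[length(master_axis)] < lo || master_axis[1] > hi)
    stop("no overlap between spectrum axis and master axis", call. = FALSE)
  out <- stats::approx(s$axis, s$intensity, xout = master_axis,
                       method = "linear", rule = 2)$y
  meta <- s$meta
  n_out <- sum(master_axis < lo | master_axis > hi)
  meta$extrapolated <- n_out > 0L
  structure(list(axis = master_axis, intensity = out, meta = meta),
            class = "raman_spectrum")
}

#' Crop a spectrum to a Raman-shift interval
#'
#' Retains points with `lo <= axis <= hi`. The 300-1700 cm^-1 region
#' carries most of the pharmaceutical band information and is the usual
#' working range.
#'
#' @param s A `raman_spectrum`.
#' @param lo,hi Interval bounds in cm^-1, `lo < hi`.
#' @return The cropped `raman_spectrum`.
#' @export
crop_spectrum <- function(s, lo = 300, hi = 1700) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (!(lo < hi)) stop("lo must be < hi", call. = FALSE)
  keep <- s$axis >= lo & s$axis <= hi
  if (sum(keep) < 2L)
    stop(sprintf("crop to [%g, %g] leaves fewer than 2 points", lo, hi),
         call. = FALSE)
  new_spectrum(s$axis[keep], s$intensity[keep], s$meta)
}

#' Pair a primary (reference) and secondary (query) spectrum
#'
#' The primary instrument's axis is the master; the secondary spectrum is
#' resampled onto it unless the axes are already identical.
#'
#' @param primary Reference `raman_spectrum` (master instrument).
#' @param secondary `raman_spectrum` to be synchronized (slave instrument).
#' @return An object of class `spectrum_pair` with elements `primary`
#'   and `secondary` sharing one axis.
#' @export
spectrum_pair <- function(primary, secondary) {
  stopifnot(inherits(primary, "raman_spectrum"),
            inherits(secondary, "raman_spectrum"))
  if (!identical(primary$axis, secondary$axis))
    secondary <- resample_to_master(secondary, primary$axis)
  structure(list(primary = primary, secondary = secondary),
            class = "spectrum_pair")
}

#' @export
print.spectrum_pair <- function(x, ...) {
  cat(sprintf("<spectrum_pair> %d points on a common axis\n",
              length(x$primary$axis)))
  invisible(x)
}
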