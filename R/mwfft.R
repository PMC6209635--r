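#' Moving-window configuration
#'
#' @param window Window width in points (default 70, which resolves
#'   pharmaceutical Raman bands well at ~1.2 cm^-1/point sampling).
#' @param hop Stride between consecutive window starts (default 1: one
#'   window at every position, the densest shift matrix).
#' @param max_lag Per-window lag bound (default `floor(window / 3)`, so
#'   overlaps stay meaningful).
#' @param var_floor Windows whose segment standard deviation is below
#'   `var_floor` times the global standard deviation contribute nothing
#'   (flat baseline stretches carry no lag information). Default 1e-3.
#' @param noise_mult Windows whose segment standard deviation is below
#'   `noise_mult` times the spectrum's noise floor (the 5th percentile of
#'   all segment standard deviations) contribute nothing: their content
#'   is indistinguishable from detector noise, whose argmax lag is
#'   arbitrary. The screen disables itself when the segment-sd
#'   distribution shows no separable floor (median below `noise_mult`
#'   times the 5th percentile), i.e. when every window carries signal.
#'   Default 3.
#' @param min_corr Windows whose best cross-correlation value is below
#'   this floor contribute nothing: a window holding no band sees only
#'   independent noise, and its argmax lag is meaningless. Default 0.5,
#'   well above the null maximum (about 0.3 for a 70-point window) and
#'   well below the value of any window containing a shared band.
#' @param medfilt_width Median-filter width used to suppress single-point
#'   flickers in the shift profile (default 5).
#' @return A list of class `window_config`.
#' @export
window_config <- function(window = 70L, hop = 1L,
                          max_lag = max(1L, window %/% 3L),
                          var_floor = 1e-3, noise_mult = 3,
                          min_corr = 0.5, medfilt_width = 5L) {
  window <- as.integer(window); hop <- as.integer(hop)
  max_lag <- as.integer(max_lag)
  if (window < 4L) stop("window must be >= 4", call. = FALSE)
  if (hop < 1L || hop > window)
    stop("hop must be in [1, window]", call. = FALSE)
  if (max_lag < 1L || max_lag >= window)
    stop("max_lag must be in [1, window)", call. = FALSE)
  structure(list(window = window, hop = hop, max_lag = max_lag,
                 var_floor = var_floor, noise_mult = noise_mult,
                 min_corr = min_corr,
                 medfilt_width = as.integer(medfilt_width)),
            class = "window_config")
}

#' Build the shift matrix of a spectrum pair
#'
#' Slides a window from the beginning to the end of the common axis;
#' in each window the integer lag between the paired segments is
#' estimated by FFT cross-correlation, and that lag is recorded for
#' every point the window covers. Near-constant windows (below the
#' variance floor on either segment) and uninformative windows (best
#' correlation below `min_corr`) are skipped.
#'
#' @param pair A [spectrum_pair()] on a common axis.
#' @param cfg A [window_config()].
#' @return An object of class `shift_matrix` holding the window starts,
#'   the per-window lags, and the geometry needed to reconstruct each
#'   column's lag multiset (see [column_lags()]).
#' @export
build_shift_matrix <- function(pair, cfg = window_config()) {
  stopifnot(inherits(pair, "spectrum_pair"))
  r <- pair$primary$intensity
  q <- pair$secondary$intensity
  N <- length(r)
  w <- cfg$window
  if (N < w) stop("spectrum shorter than the window", call. = FALSE)
  starts <- seq.int(1L, N - w + 1L, by = cfg$hop)
  idx <- outer(seq_len(w) - 1L, starts, `+`)
  Rm <- matrix(r[idx], nrow = w)
  Qm <- matrix(q[idx], nrow = w)
  sd_r <- stats::sd(r); sd_q <- stats::sd(q)
  seg_sd_r <- sqrt(colSums(sweep(Rm, 2L, colMeans(Rm))^2) / (w - 1L))
  seg_sd_q <- sqrt(colSums(sweep(Qm, 2L, colMeans(Qm))^2) / (w - 1L))
  noise_floor <- function(segsd) {
    fl <- cfg$noise_mult * stats::quantile(segsd, 0.05, names = FALSE)
    # no separable floor (even the strongest windows sit near it): off
    if (fl >= stats::quantile(segsd, 0.95, names = FALSE)) 0 else fl
  }
  keep <- seg_sd_r >= pmax(cfg$var_floor * sd_r, noise_floor(seg_sd_r)) &
          seg_sd_q >= pmax(cfg$var_floor * sd_q, noise_floor(seg_sd_q))
  lags <- rep(NA_integer_, length(starts))
  if (any(keep)) {
    V <- xcorr_fft_batch(Rm[, keep, drop = FALSE], Qm[, keep, drop = FALSE],
                         cfg$max_lag)
    lag_vals <- seq.int(-cfg$max_lag, cfg$max_lag)
    # per column: first lag (in smallest-|lag| priority order) within
    # 1e-9 of the column max — the estimate_lag tie-break, vectorized
    prio <- order(abs(lag_vals), lag_vals)
    Vp <- V[prio, , drop = FALSE]
    cmax <- apply(Vp, 2L, max)
    hit <- Vp >= rep(cmax - 1e-9, each = nrow(Vp))
    first <- max.col(t(hit), ties.method = "first")
    est <- lag_vals[prio][first]
    est[cmax < cfg$min_corr] <- NA_integer_
    lags[keep] <- est
  }
  structure(list(starts = starts, lags = lags, window = w,
                 n = N, max_lag = cfg$max_lag, hop = cfg$hop),
            class = "shift_matrix")
}

#' Lag multiset of one shift-matrix column
#'
#' The column for spectral point `i` collects the lag estimated by every
#' (non-skipped) window covering `i`.
#'
#' @param m A `shift_matrix`.
#' @param i Spectral point index (1-based).
#' @return Integer vector of lags (possibly empty).
#' @export
column_lags <- function(m, i) {
  stopifnot(inherits(m, "shift_matrix"))
  sel <- m$starts >= i - m$window + 1L & m$starts <= i & !is.na(m$lags)
  m$lags[sel]
}

#' @export
print.shift_matrix <- function(x, ...) {
  cat(sprintf("<shift_matrix> %d windows of width %d over %d points (%d skipped)\n",
              length(x$starts), x$window, x$n, sum(is.na(x$lags))))
  invisible(x)
}

#' Construct a shift profile
#'
#' @param shift Integer displacement per spectral point.
#' @param window Window width the profile was estimated with (used by
#'   change-point relocation); may be `NULL`.
#' @param diagnostics Optional list (e.g. per-column mode multiplicity).
#' @return An object of class `shift_profile` with fields `shift`,
#'   `change_points` (indices `i` with `shift[i] != shift[i-1]`, i.e. the
#'   first point of each new regime), `window`, `diagnostics`.
#' @export
shift_profile <- function(shift, window = NULL, diagnostics = list()) {
  shift <- as.integer(shift)
  structure(list(shift = shift,
                 change_points = which(diff(shift) != 0L) + 1L,
                 window = window, diagnostics = diagnostics),
            class = "shift_profile")
}

#' @export
print.shift_profile <- function(x, ...) {
  cat(sprintf("<shift_profile> %d points, %d change point(s), shifts %s\n",
              length(x$shift), length(x$change_points),
              paste(unique(x$shift), collapse = "/")))
  invisible(x)
}

#' Column-mode shift profile from a shift matrix
#'
#' The displacement of each spectral point is the mode of its column's
#' lag multiset. Mode ties are broken toward the value of the previously
#' resolved (left) column, then toward the smallest |lag|. A column's
#' mode is only trusted when it is an actual majority
#' (`multiplicity >= majority_frac * coverage`) of at least
#' `min_coverage` votes: columns whose windows see only noise produce
#' scattered lags with no majority, and those columns (like columns left
#' empty by the window screens) inherit the nearest confident column's
#' value. The first/last `floor(window/2)` points inherit the nearest
#' interior column (window coverage is one-sided there).
#'
#' In addition, every shift regime (maximal constant run) of the raw
#' profile must be anchored: it must contain at least one column where at
#' least `anchor_frac` of a full window complement of votes agrees on the
#' regime's lag. Columns around a band apex are unanimous across nearly
#' all windows covering them and anchor their regime; stretches whose
#' only votes come from windows seeing a band tail (where the
#' correlation ridge is flat and the argmax unstable) never reach that
#' level of agreement, and such spurious regimes are absorbed by the
#' nearest anchored one.
#'
#' @param m A `shift_matrix`.
#' @param min_coverage Minimum number of window votes for a column to be
#'   resolved on its own (default 5).
#' @param majority_frac Minimum fraction of a column's votes the mode
#'   must hold (default 0.5).
#' @param anchor_frac Fraction of the maximal window coverage that must
#'   agree somewhere inside each regime (default 0.5).
#' @return A [shift_profile()].
#' @export
profile_from_matrix <- function(m, min_coverage = 5L, majority_frac = 0.5,
                                anchor_frac = 0.5) {
  stopifnot(inherits(m, "shift_matrix"))
  N <- m$n; w <- m$window; ml <- m$max_lag
  off <- ml + 1L
  nlag <- 2L * ml + 1L
  lag_at_start <- rep(NA_integer_, N)
  lag_at_start[m$starts] <- m$lags
  # a sparse window layout (large hop, or a single global window) cannot
  # reach the nominal coverage; scale the requirement down to what the
  # geometry allows
  min_coverage <- min(min_coverage, sum(!is.na(m$lags)),
                      max(1L, w %/% m$hop))
  counts <- integer(nlag)
  shift <- rep(NA_integer_, N)
  mult <- integer(N); coverage <- integer(N)
  prev <- NA_integer_
  for (i in seq_len(N)) {
    if (i <= N - w + 1L && !is.na(lag_at_start[i])) {
      k <- lag_at_start[i] + off; counts[k] <- counts[k] + 1L
    }
    if (i - w >= 1L && !is.na(lag_at_start[i - w])) {
      k <- lag_at_start[i - w] + off; counts[k] <- counts[k] - 1L
    }
    tot <- sum(counts)
    coverage[i] <- tot
    if (tot == 0L) next
    mx <- max(counts)
    cand <- which(counts == mx) - off
    mult[i] <- mx
    if (tot < min_coverage || mx < majority_frac * tot) next
    shift[i] <- if (!is.na(prev) && prev %in% cand) prev
                else cand[order(abs(cand), cand)][1]
    prev <- shift[i]
  }
  if (all(is.na(shift))) stop("all shift-matrix columns are empty", call. = FALSE)
  resolved <- !is.na(shift)
  filled <- fill_nearest(shift)
  # regime anchoring: drop runs never attested by a near-unanimous column
  # (thin-coverage columns at the rim of an informative stretch vote from
  # band-edge windows, whose flat correlation ridge makes the argmax
  # unstable; they must not seed regimes of their own)
  max_cov <- min(max(1L, w %/% m$hop), sum(!is.na(m$lags)))
  anchor_votes <- max(min_coverage, floor(anchor_frac * max_cov))
  anchored_pt <- resolved & mult >= anchor_votes
  runs <- rle(filled)
  run_anchored <- rep(vapply(seq_along(runs$lengths), function(k) {
    e <- cumsum(runs$lengths)[k]
    any(anchored_pt[(e - runs$lengths[k] + 1L):e])
  }, logical(1)), runs$lengths)
  if (any(run_anchored) && !all(run_anchored)) {
    # refill from anchored evidence only, so dropped runs inherit the
    # nearest attested column rather than a previously inherited point
    shift[!(run_anchored & resolved)] <- NA_integer_
    shift <- fill_nearest(shift)
  } else {
    shift <- filled
  }
  # one-sided coverage at the edges: inherit the nearest interior column
  h <- min(w %/% 2L, (N - 1L) %/% 2L)
  if (h > 0L && N - 2L * h >= 1L) {
    shift[seq_len(h)] <- shift[h + 1L]
    shift[(N - h + 1L):N] <- shift[N - h]
  }
  shift_profile(shift, window = w,
                diagnostics = list(mode_multiplicity = mult,
                                   coverage = coverage))
}

# fill NAs with the nearest non-NA value (ties toward the left)
fill_nearest <- function(x) {
  na <- which(is.na(x))
  if (!length(na)) return(x)
  ok <- which(!is.na(x))
  nearest <- ok[pmax(1L, findInterval(na, ok))]
  right <- ok[pmin(length(ok), findInterval(na, ok) + 1L)]
  use_right <- abs(right - na) < abs(nearest - na)
  nearest[use_right] <- right[use_right]
  x[na] <- x[nearest]
  x
}

#' Locate change points of a shift profile
#'
#' A change point is a discontinuity in the (piecewise-constant) shift
#' profile: the index of the first point of a new shift regime. A running
#' median of width `filter_width` is applied first so single-point
#' flickers of the raw column modes do not register as change points.
#'
#' @param p A [shift_profile()].
#' @param filter_width Odd median-filter width, default 5.
#' @return Integer vector of change-point indices (possibly empty).
#' @export
find_change_points <- function(p, filter_width = 5L) {
  stopifnot(inherits(p, "shift_profile"))
  s <- deflickered_shift(p$shift, filter_width)
  which(diff(s) != 0L) + 1L
}

deflickered_shift <- function(shift, filter_width = 5L) {
  if (length(shift) < filter_width) return(shift)
  as.integer(round(stats::runmed(shift, filter_width, endrule = "median")))
}

# median-filtered copy of a profile (drops single-point flickers)
deflicker_profile <- function(p, filter_width = 5L) {
  shift_profile(deflickered_shift(p$shift, filter_width),
                window = p$window, diagnostics = p$diagnostics)
}

#' Relocate change points away from peaks
#'
#' Insertions and deletions happen around change points, so each change
#' point is moved to the nearest local intensity minimum (valley) of the
#' secondary spectrum within one window of its original position; the
#' shifts of points between the old and new location are reassigned so
#' the profile stays piecewise constant. Peak shapes are thereby
#' preserved during synchronization. If no valley exists in range (flat
#' region), the original position stands and is flagged in
#' `diagnostics$unrelocated`.
#'
#' @param p A [shift_profile()].
#' @param s The secondary `raman_spectrum` (same length as the profile).
#' @return A [shift_profile()] with relocated change points.
#' @export
relocate_change_points <- function(p, s) {
  stopifnot(inherits(p, "shift_profile"), inherits(s, "raman_spectrum"))
  N <- length(p$shift)
  if (length(s$axis) != N)
    stop("profile and spectrum lengths differ", call. = FALSE)
  cps <- p$change_points
  if (!length(cps)) return(p)
  w <- if (is.null(p$window)) 70L else p$window
  y <- s$intensity
  vals <- p$shift[c(1L, cps)]           # one value per regime
  bounds <- c(cps, N + 1L)
  new_cps <- integer(length(cps))
  unrelocated <- logical(length(cps))
  prev_bound <- 1L
  for (k in seq_along(cps)) {
    cp <- cps[k]
    lo <- max(prev_bound + 1L, cp - w, 2L)
    hi <- min(bounds[k + 1L] - 1L, cp + w, N - 1L)
    cand <- integer(0)
    if (lo <= hi) {
      ii <- lo:hi
      is_min <- y[ii] <= y[ii - 1L] & y[ii] <= y[ii + 1L] &
        (y[ii] < y[ii - 1L] | y[ii] < y[ii + 1L])
      cand <- ii[is_min]
    }
    if (length(cand)) {
      new_cps[k] <- cand[order(abs(cand - cp), cand)][1]
    } else {
      new_cps[k] <- cp
      unrelocated[k] <- TRUE
    }
    prev_bound <- new_cps[k]
  }
  lens <- diff(c(1L, new_cps, N + 1L))
  out <- shift_profile(rep(vals, lens), window = p$window,
                       diagnostics = p$diagnostics)
  out$diagnostics$unrelocated <- cps[unrelocated]
  out
}

#' Synchronize the secondary spectrum using a shift profile
#'
#' Each maximal constant-shift region of the secondary spectrum is
#' translated by `-shift` index points onto the master axis. At change
#' points, gaps opened by diverging translations are filled by linear
#' interpolation between the flanking region endpoints (insertion), and
#' overlaps are resolved by dropping the points of the region with the
#' smaller |shift| (deletion). Inside each region the intensity values
#' are copied bit-identically: no resampling, so peak shapes are
#' preserved.
#'
#' @param pair A [spectrum_pair()].
#' @param p A [shift_profile()] of the same length.
#' @return The synchronized secondary `raman_spectrum` on the master
#'   axis (exactly N points).
#' @export
synchronize <- function(pair, p) {
  stopifnot(inherits(pair, "spectrum_pair"), inherits(p, "shift_profile"))
  q <- pair$secondary$intensity
  N <- length(q)
  if (length(p$shift) != N)
    stop("profile length does not match the spectra", call. = FALSE)
  cps <- p$change_points
  reg_start <- c(1L, cps)
  reg_end <- c(cps - 1L, N)
  reg_shift <- p$shift[reg_start]
  too_big <- abs(reg_shift) >= (reg_end - reg_start + 1L)
  if (any(too_big)) {
    k <- which(too_big)[1]
    stop(sprintf("shift %d exceeds region %d..%d", reg_shift[k],
                 reg_start[k], reg_end[k]), call. = FALSE)
  }
  out <- rep(NA_real_, N)
  for (k in order(abs(reg_shift), reg_start)) {
    src <- reg_start[k]:reg_end[k]
    tgt <- src - reg_shift[k]
    ok <- tgt >= 1L & tgt <= N
    out[tgt[ok]] <- q[src[ok]]
  }
  gaps <- which(is.na(out))
  if (length(gaps)) {
    known <- which(!is.na(out))
    out[gaps] <- stats::approx(known, out[known], xout = gaps,
                               method = "linear", rule = 2)$y
  }
  meta <- pair$secondary$meta
  meta$synchronized <- TRUE
  structure(list(axis = pair$primary$axis, intensity = out, meta = meta),
            class = "raman_spectrum")
}

#' Full MWFFT shift correction of a spectrum pair
#'
#' Composes the pipeline: build the shift matrix with a moving window,
#' take column modes to get the shift profile, suppress flickers with a
#' running median, relocate change points to valleys of the secondary
#' spectrum, and translate the continuous regions. Returns the corrected
#' spectrum, the final profile, and before/after similarity metrics.
#'
#' @param pair A [spectrum_pair()].
#' @param cfg A [window_config()].
#' @param relocate Move change points to valleys before synchronizing
#'   (default `TRUE`).
#' @param threshold Pass threshold on the post-correction correlation
#'   (default 0.95, the conventional hit-quality cut-off).
#' @return A list with `corrected` (`raman_spectrum`), `profile`
#'   (`shift_profile`), and `report` (`sync_report`).
#' @export
mwfft_correct <- function(pair, cfg = window_config(), relocate = TRUE,
                          threshold = 0.95) {
  m <- build_shift_matrix(pair, cfg)
  p <- profile_from_matrix(m)
  p <- deflicker_profile(p, cfg$medfilt_width)
  if (relocate) p <- relocate_change_points(p, pair$secondary)
  corrected <- synchronize(pair, p)
  report <- evaluate_pair(pair, corrected, threshold = threshold)
  list(corrected = corrected, profile = p, report = report)
}
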