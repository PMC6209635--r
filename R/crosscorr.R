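# Sign convention used package-wide: a positive lag means the query is
# displaced toward HIGHER index relative to the reference; translating
# the query by -lag aligns it.
#
# Normalization convention: at each lag the correlation is a true
# Pearson coefficient over the overlapping index range (means and norms
# recomputed per lag over the overlap), so values live in [-1, 1].

# overlap variance below this fraction of the full-vector variance is
# treated as degenerate (no lag information); c is defined as 0 there
DEGENERATE_REL_VAR <- 1e-10

xcorr_check <- function(ref, qry, max_lag) {
  if (length(ref) != length(qry))
    stop("ref and qry must have equal length", call. = FALSE)
  L <- length(ref)
  if (L < 2L) stop("need at least 2 points", call. = FALSE)
  if (max_lag < 1L || max_lag > L - 1L)
    stop("max_lag must be in [1, length - 1]", call. = FALSE)
  if (stats::var(ref) == 0 || stats::var(qry) == 0)
    stop("constant input: cross-correlation undefined", call. = FALSE)
  invisible(L)
}

new_xcorr <- function(lags, values) {
  best <- pick_best_lag(lags, values)
  structure(list(lags = lags, values = values,
                 best_lag = best, best_value = values[lags == best]),
            class = "xcorr")
}

# argmax with ties (within 1e-9 of the max) broken toward the smallest
# |lag|, preferring no shift; among +/-k the negative is taken first for
# determinism
pick_best_lag <- function(lags, values) {
  mx <- max(values)
  cand <- lags[values >= mx - 1e-9]
  cand[order(abs(cand), cand)][1]
}

#' @export
print.xcorr <- function(x, ...) {
  cat(sprintf("<xcorr> lags %d..%d, best lag %d (c = %.6f)\n",
              min(x$lags), max(x$lags), x$best_lag, x$best_value))
  invisible(x)
}

#' Direct normalized cross-correlation
#'
#' Reference implementation of the lag-wise correlation between two
#' equal-length signals: for each lag `j` in `[-max_lag, max_lag]`,
#' the Pearson coefficient of `ref(i)` against `qry(i + j)` over the
#' overlapping index range, with means and norms computed over that
#' overlap. Lags whose overlap is (numerically) constant get value 0.
#'
#' @param ref Reference intensity vector.
#' @param qry Query intensity vector, same length.
#' @param max_lag Largest |lag| considered, `1 <= max_lag <= length - 1`.
#' @return An `xcorr` object with `lags`, `values`, `best_lag`,
#'   `best_value`.
#' @seealso [xcorr_fft()] for the fast route with the identical contract.
#' @export
xcorr_direct <- function(ref, qry, max_lag) {
  L <- xcorr_check(ref, qry, max_lag)
  # global centering removes the common offset; per-lag Pearson is
  # invariant to it and the cancellation error shrinks accordingly
  r <- ref - mean(ref)
  q <- qry - mean(qry)
  vfloor_r <- DEGENERATE_REL_VAR * stats::var(r)
  vfloor_q <- DEGENERATE_REL_VAR * stats::var(q)
  lags <- seq.int(-max_lag, max_lag)
  vals <- numeric(length(lags))
  for (t in seq_along(lags)) {
    j <- lags[t]
    if (j >= 0) { ri <- 1:(L - j); qi <- (1 + j):L }
    else        { ri <- (1 - j):L; qi <- 1:(L + j) }
    n <- length(ri)
    if (n < 2L) { vals[t] <- 0; next }
    ra <- r[ri]; qa <- q[qi]
    ra <- ra - mean(ra); qa <- qa - mean(qa)
    vr <- sum(ra^2) / n; vq <- sum(qa^2) / n
    vals[t] <- if (vr <= vfloor_r || vq <= vfloor_q) 0 else
      sum(ra * qa) / sqrt(sum(ra^2) * sum(qa^2))
  }
  new_xcorr(lags, vals)
}

# Batched FFT cross-correlation over the columns of two L x K matrices.
# Returns a (2*max_lag + 1) x K matrix of per-lag overlap-Pearson values
# (rows ordered lag = -max_lag .. max_lag). Columns are centered by
# their own means first. Used by both xcorr_fft (K = 1) and the moving
# window, where all window segments are processed in one mvfft call.
xcorr_fft_batch <- function(Rm, Qm, max_lag) {
  L <- nrow(Rm); K <- ncol(Rm)
  Rm <- sweep(Rm, 2L, colMeans(Rm))
  Qm <- sweep(Qm, 2L, colMeans(Qm))
  vfloor_r <- DEGENERATE_REL_VAR * colSums(Rm^2) / (L - 1)
  vfloor_q <- DEGENERATE_REL_VAR * colSums(Qm^2) / (L - 1)
  M <- stats::nextn(2L * L, 2)
  pad <- matrix(0, M - L, K)
  FR <- stats::mvfft(rbind(Rm, pad))
  FQ <- stats::mvfft(rbind(Qm, pad))
  CC <- Re(stats::mvfft(Conj(FR) * FQ, inverse = TRUE)) / M
  Pr <- apply(Rm, 2L, cumsum);  Pq <- apply(Qm, 2L, cumsum)
  Pr2 <- apply(Rm^2, 2L, cumsum); Pq2 <- apply(Qm^2, 2L, cumsum)
  if (K == 1L) {  # apply() drops to vector
    Pr <- matrix(Pr, ncol = 1L); Pq <- matrix(Pq, ncol = 1L)
    Pr2 <- matrix(Pr2, ncol = 1L); Pq2 <- matrix(Pq2, ncol = 1L)
    CC <- matrix(CC, ncol = 1L)
  }
  lags <- seq.int(-max_lag, max_lag)
  V <- matrix(0, length(lags), K)
  for (t in seq_along(lags)) {
    j <- lags[t]
    n <- L - abs(j)
    if (n < 2L) next
    if (j >= 0) {
      Srq <- CC[1L + j, ]
      Sr <- Pr[n, ];  Sr2 <- Pr2[n, ]
      Sq <- Pq[L, ] - if (j > 0) Pq[j, ] else 0
      Sq2 <- Pq2[L, ] - if (j > 0) Pq2[j, ] else 0
    } else {
      Srq <- CC[M + 1L + j, ]
      Sr <- Pr[L, ] - Pr[-j, ]; Sr2 <- Pr2[L, ] - Pr2[-j, ]
      Sq <- Pq[n, ]; Sq2 <- Pq2[n, ]
    }
    num <- Srq - Sr * Sq / n
    ssr <- pmax(Sr2 - Sr^2 / n, 0)
    ssq <- pmax(Sq2 - Sq^2 / n, 0)
    ok <- (ssr / n > vfloor_r) & (ssq / n > vfloor_q)
    v <- numeric(K)
    v[ok] <- num[ok] / sqrt(ssr[ok] * ssq[ok])
    V[t, ] <- v
  }
  V
}

#' FFT-accelerated normalized cross-correlation
#'
#' Same contract as [xcorr_direct()]: lag-wise Pearson coefficients over
#' the overlap. The cross-product term is computed in the frequency
#' domain; the per-lag overlap means and norms come from exact prefix
#' sums, so the two routes agree to well below 1e-9 at every lag.
#'
#' @inheritParams xcorr_direct
#' @return An `xcorr` object.
#' @export
xcorr_fft <- function(ref, qry, max_lag) {
  xcorr_check(ref, qry, max_lag)
  V <- xcorr_fft_batch(matrix(ref, ncol = 1L), matrix(qry, ncol = 1L),
                       max_lag)
  new_xcorr(seq.int(-max_lag, max_lag), V[, 1L])
}

#' Estimate the integer displacement between two signals
#'
#' Returns the lag maximizing the FFT cross-correlation. Ties (values
#' within 1e-9 of the maximum, as on perfectly periodic signals) are
#' broken toward the smallest |lag|, preferring no shift.
#'
#' @inheritParams xcorr_direct
#' @return Integer lag; positive means the query is displaced toward
#'   higher index relative to the reference.
#' @export
estimate_lag <- function(ref, qry, max_lag = max(1L, length(ref) %/% 3L)) {
  xcorr_fft(ref, qry, max_lag)$best_lag
}
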