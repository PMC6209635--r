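# Shared fixture builders. Everything is generated in code at test time.

# a small noiseless spectrum with a few Gaussian bands
toy_spectrum <- function(n = 400, centers = c(120, 200, 310),
                         heights = c(1, 0.7, 0.9), width = 6) {
  ax <- seq_len(n)
  y <- numeric(n)
  for (k in seq_along(centers))
    y <- y + heights[k] * exp(-0.5 * ((ax - centers[k]) / width)^2)
  new_spectrum(ax, y)
}

# the study-condition workflow: six replicates per instrument, averaged,
# Savitzky-Golay smoothed, then paired on the master axis
workflow_pair <- function(fx, n_rep = 6L) {
  pr <- make_replicates(fx$spec, n_rep, warped = FALSE, seed_offset = 0L)
  sr <- make_replicates(fx$spec, n_rep, warped = TRUE, seed_offset = n_rep)
  spectrum_pair(smooth_savgol(average_replicates(pr)),
                smooth_savgol(average_replicates(sr)))
}

# naive lag-by-lag, sum-by-sum evaluation of the overlap-normalized
# cross-correlation; the independent oracle for the crosscorr module
xcorr_naive <- function(ref, qry, max_lag) {
  L <- length(ref)
  lags <- -max_lag:max_lag
  vals <- numeric(length(lags))
  for (t in seq_along(lags)) {
    j <- lags[t]
    num <- 0; ra <- c(); qa <- c()
    for (i in seq_len(L)) {
      if (i + j >= 1 && i + j <= L) { ra <- c(ra, ref[i]); qa <- c(qa, qry[i + j]) }
    }
    if (length(ra) < 2 || stats::sd(ra) == 0 || stats::sd(qa) == 0) { vals[t] <- 0; next }
    ra <- ra - mean(ra); qa <- qa - mean(qa)
    vals[t] <- sum(ra * qa) / sqrt(sum(ra^2) * sum(qa^2))
  }
  list(lags = lags, values = vals)
}

write_toy_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
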