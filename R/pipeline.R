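#' Select or create a reference spectrum from a library
#'
#' The library is a directory of CSV spectra keyed by filename. If
#' `<sample_name>.csv` exists, it is returned. Otherwise, if entries
#' sharing the same generic name exist (files named
#' `<sample_name>_<qualifier>.csv`), a consensus reference is built: a
#' shift profile of the fallback spectrum against each such entry is
#' estimated, the profiles are combined column-wise by mode
#' (mode-of-modes), and the fallback is synchronized with the consensus
#' profile. If the library has no related entry, the fallback itself
#' becomes the reference and is saved into the library for subsequent
#' analyses.
#'
#' @param sample_name Sample (generic drug) name, the library key.
#' @param library_dir Directory of CSV spectra (created if missing).
#' @param fallback `raman_spectrum` measured for this sample, used when
#'   no exact library entry exists.
#' @param cfg A [window_config()] for the consensus profile estimation.
#' @return A `raman_spectrum` to use as the reference.
#' @export
select_reference <- function(sample_name, library_dir, fallback,
                             cfg = window_config()) {
  exact <- file.path(library_dir, paste0(sample_name, ".csv"))
  if (file.exists(exact)) return(read_spectrum(exact))
  related <- if (dir.exists(library_dir))
    list.files(library_dir, pattern = paste0("^", sample_name, "_.*\\.csv$"),
               full.names = TRUE)
  else character(0)
  if (length(related)) {
    profiles <- lapply(related, function(f) {
      entry <- read_spectrum(f)
      pr <- spectrum_pair(entry, fallback)
      deflicker_profile(profile_from_matrix(build_shift_matrix(pr, cfg)),
                        cfg$medfilt_width)
    })
    S <- vapply(profiles, function(p) p$shift,
                integer(length(fallback$axis)))
    consensus <- apply(S, 1L, function(v) {
      tb <- table(v)
      cand <- as.integer(names(tb)[tb == max(tb)])
      cand[order(abs(cand), cand)][1]
    })
    p <- shift_profile(consensus, window = cfg$window)
    ref_entry <- read_spectrum(related[[1]])
    return(synchronize(spectrum_pair(ref_entry, fallback), p))
  }
  if (!dir.exists(library_dir))
    dir.create(library_dir, recursive = TRUE)
  write_spectrum(fallback, exact)
  fallback
}

#' Run the full synchronization pipeline on one sample
#'
#' The standard workflow: read replicate spectra from both instruments,
#' screen outliers, average, preprocess (airPLS baseline, Savitzky-Golay
#' smoothing, crop), shift-correct the secondary average toward the
#' primary average with MWFFT (or SSS given a fitted model), and report
#' before/after similarity.
#'
#' @param primary_paths Character vector of primary-instrument replicate
#'   files (or a single file).
#' @param secondary_paths Character vector of secondary-instrument
#'   replicate files.
#' @param method `"mwfft"` (default) or `"sss"`.
#' @param pre A [preprocess_config()].
#' @param win A [window_config()] (MWFFT).
#' @param sss_model A [fit_shift_model()] result (required for
#'   `method = "sss"`).
#' @param out Optional path for the corrected spectrum CSV.
#' @param profile_out Optional path for the shift profile CSV (axis,
#'   shift in points).
#' @param threshold Pass threshold on R, default 0.95.
#' @return List with `corrected`, `report`, and (MWFFT) `profile`.
#' @export
run_pipeline <- function(primary_paths, secondary_paths,
                         method = c("mwfft", "sss"),
                         pre = preprocess_config(), win = window_config(),
                         sss_model = NULL, out = NULL, profile_out = NULL,
                         threshold = 0.95) {
  method <- match.arg(method)
  ref_reps <- lapply(primary_paths, read_spectrum)
  qry_reps <- lapply(secondary_paths, read_spectrum)
  ref <- preprocess_replicates(ref_reps, pre)
  qry <- preprocess_replicates(qry_reps, pre)
  pair <- spectrum_pair(ref, qry)
  if (method == "mwfft") {
    res <- mwfft_correct(pair, win, threshold = threshold)
    corrected <- res$corrected
    profile <- res$profile
    report <- res$report
  } else {
    if (is.null(sss_model))
      stop("method 'sss' needs a fitted shift model", call. = FALSE)
    corrected <- sss_correct(pair$secondary, sss_model, pair$primary$axis)
    profile <- NULL
    report <- evaluate_pair(pair, corrected, threshold = threshold)
  }
  if (!is.null(out)) write_spectrum(corrected, out)
  if (!is.null(profile_out) && !is.null(profile))
    utils::write.csv(data.frame(axis = pair$primary$axis,
                                shift = profile$shift),
                     profile_out, row.names = FALSE)
  list(corrected = corrected, report = report, profile = profile)
}
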