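Package: ramansync
Title: Synchronization of Raman Spectra Across Spectrometers by
    Moving-Window FFT Cross-Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for eliminating non-linear Raman-shift displacements
    between spectra acquired on different spectrometers. Estimates a
    piecewise-constant shift profile with a moving-window FFT
    cross-correlation (MWFFT), locates change points, and synchronizes
    the secondary spectrum to the primary one by translating continuous
    regions with insertion and deletion away from peak regions. Also
    provides the standard-scattering-shift (SSS) comparator built on
    chemical-standard peak positions, a preprocessing chain (airPLS
    baseline correction, Savitzky-Golay smoothing, replicate averaging,
    outlier screening), similarity metrics (correlation coefficients and
    mean Euclidean distance), and a synthetic spectrum-pair generator
    with known ground-truth warps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    signal,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
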