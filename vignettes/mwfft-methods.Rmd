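---
title: "Synchronizing Raman spectra with moving-window FFT cross-correlation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronizing Raman spectra with moving-window FFT cross-correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramansync)
```

## The problem and the model

Two Raman spectrometers measuring the same sample disagree about where
bands sit on the Raman-shift axis. The disagreement originates mainly in
the CCD detectors and is, in general, non-linear: a displacement of +2
points in one spectral region may coexist with +8 points in another.
`ramansync` models this as a **piecewise-constant integer displacement
field** over the spectral points — the *shift profile*. The assumptions
are:

* both spectra are sampled on (or have been interpolated onto) one
  common, strictly increasing axis;
* within a contiguous region, the displacement is a whole number of
  points and constant;
* regions are long relative to the analysis window, and the profile
  changes value at a small number of *change points*;
* band shape is instrument-independent enough that a mean-centered,
  norm-scaled segment of one spectrum correlates strongly with the
  matching segment of the other.

Under these assumptions the displacement of a segment is the argmax of
the overlap-normalized cross-correlation

$$c(j) = \frac{\sum_i (r_i - \bar r)(s_{i+j} - \bar s)}
{\sqrt{\sum_i (r_i-\bar r)^2}\sqrt{\sum_i (s_{i+j}-\bar s)^2}},$$

where all sums run over the indices at which both signals are defined
for lag $j$, and the means and norms are recomputed per lag over that
overlap. This makes $c(j)$ a genuine Pearson coefficient at every lag
(bounded in $[-1, 1]$), at the price of a slightly more involved fast
implementation: `xcorr_fft()` computes the raw cross-products in the
frequency domain and the per-lag overlap means/norms from exact prefix
sums, so it matches the literal evaluation (`xcorr_direct()`) to well
below $10^{-9}$ — a property the test suite sweeps over hundreds of
random pairs.

**Sign convention.** A positive lag means the query is displaced toward
*higher* index relative to the reference; synchronization translates the
query by $-$lag. Ties within $10^{-9}$ of the maximum break toward the
smallest $|$lag$|$ (preferring "no shift"), which also fixes the
behavior on perfectly periodic signals.

## From windows to a shift profile

`build_shift_matrix()` slides a `window`-point window (default 70) at
stride `hop` (default 1) along the pair, estimates one lag per window,
and records that lag for every point the window covers. The *shift
matrix* therefore has one column per spectral point; `profile_from_matrix()`
takes each column's **mode**. Two screens decide which windows may vote
at all:

* `var_floor` (default $10^{-3}$ of the global standard deviation)
  removes exactly-flat segments;
* `noise_mult` (default 3) removes windows whose segment standard
  deviation is below three times the spectrum's *noise floor*, taken as
  the 5th percentile of all segment standard deviations. A window whose
  content is indistinguishable from detector noise has an arbitrary
  argmax — worse, after smoothing the noise is locally correlated, so
  *adjacent* noise-only windows agree on the same junk lag and would
  otherwise fabricate whole regimes. The screen disables itself when the
  segment-sd distribution shows no separable floor (95th percentile
  below `noise_mult` times the 5th), i.e. when every window carries
  signal;
* `min_corr` (default 0.5) additionally discards windows whose best
  correlation is no better than chance.

Column modes are accepted only as actual majorities: a column needs at
least `min_coverage` (5) votes and its mode must hold at least
`majority_frac` (50%) of them; mode ties break toward the
already-resolved left neighbor, then toward the smallest $|$lag$|$.
Finally, every *regime* (maximal constant run of the profile) must be
**anchored** by at least one column where at least `anchor_frac` (50%)
of a full window complement agrees. The motivation is a failure mode of
windows that see only the monotone *tail* of a band: their correlation
ridge is nearly flat across neighboring lags, so their argmax is
confidently off by one to three points, and a cluster of them can form a
spurious regime. Columns under a band apex, by contrast, are unanimous
across essentially all windows covering them. Unanchored runs, columns
without a majority, and screened-out stretches all inherit the nearest
anchored, resolved column's value. These voting rules are this package's
realization of "the mode of each column"; the defaults were calibrated
once on the generator's study conditions by measuring the separation
between apex-anchored and tail-only columns, and are exposed as
arguments.

A running median of width `medfilt_width` (5) removes single-point
flickers before change points are read off as the indices where
consecutive shifts differ (`find_change_points()`, reporting the first
index of each new regime).

## Synchronization, insertions, and deletions

`relocate_change_points()` moves each change point to the nearest local
intensity minimum of the *secondary* spectrum within one window of its
position (bounded by the neighboring change points); if no valley exists
there — a perfectly flat stretch — the original position stands and is
flagged. `synchronize()` then translates each constant-shift region of
the secondary spectrum by $-$shift. Where neighboring regions diverge, a
gap opens and is filled by linear interpolation between the flanking
region endpoints (*insertion*); where they collide, the overlapping
points of the region with the smaller $|$shift$|$ are dropped
(*deletion*). Because all edits happen at change points, which have been
moved into valleys, the intensity values inside each region are copied
**bit-identically** — no resampling — and peak shapes survive exactly.
A shift as large as its region is refused with an error naming the
region. The output always has exactly $N$ points on the master axis.

`mwfft_correct()` composes the chain and reports `r` (correlation before),
`R` (after), the mean Euclidean distances on min–max-normalized copies,
and a pass flag against the conventional 0.95 threshold. The per-window
FFT work is batched through one `mvfft()` call, so the cost scales as
$O(N \cdot w \log w / \mathrm{hop})$; the acceptance suite checks that
doubling $N$ at fixed $w$ roughly doubles the runtime.

## The comparator: standard scattering shifts

`pick_peaks()` locates, for each certified standard band (the packaged
acetaminophen/cyclohexane table; the duplicated rows of the printed
source table were removed), the local intensity maximum within ±10 cm⁻¹
(about three times a typical 3–3.5 cm⁻¹ system resolution) and refines
the apex with a three-point parabola. `fit_shift_model()` regresses the
displacement (measured − reference) on the *reference* position — the
parameterization consistent with correcting the secondary axis toward
the primary — and `sss_correct()` maps every axis value $x$ to
$x - \widehat{d}(x)$ followed by linear re-interpolation onto the master
axis. SSS is exact (to interpolation error) for linear warps and is
structurally unable to follow a two-regime step, which is precisely the
comparison the acceptance suite makes against MWFFT.

## Preprocessing chain

The workflow mirrors standard practice: screen replicate outliers, average,
subtract the baseline, smooth, crop.

* **airPLS** baseline correction (`baseline_airpls()`): iteratively
  reweighted Whittaker smoothing, implemented here with sparse
  second-difference penalties (`Matrix`), zero weights for points above
  the running baseline, exponentially growing weights below it, and a
  stopping rule at 0.1% of the total signal magnitude or `maxiter`
  (15). `lambda` (default $10^5$) sets the baseline stiffness in units
  of the squared second difference; larger values give flatter
  baselines.
* **Savitzky–Golay** smoothing via `signal::sgolayfilt()`, 9 points and
  order 2 by default (exact on quadratics).
* **Replicate handling**: `screen_outliers()` drops replicates whose
  Pearson correlation with the median of the others falls below 0.95
  (the same convention as the hit-quality pass threshold; the procedure
  itself is a design choice, as is min–max normalization before
  distance computations — both are switchable). At most half the
  replicates can be dropped; with fewer than three, screening is
  skipped with a warning.
* **Crop** to 300–1700 cm⁻¹, the band-rich working region.

Correlations are scale-invariant and need no normalization; Euclidean
distances are computed on min–max-normalized copies.

## What the generator emulates — and what it does not

`synth_spec()`/`make_pair()` produce primary/secondary pairs with known
ground truth: Gaussian (or Lorentzian) bands on a 2048-point, 175–2700
cm⁻¹ axis (a typical portable-instrument CCD and range), a polynomial
baseline, additive Gaussian noise, and a warp that is either
piecewise-constant in index space (what MWFFT corrects) or linear in
cm⁻¹ (what SSS corrects). The study conditions baked into
`synthetic_fixture()` are: 12 bands per warp region with the tallest
apex at 1 and noise sd 0.05 (signal-to-noise 20), regions at least twice
the 70-point window, band widths of 3–7 cm⁻¹ (Gaussian sd), and six
replicates per instrument with independent noise. One band is placed
within about 60 points of each side of every regime boundary: a change
point is only identifiable where signal exists near it (and physically a
calibration regime does not flip in the middle of a band), so fixtures
without flanking bands would make the ground-truth change-point position
unrecoverable *in principle*, not merely hard.

Two honest caveats follow. First, profile recovery at this
signal-to-noise level relies on the replicate-averaging and smoothing
steps of the workflow: on a single raw acquisition, an isolated wide
band can vote for a lag off by one point *unanimously* (every window
covering it shares the same noise realization), an intrinsic limit of
integer-lag estimation rather than an implementation artifact. Second,
the generator omits cosmic-ray spikes, etaloning, fluorescence
photobleaching, detector non-linearity, and instrument-dependent band
shapes; passing tests show correct recovery of the modeled warp class
under realistic noise, not robustness to every artifact of real
instruments.

## Numerical choices and degenerate inputs

* Both cross-correlation routes center the full vectors first (the
  per-lag Pearson is invariant to it) to suppress cancellation error in
  the prefix-sum norms; overlaps whose variance falls below $10^{-10}$
  of the full-vector variance get $c = 0$ in both routes.
* Constant inputs, mismatched lengths, and out-of-range `max_lag` are
  errors; lags with fewer than two overlapping points are 0.
* `resample_to_master()` holds endpoint values outside the source range
  (no linear extrapolation — no invented signal) and flags the spectrum.
* Edge columns of the profile (first/last `window/2` points, where
  coverage is one-sided) inherit the nearest interior column.
* All randomness in the generator is seeded; identical seeds give
  bit-identical spectra.
* Fixture sizes in the test suite (2048-point spectra, 50 recovery
  trials, 16k/32k-point timing pairs) were chosen to exercise the
  study conditions at interactive runtimes.

## Limitations

* Shifts are corrected in whole points; sub-point (fractional)
  displacement correction and parabolic lag refinement are out of scope,
  as is 2-D (hyperspectral image) alignment.
* The method needs shared band structure: spectral stretches with no
  bands carry no alignment information, and their profile values are
  inherited from the nearest informative region.
* SSS support is limited to the linear displacement model; absolute
  frequency calibration from gas emission lines is not implemented.
* Vendor binary formats (SPC, WDF, JCAMP-DX) are not read; spectra are
  exchanged as two-column delimited text.
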