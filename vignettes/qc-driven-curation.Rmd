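---
title: "QC-driven curation of LC–MS untargeted metabolomics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QC-driven curation of LC-MS untargeted metabolomics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscurate)
```

## The problem

Untargeted LC–MS metabolomics produces a matrix of chromatographic peak
areas — N samples by K features, a feature being an (m/z, retention time)
pair — that is contaminated by several distinct technical artefacts:
solvent and handling contaminants visible in blank injections, smooth
intensity drift over the injection sequence, features detected too
erratically to be usable, and features whose variation is dominated by
technical rather than biological variance. `mscurate` implements a
pooled-QC-based curation pipeline for this matrix, plus the raw-data
operations needed upstream (chromatogram extraction, CWT peak picking,
centWave-style feature detection, feature correspondence) and
system-suitability checking.

The pooled QC sample — equal aliquots of all study samples, injected
repeatedly through the run — is the instrument's own control chart: any
variation it shows is technical by construction, and every filter and
correction in the pipeline is parameterised by it.

## The data model

`ms_dataset()` bundles the area matrix with per-sample metadata (class,
run order, batch) and per-feature metadata (m/z, Rt). A *sample mapping*
assigns class labels to the roles `study`, `qc` and `blank`; each
processing step picks the rows it needs through the mapping rather than
through explicit class lists. All user-facing functions take the dataset
first and return it modified, so pipelines read as pipes, and `tidy()` /
`glance()` expose the contents as tibbles.

## Metrics

For a feature with areas $x_1, \dots, x_n$ over a set of samples:

* **Detection rate (DR)** — the fraction of samples with area above a
  threshold. In *intraclass* mode the minimum per-class fraction is used,
  so DR = 1 demands consistent detection in every class. (The per-class
  maximum is available as `mode = "any_class"` for the laxer reading of
  "consistently detected in at least one class".)
* **Robust RSD** — $1.4826 \cdot \mathrm{MAD} / \mathrm{median}$, the
  MAD-based analogue of the coefficient of variation; 1.4826 is the
  consistency factor under normality.
* **D-ratio** — $\mathrm{MAD}_{QC} / \mathrm{MAD}_{study}$: technical
  dispersion relative to total dispersion. Near 0 means technical noise is
  negligible; near 1 means the feature carries essentially no biological
  information.

Metrics whose centre is zero are reported as `NA` and treated by every
filter as failing — curation is deliberately conservative about undefined
quantities.

## The default pipeline

`default_pipeline()` reproduces a standard plasma-study curation sequence:

1. **Rt filter** — drop features eluting before 90 s (column dead time);
   the interval is closed, so a feature at exactly 90 s is kept.
2. **QC-presence filter** — a feature must be detected in every QC
   injection, including the first and last QC of each batch
   (`require_bracket`), so the drift model below never extrapolates.
3. **Blank correction** — per feature, with $B_{max}$ and $B_{mean}$ the
   maximum and mean blank area: sample areas $\le 10 \cdot B_{max}$ become
   0; larger areas have $B_{mean}$ subtracted (clipped at zero).
4. **LOESS drift correction** — per feature and batch, QC area is
   regressed on run order with a robust LOESS (degree 1,
   `family = "symmetric"`); the span is chosen per feature by leave-one-out
   cross-validation over the grid 0.3–1.0 in steps of 0.1, ties going to
   the larger (smoother) span; the fitted curve is evaluated at QC orders,
   linearly interpolated to every sample's order, and areas are rescaled as
   $x \cdot \mathrm{median}(QC) / \hat g(\mathrm{order})$.
5. **Variation filter** — remove features with robust RSD over QCs
   strictly above 20%.
6. **Prevalence filter** — zero all areas below 5 (matrix-wide), then
   require 100% intraclass detection over the study classes.
7. **D-ratio filter** — keep features with D-ratio strictly below 10%.
8. **Total-area normalization** — divide each sample row by its total.

Each step appends a record (parameters, features removed, per-feature
values where relevant) to the dataset's log; `curation_report()` turns the
log into the feature funnel and `plot_curation_funnel()` draws it.

### Numerical and design choices

* **Strictness of inequalities** follows the verbal rules: "larger than
  20% … eliminated" removes at RSD > 0.20; "lower than 10%" keeps at
  D-ratio < 0.10; the Rt interval is closed.
* **Zeros are data.** Zeroed areas (from blank correction or prevalence
  thresholding) count as *not detected* in later detection-rate
  computations, and zeros participate in dispersion metrics; missing cells
  on load become 0 with a warning, since exported area tables rarely
  distinguish the two.
* **Correction is multiplicative.** The drift model rescales by the ratio
  of the QC median to the drift curve. A consequence worth knowing when
  validating against simulations: if a multiplicative drift $g$ is planted
  on true areas $x$, the corrected areas converge to
  $x \cdot \mathrm{median}(g(\text{QC orders}))$ — drift-free up to one
  common anchor constant set by the QC median. Our recovery tests compare
  after removing that known anchor.
* **Extrapolation is forbidden.** The LOESS step errors if a batch's
  samples fall outside the QC-bracketed run-order range, and removes
  (rather than guesses at) features whose *detected* QCs fail to bracket
  the samples; `qc_presence_filter(require_bracket = TRUE)` screens these
  out up front. At least 4 detected QC points per batch are required per
  feature.
* **Blank rows are not normalized** by default: after blank correction
  they no longer mean anything and may be all zero. A zero-total sample
  among the normalized roles is an error naming the sample.
* **Batches are independent.** No inter-batch scaling is attempted; the
  drift model is fitted per batch.

## Raw-data processing

`read_mzml()` / `write_mzml()` wrap Bioconductor's mzR, ordering spectra
by acquisition time and flagging profile-mode scans (accepted for
chromatogram work, refused by ROI detection, which needs centroids).

`detect_peaks_cwt()` implements ridge-line peak picking: the signal is
transformed with a Ricker (Mexican-hat) wavelet over a geometric grid of
scales (`cwt_widths()`, spanning 1 to half the widest expected peak in
samples — the Ricker scale tracks the Gaussian SD of a peak), per-scale
local maxima are linked into ridges from coarse to fine, and a ridge
becomes a peak if it persists over at least a quarter of the scale grid
and clears the SNR bound. Peak boundaries are the flanking signal minima
within ±5 best-scale widths of the apex; the area is the trapezoidal
integral above a straight baseline between the boundary intensities; SNR
is the baseline-corrected height over a robust noise level, the
1.4826-scaled MAD of the first-differenced flanking signal (first
differencing detrends slow baselines; the √2 factor corrects the variance
doubling). On noiseless Gaussians this recovers the analytic area
$A\sigma\sqrt{2\pi}$ to well under 1%; at `min_snr = 10` pure-noise
signals produce a spurious peak in ≲2% of runs.

`make_rois()` is a centWave-style region-of-interest builder: points
extend an open ROI when within an absolute m/z tolerance (default 0.005
Th) of its running mean m/z; one missed scan is tolerated as a gap
(intensity 0), and ROIs need 5 real points and a 500-count apex by
default — conventional centWave-ish defaults, configurable.
`detect_features()` runs the CWT picker over each ROI trace and reports
the intensity-weighted mean m/z within the peak bounds;
`targeted_feature_detection()` extracts an EIC per target m/z and keeps
the largest-area peak in the requested Rt window, reporting absent
targets explicitly. Retention times are seconds everywhere.

`match_features()` performs correspondence across samples by a
DBSCAN-style density clustering (eps = 1, min 2 neighbours) on
tolerance-standardized (m/z, Rt) coordinates, resolving same-sample
duplicates by the larger area (ties: earlier Rt) and dropping clusters
seen in fewer than `min_fraction` of samples. This is a deliberately
standard scheme chosen for the stated tolerance semantics; it has not
been stress-tested against heavily warped retention times, and no Rt
alignment is attempted.

## Suitability checking and PCA

`build_reference()` summarizes ≥ 2 replicate standard injections into
per-analyte means and SDs; `check_injection()` applies the closed
acceptance intervals (mean ± 2 SD for m/z and area, ± 3 s for Rt by
default) and reports per-quantity pass flags. `pca_scores()` provides
column-centred SVD scores (optionally autoscaled or Pareto-scaled, though
drift checks default to no scaling since areas share a scale after
normalization), with signs fixed by forcing each component's
largest-magnitude loading positive. A QC-only PCA whose leading component
correlates with run order is the standard visual symptom of drift; after
LOESS correction that correlation should collapse.

## The synthetic generators

`generate_raw_run()` plants Gaussian elution profiles (apex, width,
height, per-scan m/z jitter) on a centroid scan grid with optional uniform
noise points, returning the analytic truth
($\mathrm{area} = h\sigma\sqrt{2\pi}$) alongside — so detection accuracy
is scored against closed forms, not against another tool.

`generate_study()` emulates a single-batch plasma-style study: by default
two classes of 8 samples, 50 features with log-normal abundances and
between-sample biological variation (CV ≈ 30%), 3 leading blanks, a QC
template of 3 conditioning injections, a bracketing QC every 4th study
injection and 2 trailing QCs, multiplicative linear drift of 40% across
the run, 2% proportional technical noise, 10% of features contaminated at
5% of their abundance (visible in blanks), 15% of features subject to
class-specific detection dropout, and 20% of features with no biological
variation (D-ratio bait). The defaults were chosen once as representative
of a well-run single-batch study; tests vary seeds, not conditions.

What the generator does *not* emulate — correlated features, co-eluting
isomers, retention-time warping, heteroscedastic detector saturation,
batch-to-batch effects — bounds what passing tests show: they validate
the algorithms' contracts on data satisfying their assumptions, not
performance on any particular real cohort.

Problem sizes used in the shipped tests (40-injection drift batches;
studies of 27 injections × 15–50 features; 100-seed replicate loops for
noise, drift and suitability properties; 50-seed full-pipeline oracle
comparisons) were chosen to make the whole suite convenient to run while
keeping every Monte-Carlo bound well-determined.

## Known limitations

* No profile-mode centroiding, no MS2 handling, no isotope/adduct
  grouping or annotation.
* No retention-time alignment before correspondence.
* No inter-batch normalization (ComBat-style) — batches are corrected
  independently and left on their own QC-median scales.
* The LOOCV span search refits LOESS per left-out point; it is the
  dominant cost of the pipeline and scales linearly in features × QCs ×
  grid size.
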