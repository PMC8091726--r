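---
title: "Plane-threshold quantification of iRFP tumour fluorescence"
author: "irfpquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plane-threshold quantification of iRFP tumour fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irfpquant)
```

## The measurement problem

In vivo imaging of tumours expressing a near-infrared fluorescent protein
(iRFP713) produces single-channel intensity images in arbitrary,
platform-specific raw units: radiant efficiency, counts or signal,
depending on the instrument. Proprietary platform software quantifies
tumours after the user *gates* the display — sets intensity thresholds by
eye — which removes background from view and makes the judgement of where
signal starts subjective and poorly comparable across platforms.

This package implements the alternative: work directly on the raw
exported TIFFs, view the cropped image as a 3D intensity surface, and cut
that surface with a horizontal plane. Everything above the plane is
tumour signal, everything below it is mouse-body background, and the
plane height itself is the background level to subtract. Because
background and signal are visible simultaneously on the surface, the
choice of cut is far less arbitrary than display gating, and it transfers
unchanged across platforms.

## The procedure

For each image the workflow is:

1. **Crop** to the tumour and a small surrounding area (coordinates are
   0-based, half-open `[start, stop)`, rows before columns — one fixed
   convention, documented in the CLI help, so crops are reproducible).
2. **Normalize**: divide by the image maximum so values lie in `[0, 1]`
   with the brightest pixel exactly 1 (`normalizeImage()`). The raw
   maximum is retained; normalization only serves visualization and
   thresholding, never measurement.
3. **Threshold**: an initial plane height comes from Kapur
   maximum-entropy histogram thresholding (`entropyThreshold()`): among
   all cuts of the 256-bin histogram of `[0, 1]`, choose the one
   maximizing the summed Shannon entropies of the below- and above-cut
   partitions. The level is an *initial value* by design — the analyst
   may move the plane (`thresholdPlane()`) until it transcribes the
   tumour boundary, and the method tag (`auto_entropy` vs `manual`)
   travels with every downstream measurement.
4. **Segment**: pixels strictly above the plane form the tumour mask
   (`planeSegment()`); its 4-connected boundary is extracted for
   overlay display. Equality belongs to background: a plane *through*
   the surface excludes points lying on it, and one consistent
   convention matters more than which one.
5. **Measure** (`measureRegion()`): all quantities come from the raw,
   unscaled counts. With plane raw level \(\ell\) and mask area \(A\),

   \[
   \mathrm{net} \;=\; \sum_{p \in \mathrm{mask}} I_p \;-\; \ell A ,
   \]

   the plane-level background subtraction. Saturated pixels
   (`detectSaturation()`: value equal to \(2^{\mathrm{bits}}-1\))
   inside the mask are counted and reported, because clipped peaks
   bias totals downwards.

Scale invariance follows by construction: multiplying the raw image by
any positive constant (without clipping) leaves the normalized surface,
the entropy level and the mask unchanged. Raising the plane can only
shrink the mask.

### Why Kapur for the initial value

The cut is an adjustable starting point, so the requirements are that it
be deterministic, histogram-based, scale-free and sensible on bimodal
body/tumour crops. Maximum-entropy thresholding meets all four and is
the standard automatic method of this family; the criterion and bin
count (`nBins = 256`) are configurable, and ties resolve to the *lowest*
maximizing level, i.e. the most inclusive mask. On the synthetic scenes
below, the automatic cut typically lands a few counts above the
body-plateau level — exactly where an analyst would put it.

## Raw-unit bookkeeping across platforms

Detector bit depth governs dynamic range: 16-bit platforms clip at
65535, while 22-bit data reach 4194303. The logical bit depth is a
property of the data, not of the file: depths up to 16 are stored as
16-bit unsigned TIFF, deeper data go into the 32-bit TIFF container with
the declared logical ceiling used for validation (the on-disk container
for 22-bit exports is not standardized, so the package adopts the
32-bit container and round-trips counts bit-exactly through it).

Detector binning (`binImage()`) is block **summation**, not averaging: a
k×k binned acquisition accumulates k² pixels' worth of photons per
output pixel, so 8×8 binning multiplies per-pixel signal by 64 relative
to unbinned acquisition. Sum semantics conserve total image intensity
and reproduce that factor exactly; binning that does not divide the
image dimensions is rejected rather than padded so that sums stay exact.
Block sums that overflow the ceiling either widen the container (with a
warning) or clip on request — clipping is what a real detector does, and
`detectSaturation()` will then flag it.

## Statistics on measurement series

* **Fold change** (`foldChange()`): ratio of across-mice mean
  measurements between two imaging days (group means, matching "fold
  increase of average tumour size"); a per-mouse-ratio variant
  (`perMouse = TRUE`) is provided for per-animal trajectory analyses and
  labelled distinctly, because the two differ under heterogeneous
  growth.
* **Coefficient of variance** (`coefficientOfVariance()`):
  `100 · sd / mean` with the sample (n−1) standard deviation
  throughout — group sizes in mouse work are small. The headline CV of
  a longitudinal experiment is taken across mice at the final day; the
  across-days-within-mouse alternative is deliberately not the headline.
* **Limit of detection** (`limitOfDetection()`): the smallest dilution
  whose replicate mean exceeds the background-well mean by more than
  `k` background standard deviations (`k = 3` default). This replaces
  the subjective "last visible dilution" call with an explicit rule;
  `k` is exposed everywhere because the visual calls it formalizes were
  themselves judgement calls.
* **Dilution linearity** (`dilutionLinearity()`): per-dilution means
  normalized to the top dilution, and the log10–log10 slope of
  background-subtracted signal against dilution factor over the
  detectable range (slope 1 = perfect proportionality). Background is
  subtracted before normalization by default (`subtractBackground`,
  recorded in the output), since wells at background otherwise distort
  the low end of the curve.
* **Detection tables** (`detectionTable()`): earliest detected day per
  (lesion, platform), `NA` for never-detected, the layout of a
  detection heatmap. `detectSignal()` supplies the underlying per-day
  calls: candidate mean above background mean plus `k` background sd.

## The synthetic module: what it does and does not emulate

`simMouseImage()` renders the structure the analysis relies on: an
imaging-bed level, a mouse-body plateau clearly above it (the
high-dynamic-range situation in which body and bed backgrounds
separate), Gaussian tumour blobs, additive Gaussian detector noise
(a Poisson option exists but is not the default — the true detector
noise model is instrument-specific), integer rounding, and bit-depth
clipping. Defaults: 96×96 crop, bed 500 counts, body 2000 counts, blob
σ = 4 px, noise sd 20 counts, 16-bit — chosen once as a plausible
tumour-neighbourhood crop with body background well above bed and noise
around 1% of the plateau. `simDilutionPlate()` (tenfold steps,
triplicates, 6 dilutions spanning 10⁵), `simPhantomSeries()`
(log-normal multiplicative amplitude jitter plus positional shifts,
emulating random repositioning of a phantom mouse) and
`simGrowthTimecourse()` (exponential amplitude growth over a
twice-weekly 14/17/21/24-day schedule, default doubling time 3.5 days)
compose scenes into the study designs. Every generator is deterministic
given a seed and emits its ground truth, so recovery tests never rely
on the pipeline under test.

The Gaussian blob is a point-spread proxy, not an optical model: no
light transport, tissue attenuation, depth dependence or autofluorescence
texture is simulated. Passing recovery tests therefore demonstrates that
the measurement chain is correct and unbiased on smooth unimodal signals
over a uniform plateau — not that any platform resolves deep-tissue
tumours.

## Numerical and design choices

* Strict `>` defines signal; ties in the entropy objective go to the
  lowest level; histogram bin `i` covers `[(i−1)/n, i/n)` with 1 in the
  last bin.
* The mask is **not** restricted to the largest connected component by
  default (images are already cropped to a tumour neighbourhood); an
  optional `largestComponent` filter exists and announces itself when
  used.
* Plane-based subtraction (`level × area`) is the only subtraction
  applied; the ellipse background estimate (`estimateBackground()`,
  `ellipseMask()`) feeds detection calls and QC, never a second
  subtraction.
* An all-zero image cannot be normalized and a constant surface has no
  threshold; both are explicit degenerate-input errors rather than
  silent results. An empty detectable range in a dilution series is a
  *result*, not an error.
* Empty masks measure as zero totals; `netTotal` can be negative if the
  plane sits above the mask mean — that is information, not an error.
* In noisy recovery analyses (growth fold change with per-pixel noise,
  phantom CV), measurement uses a fixed disc of radius 3σ centred on
  the signal peak with the plane at the known plateau level, emulating
  the user-drawn region of the real workflow. A free thresholded mask
  under per-pixel noise admits every upward noise fluctuation across
  the whole body and would bias totals upwards — a property of
  free-mask thresholding at the background level, not of the
  measurement itself. Noiseless end-to-end checks use the
  plane-segmented mask directly.
* Both `net_total` and `mean_net` are emitted per measurement;
  `net_total` is the headline column (fold changes on noiseless
  synthetic growth recover the true amplitude ratio with it, since blob
  integral scales with amplitude while mask area does not stay fixed).

## Problem sizes in the shipped tests

The test suite and the acceptance script run entirely on the synthetic
module: 32×32 surfaces for threshold-oracle equivalence (20 seeds),
96×96 scenes for measurement recovery, 100-seed Monte-Carlo for noisy
fold-change recovery (noise sd 5% of amplitude), and 50-seed series of
12 phantom repositionings. These sizes give Monte-Carlo intervals a few
tenths of a percent wide for the recovered quantities while keeping the
whole suite in the tens of seconds on a single core.

## Limitations

Absolute intensity calibration across platforms is out of scope — raw
units are platform-specific and only within-platform comparisons (fold
changes, CVs, detection days) are meaningful. The package formalizes
detection with a k·sd rule whose calls need not coincide with visual
judgements near the detection limit. Proprietary acquisition formats are
not read; images must be exported as plain grayscale TIFF.
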