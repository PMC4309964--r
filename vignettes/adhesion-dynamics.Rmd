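---
title: "Quantifying cell-matrix adhesion turnover from fluorescence time-lapse movies"
author: "AdhesionDynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-matrix adhesion turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cell-matrix adhesions (focal adhesions) are the multiprotein contacts
through which a migrating cell grips its substrate. When an adhesion
marker such as paxillin or vinculin carries a GFP tag, each adhesion
appears as a bright punctum or streak whose integrated fluorescence rises
as the adhesion assembles and falls as it disassembles. Quantifying that
turnover by hand - outlining each adhesion, reading off its intensity at
every timepoint, fitting rates - is slow and subjective, and becomes
prohibitive for cells embedded in 3D matrices where adhesions also move
between focal planes.

`AdhesionDynamics` automates the whole chain: detection, segmentation,
tracking through time (and through z for volumetric movies), and kinetic
analysis, with a synthetic-movie generator that provides exact ground
truth so every stage can be validated without microscopy data.

## The segmentation model

Each frame is processed independently before regions are linked:

1. **Gaussian smoothing** (`gaussianSmooth`, default sigma = 1 px)
   suppresses camera noise. The kernel is truncated at 4 sigma and
   normalized, so constant regions pass through unchanged.
2. **Illumination correction** (`correctIllumination`) divides the
   smoothed frame by a low-pass filtered copy of itself. Background
   pixels map to values near 1 and bright structures above 1, removing
   slow illumination gradients. The low-pass stage is a uniform box mean
   (default side 51 px); a Gaussian low-pass is available via
   configuration. The kernel must be large relative to the adhesion
   diameter, or the filter starts tracking the adhesions themselves and
   the division flattens them away.
3. **Local-mean adaptive thresholding** (`localThresholdAdhesions`)
   classifies a pixel as an adhesion pixel when its value is *strictly*
   greater than the mean of its local neighbourhood (default 15 px,
   center pixel included) plus an offset. Strict inequality means a
   perfectly flat region yields no detections. The offset (default 0) is
   the user's sensitivity knob; on noisy movies it should sit a few
   noise standard deviations above zero (in corrected-image units, where
   the background is about 1).
4. **Global cell thresholding** (`globalThresholdCell`) finds the cell
   outline on the corrected image, either at a user-supplied intensity
   or by Otsu's method from the frame histogram. By default the largest
   connected component is kept and holes are filled (both switchable),
   since one movie frames one cell. Adhesion pixels are then restricted
   to the cell mask, and connected components smaller than
   **1 um^2** (configurable) are removed as sub-resolution noise - at
   0.25 um/px that is a 16-pixel cutoff. The area filter runs *after*
   the cell-mask intersection, matching the order in which the masks are
   combined before export.

All filters use mirror (symmetric) border padding so frame edges do not
acquire dark rims that would distort the division or the local means.
The guard term in the division defaults to 1e-6 x max(frame), which
keeps truly empty regions finite while leaving the correction invariant
to global intensity rescaling. Kernel sizes and thresholds are
deliberately user-designated throughout: magnification, expression level
and noise differ between experiments, and no fixed setting suits all.

Measurements per region: pixel count, physical area, unweighted 0-based
centroid (intensity-weighted centroids are available by measuring on a
weight image, but the default follows plain geometric centroids), and
integrated intensity summed over the region on both the corrected and
the raw frame.

## Tracking

Regions in consecutive frames are linked by a **greedy nearest-neighbour
rule on centroid distance in micrometres**: the globally closest pair is
matched first, each region is used at most once, and pairs farther apart
than `maxLinkUm` (default 2 um) are never matched. We use the greedy
capped rule rather than a globally optimal assignment because it is the
faithful baseline for a nearest-neighbour tracker; in the regime the
tracker targets (inter-adhesion spacing well above the per-frame
displacement) the two coincide, and a property test verifies both that
coincidence and >= 95% agreement on randomly displaced consecutive-frame
instances.

The split rule falls out of the same matching: when one adhesion splits,
the child that remained closest to the parent's previous position keeps
the parent's ID and the other child starts a new ID. Merges mirror it:
the closer parent's ID continues, the other track ends. Ties are broken
by lower label index, then lower ID, so results are deterministic.

There is **no gap closing**: a missed detection terminates a track and a
redetection starts a fresh ID. Users of interactive trackers commonly
repair such events by hand; this package instead reports honest
fragments (and `filterTracks`/`min_track_len`, default 3 observations,
drops fragments too short to analyze - at reporting time only, so
internal book-keeping stays complete).

**Lifetime** is occupancy time: (number of observed frames) x dt. A
single-frame detection therefore has lifetime dt, not zero, consistent
with "total time the adhesion was observed".

### Volumetric movies

For z-stack time-lapse data the pipeline segments every z-plane of every
timepoint independently, then merges per-plane regions into 3D adhesions
(`groupZ`): regions in *adjacent* planes whose lateral centroid distance
is within `zLinkRadiusUm` (default 1 um) belong to one adhesion, closed
transitively across consecutive planes. With the usual 0.5 um z-step an
adhesion spans a handful of consecutive planes, which is why only
adjacent planes link directly. A 3D object reports the mean of its
member centroids, the **mean of its member planes' integrated
intensities** (the z-averaged intensity), and its maximal single-plane
area. The 3D objects are then linked through time by nearest 3D centroid
(lateral um, z via the z-step), so an adhesion drifting through focal
planes keeps one identity. Grouping precedes temporal linking; a
simultaneous formulation would couple all planes and frames and buys
nothing at these densities.

## Turnover kinetics

For an intensity series I(t) covering one phase, with I0 the first
intensity of the phase, the package fits ordinary least squares in log
space, exactly as one would lay a linear trendline on a semilog plot:

- assembly: ln(I/I0) = k t + b
- disassembly: ln(I0/I) = k t + b

The slope k (per minute) is the apparent first-order rate constant and
the half-life is **t1/2 = ln(2)/k**. R^2 is the ordinary coefficient of
determination of that regression. A non-positive slope means the trace
is not actually growing (or decaying); such fits are returned flagged
rather than converted into a negative half-life. Because the transform
uses intensity ratios, k, t1/2 and R^2 are invariant to rescaling the
intensities - bit depth and exposure drop out.

Two practical points:

- **Which intensity series to fit.** The illumination-corrected image is
  a ratio image: multiplying a frame by a constant leaves it unchanged.
  That is exactly what makes it good for segmentation and bad for
  kinetics - part of an adhesion's amplitude change is divided away, and
  the summed corrected intensity rides on a +1-per-pixel background
  pedestal. Kinetics therefore default to the raw-image integrated
  intensities (`kineticsIntensity = "raw"`), optionally after
  adjacent-background subtraction (`subtractAdjacentBackground`), which
  mirrors the manual workflow of placing a duplicate region beside the
  adhesion and subtracting its series. Timepoints whose corrected value
  is not positive are flagged invalid and excluded rather than aborting
  the trace (a log-domain requirement). The exported track CSV carries
  the corrected intensities by default (they are what the segmentation
  saw); `intensity = "raw"` switches the column.
- **Choosing the fit window.** Historically assembling and disassembling
  adhesions were selected by eye. `extractPhases` automates a proxy:
  smooth the series with a 3-point moving average, take maximal runs of
  at least `min_run` (default 5) consecutive non-decreasing
  (non-increasing) timepoints, and where candidate runs overlap by more
  than a shared endpoint keep the longer. The fit then uses the
  original, unsmoothed intensities at those timepoints. This is a stated
  proxy, not a reconstruction of anyone's manual choices, so a manual
  bypass exists: supply explicit per-adhesion frame windows
  (`kineticsWindows`) and the extractor is skipped.

Summaries (`summarizeTracks`) report the adhesion count, mean +/- SEM of
lifetime and of adhesion size (a track's mean area), lifetime and size
histograms as percent of total adhesions (default bins 2 min and
2 um^2), and mean size per lifetime bin. With a single track the SEM is
reported absent rather than zero.

## The synthetic-movie generator

`sceneSpec`/`blobSpec`/`renderMovie` produce movies with exact ground
truth: each adhesion is an elliptical Gaussian spot (optionally oriented
along a "fiber" direction) with a linear centroid drift, an exponential
peak-amplitude trajectory A(t) = A0 exp(k t) (k = 0 gives a static
adhesion), and, in volumetric scenes, a Gaussian z-profile (sigma_z =
0.5 planes by default) and a z drift. Frames are background (constant
plus linear or parabolic illumination gradient) + sum of blobs +
Gaussian read noise (optionally Poisson), clipped at zero. A fixed seed
reproduces the movie bit for bit.

Defaults mirror the imaging regime the platform targets: dt = 1 min
(typical acquisitions run at 45 s - 1 min), dz = 0.5 um, 0.2 um/px,
blob footprints giving areas of roughly 1-12 um^2, rate constants giving
half-lives of a few to ~20 minutes, and read noise at 2% of the peak
amplitude. Footprints are truncated at 4 lateral sigma (3 sigma in z) so
blobs have finite support; the truth tables list, per frame, the exact
centroid, the half-max footprint area, the blob's own integrated
intensity (z-averaged over member planes in 3D, member = planes at >=
10% of the peak plane amplitude), and the planted k and t1/2.
`renderSplitEvent` schedules a parent splitting into two children and
records which child is nearer (the expected ID keeper), whether the
offsets tie, and whether the event clears a 5-sigma detectability bar
(undetectable events are marked for exclusion from scoring).

What the generator does *not* emulate: realistic optics (no PSF model,
no depth-dependent aberrations), collagen-fiber background structure,
photobleaching, or adhesion shape change during maturation. Passing the
synthetic validation therefore demonstrates that the algorithms are
correct under their stated assumptions - well-separated blob-like
objects, slow drift, multiplicative-exponential intensity dynamics - not
that any particular microscope's movies will segment well with default
settings. On real data the user-designated kernels and thresholds, and
the overlay images written for manual inspection, remain essential.

## Numerical and design choices, in one place

- Mirror border padding for all filters (no dark rims at frame edges).
- Local mean includes the center pixel; comparison is strictly greater.
- Division guard epsilon = 1e-6 x max(frame), resolved per frame.
- Otsu threshold maximizes between-class variance on a 256-bin
  histogram; ties take the lowest cut.
- Component labels are assigned in raster-scan order of each component's
  first pixel; connectivity defaults to 8 so adhesions elongated along
  diagonal fibers do not fragment (4 is available).
- Greedy matching ties: lower label index, then lower ID.
- IDs are assigned in order of first appearance, frame-major then label
  order.
- TIFF pages are taken t-major (t0z0, t0z1, ...) by default; a config
  switch (`page_order: zt`) flips to z-major. Volumetric mode is always
  explicit, never inferred from page counts.
- Intensities are used as stored - 8/16-bit pages keep native counts,
  float pages are untouched; no bit-depth rescaling. Ratio-based
  kinetics make absolute scale irrelevant.
- CSV output is written with fixed formatting (up to 10 significant
  digits), sorted on stable keys, so identical configurations and seeds
  give byte-identical files.

## Validation scale

The test suite validates every image operator against independent
brute-force references on hundreds of random frames up to 16 x 16,
tracks 5-15 planted blobs across 50 seeded 96 x 96 movies of 10 frames,
runs split-event fixtures over 8 orientations, checks exact kinetics
recovery for noiseless exponentials across k in [0.01, 1] per minute,
recovers half-lives within 10% median relative error under 10%
multiplicative lognormal noise (500 replicates per rate), and exercises
the volumetric pipeline on a zero-noise 7-plane fixture whose blob
drifts one focal plane per frame. These sizes keep the full suite in the
low minutes on a single core while leaving no stage untested.

## Known limitations

- No gap closing or motion model: transient detection dropouts fragment
  tracks by design.
- Touching adhesions are not split by watershed; they merge into one
  region until they separate.
- The greedy matcher can differ from the globally optimal assignment
  when adhesions pack within a frame's displacement scale of each other.
- Phase extraction is a monotone-run heuristic; for publication-grade
  rate constants on real data, inspect the overlays and prefer explicit
  fit windows.
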