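# AdhesionDynamics

Automated analysis of cell-matrix adhesion dynamics in fluorescence
time-lapse microscopy, for cell biologists studying adhesion turnover
during migration - on 2D substrates (e.g. TIRF movies of GFP-paxillin or
GFP-vinculin cells) and in 3D matrices (spinning-disk z-series of cells
embedded in collagen).

Manually outlining adhesions, reading their intensities at every
timepoint and fitting rates is slow and subjective. This package
automates the chain end to end:

1. **Segmentation** - Gaussian smoothing; illumination correction by
   dividing each frame with a low-pass filtered copy of itself;
   local-mean adaptive thresholding (a pixel strictly brighter than its
   neighbourhood mean is an adhesion pixel); a global cell threshold
   restricting detections to the cell; removal of objects below 1 um^2.
2. **Tracking** - capped greedy nearest-neighbour linking of region
   centroids through time; for volumetric movies, per-plane regions are
   first merged across adjacent z-planes and the 3D objects are linked
   through time, so adhesions moving between focal planes keep one ID.
   When an adhesion splits, the child closest to the parent's previous
   position keeps the ID; the other child gets a new one.
3. **Kinetics** - for each assembly (disassembly) phase, ordinary least
   squares on the semilog transform ln(I/I0) (ln(I0/I)) versus time:
   the slope is the apparent first-order rate constant *k* (min^-1),
   the half-life is

   t<sub>1/2</sub> = ln(2) / k

   with the fit's R^2 as the quality measure, plus lifetime and size
   summaries and histograms.
4. **Synthetic ground truth** - a seeded generator renders 2D and 4D
   movies of Gaussian "adhesions" with exponential intensity dynamics,
   drift (including through z), uneven illumination and camera noise,
   together with exact truth tables, so every stage is testable without
   microscopy data.

## Worked example

Render a small synthetic movie with three planted adhesions (one
assembling at k = 0.10/min, one disassembling at k = 0.05/min, one
static), run the full pipeline, and inspect the results:

```r
library(AdhesionDynamics)

blobs <- list(
  blobSpec(x0 = 16, y0 = 16, amplitude0 = 400, kPerMin =  0.10, sigmaXPx = 1.7),
  blobSpec(x0 = 48, y0 = 20, amplitude0 = 400, kPerMin = -0.05, sigmaXPx = 1.7),
  blobSpec(x0 = 30, y0 = 46, amplitude0 = 400, kPerMin =  0,    sigmaXPx = 2.0))
scene <- sceneSpec(64, 64, 12, blobs = blobs,
                   background = list(constant = 40), seed = 7)
movie <- renderMovie(scene)
movie$stack
#> ImageStack (planar): 64 x 64 px, 12 frames
#>   calibration: 0.2 um/px, dt = 60 s
#>   intensity range: [8.301, 1237]

cfg <- runConfig(input = movie$stack, mode = "2d",
                 outputDir = tempfile(), seed = 7,
                 preprocess = preprocessConfig(lowpassKernelPx = 31),
                 segment = segmentConfig(localKernelPx = 15,
                                         localOffset = 0.6,
                                         cellThreshold = 0))
res <- runPipeline(cfg)
res$tracks
#> AdhesionTrackSet: 3 tracks, 36 observations, dt = 60 s
#>   lifetimes: 12-12 min (mean 12)
res$summary
#> Adhesion summary
#>   n adhesions:    3
#>   lifetime (min): 12 +/- 0
#>   size (um2):     1.76 +/- 0.11
res$fits[, c("adhesion_id", "phase", "k_per_min", "t_half_min", "r_squared")]
#>   adhesion_id       phase  k_per_min t_half_min r_squared
#> 1           1    assembly 0.09410621   7.365584 0.9993192
#> 2           2 disassembly 0.04549588  15.235383 0.9940744
```

All three planted adhesions are detected and tracked for the full 12
minutes. The automatic phase extractor finds the assembling and
disassembling adhesions (the static one has no monotone run) and the
semilog fits recover the planted rate constants to within a few percent
- the residual bias comes from the background pedestal inside each
region's footprint, which the adjacent-background subtraction mode
(`subtractAdjacentBackground`) removes in the manual-parity workflow.
The output directory contains `tracks.csv` (fixed schema
`adhesion_id,t_index,time_min,centroid_x_px,centroid_y_px,centroid_z_index,area_um2,integrated_intensity`),
`kinetics.csv`, `summary.csv` and a run log; overlay PNGs with region
outlines and ID numbers are one flag away (`writeOverlays = TRUE`).

A thin command-line front end with `run`, `synth`, `fit` and `overlay`
subcommands lives in `inst/scripts/adhesion-pipeline.R`, driven by a
YAML configuration (see `inst/extdata/example_config.yaml`).

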