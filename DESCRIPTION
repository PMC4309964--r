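Package: AdhesionDynamics
Title: Segmentation, Tracking and Turnover Kinetics of Cell-Matrix Adhesions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated analysis of fluorescently labeled cell-matrix
    adhesions in 2D time-lapse and 3D (z-stack) time-lapse fluorescence
    microscopy. Frames are Gaussian-smoothed, corrected for uneven
    illumination by division with a low-pass filtered copy, and adhesion
    pixels are detected by local-mean adaptive thresholding restricted to a
    globally thresholded cell mask, with sub-resolution objects removed.
    Labeled adhesions are linked through time (and through z-planes for
    volumetric movies) with a capped nearest-neighbour algorithm including
    an explicit split rule, yielding per-adhesion tracks of centroid, area
    and integrated intensity. Assembly and disassembly rate constants are
    estimated from semilogarithmic intensity fits, with half-lives
    t1/2 = ln(2)/k, plus lifetime and size summaries. A synthetic movie
    generator with exact ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AdhesionDynamics-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'ImageStack-methods.R'
    'RegionSet-methods.R'
    'preprocess.R'
    'segment.R'
    'io.R'
    'track.R'
    'kinetics.R'
    'synth.R'
    'pipeline.R'
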