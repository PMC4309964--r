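#' @include preprocess.R AllClasses.R
NULL

#' Segmentation configuration
#'
#' Kernel sizes and thresholds are deliberately user-designated: image
#' scale, labeling density and noise vary between experiments, so no
#' single setting suits all movies. The local kernel should be comparable
#' to (or slightly larger than) the adhesion diameter in pixels; the
#' default of 15 px suits adhesions of a few um2 sampled at ~0.2 um/px.
#'
#' @param localKernelPx side of the local-mean neighbourhood, odd integer
#'   >= 3. Default 15.
#' @param localOffset sensitivity offset added to the local mean before
#'   comparison (>= 0, in corrected-image units). Default 0: any pixel
#'   strictly brighter than its neighbourhood mean is an adhesion pixel.
#'   Raise it to reject noise on noisy movies.
#' @param cellThreshold global threshold defining the cell mask on the
#'   corrected image: a finite number, or `"otsu"` (default) to derive it
#'   from the frame histogram.
#' @param minAreaUm2 objects smaller than this are excluded (default
#'   1 um2), which removes background noise specks below adhesion scale.
#' @param connectivity pixel connectivity for components, 4 or 8
#'   (default 8: elongated adhesions along diagonal fibers should not
#'   fragment).
#' @param cellKeepLargest keep only the largest connected component of the
#'   cell mask (default TRUE; a movie frames a single cell).
#' @param cellFillHoles fill enclosed holes in the cell mask
#'   (default TRUE).
#' @return a validated list of class `segmentConfig`.
#' @export
segmentConfig <- function(localKernelPx = 15L, localOffset = 0,
                          cellThreshold = "otsu", minAreaUm2 = 1.0,
                          connectivity = 8L, cellKeepLargest = TRUE,
                          cellFillHoles = TRUE) {
    stopIfNotOddKernel(localKernelPx, "local threshold kernel")
    if (!is.finite(localOffset) || localOffset < 0)
        stop("localOffset must be >= 0", call. = FALSE)
    if (!(identical(cellThreshold, "otsu") ||
          (is.numeric(cellThreshold) && length(cellThreshold) == 1L &&
           is.finite(cellThreshold))))
        stop("cellThreshold must be a finite number or \"otsu\"",
             call. = FALSE)
    if (!is.finite(minAreaUm2) || minAreaUm2 <= 0)
        stop("minAreaUm2 must be > 0", call. = FALSE)
    if (!connectivity %in% c(4, 8))
        stop("connectivity must be 4 or 8", call. = FALSE)
    structure(list(localKernelPx = as.integer(localKernelPx),
                   localOffset = localOffset,
                   cellThreshold = cellThreshold,
                   minAreaUm2 = minAreaUm2,
                   connectivity = as.integer(connectivity),
                   cellKeepLargest = isTRUE(cellKeepLargest),
                   cellFillHoles = isTRUE(cellFillHoles)),
              class = "segmentConfig")
}

#' Local-mean adaptive threshold for adhesion pixels
#'
#' A pixel is classified as an adhesion pixel when its intensity is
#' strictly higher than the mean of its local neighbourhood (plus an
#' optional offset); otherwise it belongs to the background class. The
#' local mean includes the center pixel and uses mirror border padding.
#' Strict inequality means constant regions yield no detections.
#'
#' @param frame corrected 2D matrix.
#' @param cfg a [segmentConfig()].
#' @return logical matrix: TRUE = adhesion pixel.
#' @examples
#' f <- matrix(1, 5, 5); f[3, 3] <- 10
#' localThresholdAdhesions(f, segmentConfig(localKernelPx = 3))
#' @export
localThresholdAdhesions <- function(frame, cfg = segmentConfig()) {
    frame <- asFrameMatrix(frame)
    lm <- boxMean(frame, cfg$localKernelPx)
    frame > lm + cfg$localOffset
}

#' Otsu threshold of a frame histogram
#'
#' Maximizes the between-class variance over a fixed-width histogram of
#' the frame values; returns the intensity cut so that
#' `frame >= threshold` selects the bright class. Ties take the lowest
#' cut.
#'
#' @param frame 2D matrix.
#' @param nBins histogram resolution (default 256).
#' @return a single threshold value.
#' @export
otsuThreshold <- function(frame, nBins = 256L) {
    v <- as.vector(asFrameMatrix(frame))
    mn <- min(v); mx <- max(v)
    if (mx == mn) return(mx)
    w <- (mx - mn) / nBins
    bin <- pmin(as.integer(floor((v - mn) / w)) + 1L, nBins)
    counts <- tabulate(bin, nBins)
    centers <- mn + (seq_len(nBins) - 0.5) * w
    total <- length(v)
    cum <- cumsum(counts)
    cumMean <- cumsum(counts * centers)
    grand <- cumMean[nBins]
    cuts <- seq_len(nBins - 1L)
    w0 <- cum[cuts]; w1 <- total - w0
    valid <- w0 > 0 & w1 > 0
    bcv <- rep(-Inf, nBins - 1L)
    mu0 <- cumMean[cuts][valid] / w0[valid]
    mu1 <- (grand - cumMean[cuts][valid]) / w1[valid]
    bcv[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
    cut <- which.max(bcv)
    mn + cut * w
}

#' Global intensity threshold for the cell mask
#'
#' The cell outline is detected by thresholding the corrected image with a
#' global intensity threshold: `mask = frame >= threshold`. With
#' `cellThreshold = "otsu"` the threshold is computed from the frame
#' histogram.
#'
#' @param frame corrected 2D matrix.
#' @param cfg a [segmentConfig()].
#' @return logical matrix: TRUE = inside the cell.
#' @export
globalThresholdCell <- function(frame, cfg = segmentConfig()) {
    frame <- asFrameMatrix(frame)
    thr <- if (identical(cfg$cellThreshold, "otsu"))
        otsuThreshold(frame) else cfg$cellThreshold
    frame >= thr
}

#' Restrict adhesion pixels to the cell
#'
#' Logical AND of the adhesion mask with the cell mask, so detections
#' outside the cell outline are discarded.
#'
#' @param adhesionMask,cellMask logical matrices of identical shape.
#' @return logical matrix.
#' @export
combineMasks <- function(adhesionMask, cellMask) {
    if (!identical(dim(adhesionMask), dim(cellMask)))
        stop("mask shapes differ", call. = FALSE)
    adhesionMask & cellMask
}

#' Connected-component labeling
#'
#' Labels connected foreground components under 4- or 8-connectivity.
#' Labels are contiguous from 1 in raster-scan order of each component's
#' first (topmost, then leftmost) pixel, so output is deterministic.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels; 0 = background.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
    if (!connectivity %in% c(4, 8))
        stop("connectivity must be 4 or 8", call. = FALSE)
    mask <- mask != 0
    n <- nrow(mask); p <- ncol(mask)
    out <- matrix(0L, n, p)
    if (!any(mask)) return(out)
    ## iterative minimum-seed diffusion to the component fixpoint
    idx <- matrix(Inf, n, p)
    idx[mask] <- (row(mask)[mask] - 1) * p + col(mask)[mask]
    shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    if (connectivity == 8)
        shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
    repeat {
        nxt <- idx
        for (s in shifts)
            nxt <- pmin(nxt, shiftMat(idx, s[1], s[2], fill = Inf))
        nxt[!mask] <- Inf
        if (identical(nxt, idx)) break
        idx <- nxt
    }
    seeds <- sort(unique(idx[mask]))
    out[mask] <- match(idx[mask], seeds)
    out
}

## Keep the largest component (ties: lowest label, i.e. raster-first).
keepLargestComponent <- function(mask, connectivity = 8L) {
    lab <- labelComponents(mask, connectivity)
    if (max(lab) == 0L) return(mask & FALSE)
    counts <- tabulate(lab[lab > 0L])
    lab == which.max(counts)
}

## Fill holes: background components not reachable from the border.
fillHoles <- function(mask) {
    bg <- labelComponents(!mask, connectivity = 4L)
    border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    border <- border[border > 0L]
    mask | (bg > 0L & !(bg %in% border))
}

#' Remove sub-resolution objects
#'
#' Excludes connected components whose physical area (pixel count x
#' pixelSizeUm^2) is below `minAreaUm2`, eliminating background noise from
#' the analysis; components at or above the cutoff pass unchanged. At
#' 0.25 um/px and the default 1 um2 this removes objects of 15 px or
#' fewer and keeps 16 px objects.
#'
#' @param mask logical matrix.
#' @param pixelSizeUm micrometres per pixel (> 0).
#' @param minAreaUm2 area cutoff in um2 (default 1).
#' @param connectivity 4 or 8 (default 8).
#' @return logical matrix with small components removed.
#' @export
filterSmallObjects <- function(mask, pixelSizeUm, minAreaUm2 = 1.0,
                               connectivity = 8L) {
    if (!is.finite(pixelSizeUm) || pixelSizeUm <= 0)
        stop("pixelSizeUm must be > 0", call. = FALSE)
    lab <- labelComponents(mask, connectivity)
    if (max(lab) == 0L) return(mask != 0)
    areas <- tabulate(lab[lab > 0L]) * pixelSizeUm^2
    keep <- which(areas >= minAreaUm2)
    lab %in% keep & lab > 0L
}

#' Label a mask and measure its regions
#'
#' Connected-component labeling plus per-region measurements: pixel count,
#' physical area, unweighted 0-based centroid, and integrated intensity
#' (sum over the region) on the measurement frame and, optionally, on the
#' raw frame.
#'
#' @param mask logical matrix of adhesion pixels.
#' @param measurementFrame frame whose intensities are summed per region
#'   (the corrected image in the standard pipeline).
#' @param pixelSizeUm micrometres per pixel.
#' @param connectivity 4 or 8 (default 8).
#' @param rawFrame optional second measurement frame (the raw image); when
#'   omitted, raw sums repeat the measurement-frame sums.
#' @return a [RegionSet-class].
#' @examples
#' m <- matrix(FALSE, 5, 5); m[2:3, 2:3] <- TRUE
#' f <- matrix(5, 5, 5)
#' regionTable(labelAndMeasure(m, f, pixelSizeUm = 0.2))
#' @export
labelAndMeasure <- function(mask, measurementFrame, pixelSizeUm,
                            connectivity = 8L, rawFrame = NULL) {
    measurementFrame <- asFrameMatrix(measurementFrame)
    if (!identical(dim(mask), dim(measurementFrame)))
        stop("mask and measurement frame shapes differ", call. = FALSE)
    if (is.null(rawFrame)) rawFrame <- measurementFrame
    rawFrame <- asFrameMatrix(rawFrame)
    if (!identical(dim(mask), dim(rawFrame)))
        stop("mask and raw frame shapes differ", call. = FALSE)
    lab <- labelComponents(mask, connectivity)
    k <- max(lab)
    if (k == 0L) {
        reg <- data.frame(label = integer(), n_pixels = integer(),
                          area_um2 = numeric(), centroid_x_px = numeric(),
                          centroid_y_px = numeric(),
                          integrated_intensity = numeric(),
                          integrated_intensity_raw = numeric())
        return(new("RegionSet", labels = lab, regions = reg,
                   pixelSizeUm = pixelSizeUm))
    }
    fg <- lab > 0L
    l <- lab[fg]
    counts <- tabulate(l, k)
    ## 0-based geometric centroids
    cx <- tapply((col(lab)[fg] - 1), l, mean)
    cy <- tapply((row(lab)[fg] - 1), l, mean)
    ii <- tapply(measurementFrame[fg], l, sum)
    iir <- tapply(rawFrame[fg], l, sum)
    reg <- data.frame(label = seq_len(k), n_pixels = counts,
                      area_um2 = counts * pixelSizeUm^2,
                      centroid_x_px = as.numeric(cx),
                      centroid_y_px = as.numeric(cy),
                      integrated_intensity = as.numeric(ii),
                      integrated_intensity_raw = as.numeric(iir))
    new("RegionSet", labels = lab, regions = reg, pixelSizeUm = pixelSizeUm)
}

#' Segment one frame end to end
#'
#' The full per-frame segmentation chain: Gaussian smoothing,
#' illumination correction by low-pass division, local-mean adhesion
#' thresholding, global cell thresholding, mask combination, and removal
#' of objects below the minimum area (applied after the cell-mask
#' intersection). Measurements are taken on the corrected image, with raw
#' sums carried alongside.
#'
#' @param rawFrame raw 2D frame.
#' @param pixelSizeUm micrometres per pixel.
#' @param preCfg a [preprocessConfig()].
#' @param segCfg a [segmentConfig()].
#' @return list with `regions` ([RegionSet-class]), `corrected` frame,
#'   `adhesionMask` (final), and `cellMask`.
#' @export
segmentFrame <- function(rawFrame, pixelSizeUm,
                         preCfg = preprocessConfig(),
                         segCfg = segmentConfig()) {
    pp <- preprocessFrame(rawFrame, preCfg)
    adh <- localThresholdAdhesions(pp$corrected, segCfg)
    cell <- globalThresholdCell(pp$corrected, segCfg)
    if (segCfg$cellKeepLargest && any(cell))
        cell <- keepLargestComponent(cell, segCfg$connectivity)
    if (segCfg$cellFillHoles) cell <- fillHoles(cell)
    mask <- combineMasks(adh, cell)
    mask <- filterSmallObjects(mask, pixelSizeUm, segCfg$minAreaUm2,
                               segCfg$connectivity)
    regions <- labelAndMeasure(mask, pp$corrected, pixelSizeUm,
                               segCfg$connectivity,
                               rawFrame = asFrameMatrix(rawFrame))
    list(regions = regions, corrected = pp$corrected,
         adhesionMask = mask, cellMask = cell)
}
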