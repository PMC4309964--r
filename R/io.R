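#' @include AllClasses.R segment.R
NULL

trackCsvColumns <- c("adhesion_id", "t_index", "time_min", "centroid_x_px",
                     "centroid_y_px", "centroid_z_index", "area_um2",
                     "integrated_intensity")

#' Read a calibrated multi-page TIFF stack
#'
#' Reads a grayscale multi-page TIFF into an [ImageStack-class].
#' Intensities are used exactly as stored (integer pages keep their native
#' values; float pages are untouched) - no bit-depth rescaling, since the
#' downstream kinetics work on intensity ratios.
#'
#' For volumetric movies, declare the number of z-planes: the page count
#' must be divisible by it. Pages are taken t-major by default
#' (t0z0, t0z1, ..., t1z0, ... - the common acquisition order);
#' `pageOrder = "zt"` flips to z-major.
#'
#' @param path TIFF file path.
#' @param pixelSizeUm micrometres per pixel (> 0).
#' @param dtS seconds between frames (> 0).
#' @param dzUm micrometres between z-planes (> 0, volumetric only).
#' @param zCount declared number of z-planes per timepoint (volumetric
#'   only; both `dzUm` and `zCount` must be given together).
#' @param pageOrder `"tz"` (default, t-major pages) or `"zt"` (z-major).
#' @return an [ImageStack-class].
#' @export
readStack <- function(path, pixelSizeUm, dtS, dzUm = NULL, zCount = NULL,
                      pageOrder = c("tz", "zt")) {
    pageOrder <- match.arg(pageOrder)
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    if (is.null(dzUm) != is.null(zCount))
        stop("dzUm and zCount must be given together for volumetric stacks",
             call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (any(!vapply(pages, is.matrix, logical(1))))
        stop("non-grayscale TIFF pages are not supported", call. = FALSE)
    ## 8/16-bit pages come back scaled to [0,1]: restore native integer
    ## counts. 32-bit pages are floating point and already native.
    pages <- lapply(pages, function(pg) {
        bits <- attr(pg, "bits.per.sample")
        if (!is.null(bits) && bits %in% c(8L, 16L))
            pg <- round(pg * (2^bits - 1))
        pg
    })
    dims <- vapply(pages, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
        stop("all pages must share identical spatial dimensions",
             call. = FALSE)
    np <- length(pages)
    ny <- dims[1, 1]; nx <- dims[2, 1]
    flat <- array(unlist(pages), c(ny, nx, np))
    if (is.null(zCount)) {
        return(ImageStack(flat, pixelSizeUm, dtS))
    }
    zCount <- as.integer(zCount)
    if (np %% zCount != 0)
        stop(sprintf("page count (%d) is not divisible by z-count (%d)",
                     np, zCount), call. = FALSE)
    nt <- np %/% zCount
    data <- array(0, c(ny, nx, zCount, nt))
    for (t in seq_len(nt)) for (z in seq_len(zCount)) {
        page <- if (pageOrder == "tz") (t - 1L) * zCount + z
                else (z - 1L) * nt + t
        data[, , z, t] <- flat[, , page]
    }
    ImageStack(data, pixelSizeUm, dtS, dzUm)
}

#' Write an ImageStack to a multi-page TIFF
#'
#' Pages are written t-major (z fastest for volumetric stacks) as 32-bit
#' float. TIFF viewers expect values in `[0, 1]`, so by default the stack
#' is divided by its maximum before writing; set `normalize = FALSE` if
#' the data already lie in `[0, 1]`. The scaling is a global constant and
#' does not affect ratio-based kinetics.
#'
#' @param stack an [ImageStack-class].
#' @param path output TIFF path.
#' @param normalize divide by the stack maximum before writing (default
#'   TRUE).
#' @return the path, invisibly.
#' @export
writeStack <- function(stack, path, normalize = TRUE) {
    stopifnot(is(stack, "ImageStack"))
    d <- stack@data
    if (normalize && max(d) > 0) d <- d / max(d)
    pages <- list()
    if (isVolumetric(stack)) {
        i <- 1L
        for (t in seq_len(nFrames(stack)))
            for (z in seq_len(nPlanes(stack))) {
                pages[[i]] <- d[, , z, t]
                i <- i + 1L
            }
    } else {
        for (t in seq_len(nFrames(stack))) pages[[t]] <- d[, , t]
    }
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    invisible(path)
}

#' Export a track table to CSV
#'
#' Writes one row per (adhesion, timepoint), sorted by `adhesion_id` then
#' `t_index`, with the fixed header
#' `adhesion_id,t_index,time_min,centroid_x_px,centroid_y_px,centroid_z_index,area_um2,integrated_intensity`.
#' `centroid_z_index` is empty for planar movies. Output bytes are
#' deterministic for a given table.
#'
#' @param tracks an [AdhesionTrackSet-class] or a data.frame already in
#'   the export schema.
#' @param path output CSV path.
#' @param intensity which integrated intensity to export when `tracks` is
#'   an `AdhesionTrackSet`: `"corrected"` (default; measured on the
#'   illumination-corrected image) or `"raw"`.
#' @param comments character vector written as leading `# ` comment lines
#'   (e.g. the run seed).
#' @return the path, invisibly.
#' @export
writeTrackTable <- function(tracks, path, intensity = c("corrected", "raw"),
                            comments = character()) {
    intensity <- match.arg(intensity)
    df <- if (is(tracks, "AdhesionTrackSet"))
        asTrackTable(tracks, intensity = intensity) else as.data.frame(tracks)
    if (!identical(names(df), trackCsvColumns))
        stop("track table must have the exact export columns: ",
             paste(trackCsvColumns, collapse = ","), call. = FALSE)
    df <- df[order(df$adhesion_id, df$t_index), , drop = FALSE]
    writeCsvDeterministic(df, path, comments)
}

#' Read a track table CSV
#'
#' Reads a CSV written by [writeTrackTable()] (leading `#` comment lines
#' are skipped) and returns the table with the exact export schema.
#'
#' @param path CSV path.
#' @return data.frame with the export columns.
#' @export
readTrackTable <- function(path) {
    df <- utils::read.csv(path, comment.char = "#",
                          colClasses = c(adhesion_id = "integer",
                                         t_index = "integer",
                                         centroid_z_index = "numeric"))
    if (!identical(names(df), trackCsvColumns))
        stop("not a track table CSV: ", path, call. = FALSE)
    df
}

#' Overlay detected region outlines on a frame
#'
#' Renders the frame as min-max normalized grayscale RGB and recolors
#' each region's boundary pixels (the region minus its 4-neighbour
#' erosion). With `showIds`, the region's label number is stamped at its
#' centroid with a small bitmap font. Pure function: neither the frame
#' nor the regions are modified.
#'
#' @param frame 2D matrix the regions were computed from.
#' @param regions a [RegionSet-class] of identical shape.
#' @param showIds draw ID numbers at centroids (default FALSE).
#' @param boundaryCol RGB triple in `[0, 1]` for outlines (default green).
#' @param idCol RGB triple for ID text (default yellow).
#' @return `[y, x, 3]` array in `[0, 1]`.
#' @export
renderOverlay <- function(frame, regions, showIds = FALSE,
                          boundaryCol = c(0, 1, 0), idCol = c(1, 1, 0)) {
    frame <- asFrameMatrix(frame)
    stopifnot(is(regions, "RegionSet"))
    lab <- labelImage(regions)
    if (!identical(dim(frame), dim(lab)))
        stop("frame and regions shapes differ", call. = FALSE)
    g <- normalize01(frame)
    rgb <- array(g, c(dim(g), 3L))
    if (nRegions(regions) > 0) {
        fg <- lab > 0L
        boundary <- matrix(FALSE, nrow(lab), ncol(lab))
        for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
            boundary <- boundary | (shiftMat(lab, s[1], s[2], fill = 0) != lab)
        boundary <- boundary & fg
        for (ch in 1:3) {
            plane <- rgb[, , ch]
            plane[boundary] <- boundaryCol[ch]
            rgb[, , ch] <- plane
        }
        if (showIds) {
            reg <- regionTable(regions)
            for (i in seq_len(nrow(reg)))
                rgb <- drawNumber(rgb, reg$label[i],
                                  reg$centroid_y_px[i] + 1,
                                  reg$centroid_x_px[i] + 1, col = idCol)
        }
    }
    rgb
}

#' Write per-frame overlay PNGs
#'
#' One PNG per timepoint, named `<stem>_t%04d_overlay.png` (0-based frame
#' numbers), showing detected outlines over the original frame.
#'
#' @param stack a planar [ImageStack-class].
#' @param regionSets list of [RegionSet-class], one per frame.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @param showIds draw ID numbers (default FALSE).
#' @return character vector of written paths, invisibly.
#' @export
writeOverlays <- function(stack, regionSets, dir, stem = "frame",
                          showIds = FALSE) {
    stopifnot(is(stack, "ImageStack"), !isVolumetric(stack))
    if (length(regionSets) != nFrames(stack))
        stop("need one RegionSet per frame", call. = FALSE)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character(nFrames(stack))
    for (t in seq_len(nFrames(stack))) {
        img <- renderOverlay(getFrame(stack, t), regionSets[[t]], showIds)
        paths[t] <- file.path(dir, sprintf("%s_t%04d_overlay.png",
                                           stem, t - 1L))
        png::writePNG(img, paths[t])
    }
    invisible(paths)
}
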