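#' @include AllClasses.R utils.R
NULL

#' @describeIn ImageStack-class micrometres per pixel.
#' @param x an `ImageStack`.
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixelSizeUm)

#' @describeIn ImageStack-class seconds between frames.
#' @export
setMethod("frameInterval", "ImageStack", function(x) x@dtS)

#' @describeIn ImageStack-class micrometres between z-planes (NA if planar).
#' @export
setMethod("zStep", "ImageStack", function(x) x@dzUm)

#' @describeIn ImageStack-class TRUE for a z-series movie.
#' @export
setMethod("isVolumetric", "ImageStack", function(x)
    length(dim(x@data)) == 4L)

#' @describeIn ImageStack-class number of timepoints.
#' @export
setMethod("nFrames", "ImageStack", function(x) {
    d <- dim(x@data)
    d[length(d)]
})

#' @describeIn ImageStack-class number of z-planes (1 if planar).
#' @export
setMethod("nPlanes", "ImageStack", function(x) {
    d <- dim(x@data)
    if (length(d) == 4L) d[3L] else 1L
})

#' @describeIn ImageStack-class extract one frame as a `[y, x]` matrix;
#'   `t` (and `z` for volumetric stacks) are 1-based.
#' @param t 1-based timepoint index.
#' @param z 1-based z-plane index (volumetric stacks only).
#' @export
setMethod("getFrame", "ImageStack", function(x, t, z) {
    nt <- nFrames(x)
    if (t < 1L || t > nt) stop("frame index out of range", call. = FALSE)
    if (isVolumetric(x)) {
        if (missing(z)) stop("z is required for a volumetric stack",
                             call. = FALSE)
        if (z < 1L || z > nPlanes(x))
            stop("z-plane index out of range", call. = FALSE)
        x@data[, , z, t]
    } else {
        if (!missing(z) && !is.null(z))
            stop("planar stack has no z axis", call. = FALSE)
        x@data[, , t]
    }
})

setMethod("show", "ImageStack", function(object) {
    d <- dim(object@data)
    if (length(d) == 4L) {
        cat(sprintf(
            "ImageStack (volumetric): %d x %d px, %d z-planes, %d frames\n",
            d[1], d[2], d[3], d[4]))
        cat(sprintf("  calibration: %.4g um/px, dt = %.4g s, dz = %.4g um\n",
                    object@pixelSizeUm, object@dtS, object@dzUm))
    } else {
        cat(sprintf("ImageStack (planar): %d x %d px, %d frames\n",
                    d[1], d[2], d[3]))
        cat(sprintf("  calibration: %.4g um/px, dt = %.4g s\n",
                    object@pixelSizeUm, object@dtS))
    }
    cat(sprintf("  intensity range: [%.4g, %.4g]\n",
                min(object@data), max(object@data)))
})
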