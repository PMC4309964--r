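#' @include AllGenerics.R
NULL

#' ImageStack: a calibrated fluorescence time-lapse
#'
#' Container for a grayscale time-lapse movie, either planar
#' (frames indexed by time) or volumetric (a z-series per timepoint, as
#' acquired by spinning-disk confocal imaging of cells in 3D matrices).
#' Intensities are kept exactly as stored on disk: the downstream kinetics
#' work on intensity ratios, which are invariant to bit-depth scaling.
#'
#' The pixel array is laid out `[y, x, t]` (planar) or `[y, x, z, t]`
#' (volumetric), so a single frame is a contiguous matrix slice with rows
#' as image rows (y) and columns as image columns (x). Pixel coordinates
#' reported by the pipeline are 0-based.
#'
#' @slot data numeric array of finite, non-negative intensities,
#'   `[y, x, t]` or `[y, x, z, t]`.
#' @slot pixelSizeUm lateral calibration, micrometres per pixel (> 0).
#' @slot dtS frame interval in seconds (> 0).
#' @slot dzUm z-plane spacing in micrometres (> 0); `NA` for planar movies.
#'
#' @seealso [ImageStack()], [readStack()], [getFrame()]
#' @name ImageStack-class
#' @aliases ImageStack-class
#' @exportClass ImageStack
setClass("ImageStack",
    representation(
        data = "array",
        pixelSizeUm = "numeric",
        dtS = "numeric",
        dzUm = "numeric"
    ),
    prototype(
        data = array(0, c(1, 1, 1)),
        pixelSizeUm = 1,
        dtS = 60,
        dzUm = NA_real_
    )
)

setValidity("ImageStack", function(object) {
    d <- object@data
    nd <- length(dim(d))
    msgs <- character()
    if (!nd %in% c(3L, 4L))
        msgs <- c(msgs, "data must be a [y,x,t] or [y,x,z,t] array")
    if (anyNA(d) || any(!is.finite(d)))
        msgs <- c(msgs, "intensities must be finite")
    else if (any(d < 0))
        msgs <- c(msgs, "intensities must be >= 0")
    if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
        object@pixelSizeUm <= 0)
        msgs <- c(msgs, "pixelSizeUm must be a single positive number")
    if (length(object@dtS) != 1L || !is.finite(object@dtS) || object@dtS <= 0)
        msgs <- c(msgs, "dtS must be a single positive number")
    if (length(object@dzUm) != 1L)
        msgs <- c(msgs, "dzUm must be a single number (NA for planar movies)")
    else if (nd == 4L && (is.na(object@dzUm) || object@dzUm <= 0))
        msgs <- c(msgs, "volumetric stacks require dzUm > 0")
    else if (nd == 3L && !is.na(object@dzUm))
        msgs <- c(msgs, "planar stacks must have dzUm = NA")
    if (length(msgs)) msgs else TRUE
})

#' Construct an ImageStack
#'
#' @param data numeric array `[y, x, t]` (planar) or `[y, x, z, t]`
#'   (volumetric) of non-negative intensities.
#' @param pixelSizeUm micrometres per pixel (> 0).
#' @param dtS seconds between frames (> 0).
#' @param dzUm micrometres between z-planes; required for 4D data,
#'   must be omitted (`NA`) for 3D data.
#' @return an [ImageStack-class] object.
#' @examples
#' mov <- ImageStack(array(1, c(8, 8, 4)), pixelSizeUm = 0.2, dtS = 60)
#' nFrames(mov)
#' @export
ImageStack <- function(data, pixelSizeUm, dtS, dzUm = NA_real_) {
    new("ImageStack", data = data, pixelSizeUm = as.numeric(pixelSizeUm),
        dtS = as.numeric(dtS), dzUm = as.numeric(dzUm))
}

#' RegionSet: labeled adhesion regions of one frame
#'
#' Connected-component labeling of a segmented frame plus per-region
#' measurements. Labels are positive and contiguous from 1, assigned in
#' raster-scan order (topmost, then leftmost first pixel). Each region
#' record carries pixel count, physical area, 0-based unweighted centroid,
#' and integrated intensities measured on both the illumination-corrected
#' and the raw frame.
#'
#' @slot labels integer matrix, same shape as the frame; 0 = background.
#' @slot regions data.frame with columns `label`, `n_pixels`, `area_um2`,
#'   `centroid_x_px`, `centroid_y_px`, `integrated_intensity`,
#'   `integrated_intensity_raw`.
#' @slot pixelSizeUm micrometres per pixel used for areas.
#'
#' @seealso [labelAndMeasure()], [segmentFrame()]
#' @name RegionSet-class
#' @aliases RegionSet-class
#' @exportClass RegionSet
setClass("RegionSet",
    representation(
        labels = "matrix",
        regions = "data.frame",
        pixelSizeUm = "numeric"
    )
)

setValidity("RegionSet", function(object) {
    msgs <- character()
    reg <- object@regions
    need <- c("label", "n_pixels", "area_um2", "centroid_x_px",
              "centroid_y_px", "integrated_intensity",
              "integrated_intensity_raw")
    if (!all(need %in% names(reg)))
        msgs <- c(msgs, paste("regions must have columns:",
                              paste(need, collapse = ", ")))
    else {
        if (nrow(reg) > 0 && !identical(as.integer(reg$label),
                                        seq_len(nrow(reg))))
            msgs <- c(msgs, "labels must be contiguous from 1")
        lab <- object@labels
        u <- sort(unique(as.integer(lab[lab > 0])))
        if (!identical(u, as.integer(seq_len(nrow(reg)))))
            msgs <- c(msgs, "label image and region table disagree")
    }
    if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
        msgs <- c(msgs, "pixelSizeUm must be a single positive number")
    if (length(msgs)) msgs else TRUE
})

#' AdhesionTrackSet: per-adhesion observation series
#'
#' The result of nearest-neighbour linking: one row per (adhesion,
#' timepoint) observation. IDs are assigned in order of first appearance;
#' each track's `t_index` values are contiguous (a missed detection ends a
#' track). Lifetime is occupancy time: (number of observed frames) x dt,
#' so a single-frame detection has lifetime dt, not zero.
#'
#' @slot observations data.frame with columns `adhesion_id`, `t_index`,
#'   `centroid_x_px`, `centroid_y_px`, `centroid_z_index` (NA for planar
#'   movies), `z_planes` (semicolon-joined 0-based plane list, "" for
#'   planar), `area_um2`, `integrated_intensity`,
#'   `integrated_intensity_raw`.
#' @slot dtS frame interval in seconds.
#' @slot pixelSizeUm micrometres per pixel.
#' @slot dzUm z spacing in micrometres (NA for planar movies).
#'
#' @seealso [trackStack()], [buildTracks()], [lifetimes()]
#' @name AdhesionTrackSet-class
#' @aliases AdhesionTrackSet-class
#' @exportClass AdhesionTrackSet
setClass("AdhesionTrackSet",
    representation(
        observations = "data.frame",
        dtS = "numeric",
        pixelSizeUm = "numeric",
        dzUm = "numeric"
    ),
    prototype(dzUm = NA_real_)
)

setValidity("AdhesionTrackSet", function(object) {
    obs <- object@observations
    msgs <- character()
    need <- c("adhesion_id", "t_index", "centroid_x_px", "centroid_y_px",
              "centroid_z_index", "z_planes", "area_um2",
              "integrated_intensity", "integrated_intensity_raw")
    if (!all(need %in% names(obs)))
        msgs <- c(msgs, paste("observations must have columns:",
                              paste(need, collapse = ", ")))
    else if (nrow(obs) > 0) {
        key <- paste(obs$adhesion_id, obs$t_index)
        if (anyDuplicated(key))
            msgs <- c(msgs, "(adhesion_id, t_index) pairs must be unique")
        contiguous <- vapply(split(obs$t_index, obs$adhesion_id),
            function(t) all(diff(sort(t)) == 1) || length(t) == 1L,
            logical(1))
        if (!all(contiguous))
            msgs <- c(msgs, "each track's t_index run must be contiguous")
    }
    if (length(object@dtS) != 1L || object@dtS <= 0)
        msgs <- c(msgs, "dtS must be a single positive number")
    if (length(msgs)) msgs else TRUE
})

#' KineticsFit: one adhesion phase's turnover kinetics
#'
#' Ordinary least-squares fit of the semilogarithmic intensity transform
#' (ln(I/I0) for assembly, ln(I0/I) for disassembly) against time. The
#' slope is the apparent first-order rate constant k (per minute); the
#' half-life is t1/2 = ln(2)/k. A fit whose slope is not positive cannot
#' be converted to a half-life and is flagged `converged = FALSE`.
#'
#' @slot adhesionId integer source adhesion ID (NA when fitted from a bare
#'   trace).
#' @slot phase "assembly" or "disassembly".
#' @slot kPerMin fitted rate constant, per minute (the regression slope).
#' @slot tHalfMin ln(2)/k minutes; NA when not converged.
#' @slot rSquared coefficient of determination of the semilog regression.
#' @slot intercept regression intercept (log units).
#' @slot nPoints number of timepoints used.
#' @slot tStartMin time (minutes) of the first fitted point.
#' @slot converged TRUE when the slope is positive and finite.
#'
#' @seealso [fitAssembly()], [fitDisassembly()], [halfLife()]
#' @name KineticsFit-class
#' @aliases KineticsFit-class
#' @exportClass KineticsFit
setClass("KineticsFit",
    representation(
        adhesionId = "integer",
        phase = "character",
        kPerMin = "numeric",
        tHalfMin = "numeric",
        rSquared = "numeric",
        intercept = "numeric",
        nPoints = "integer",
        tStartMin = "numeric",
        converged = "logical"
    )
)

setValidity("KineticsFit", function(object) {
    msgs <- character()
    if (!object@phase %in% c("assembly", "disassembly"))
        msgs <- c(msgs, "phase must be 'assembly' or 'disassembly'")
    if (object@nPoints < 3L)
        msgs <- c(msgs, "a kinetics fit needs at least 3 points")
    if (isTRUE(object@converged)) {
        if (!is.finite(object@kPerMin) || object@kPerMin <= 0)
            msgs <- c(msgs, "a converged fit must have k > 0")
        else if (abs(object@tHalfMin * object@kPerMin - log(2)) >
                 1e-9 * log(2))
            msgs <- c(msgs, "t_half * k must equal ln(2)")
    }
    if (is.finite(object@rSquared) &&
        (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
        msgs <- c(msgs, "r_squared must lie in [0, 1]")
    if (length(msgs)) msgs else TRUE
})
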