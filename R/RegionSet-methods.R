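#' @include AllClasses.R
NULL

#' @describeIn RegionSet-class number of labeled regions.
#' @param x a `RegionSet`.
#' @export
setMethod("nRegions", "RegionSet", function(x) nrow(x@regions))

#' @describeIn RegionSet-class per-region measurement table.
#' @export
setMethod("regionTable", "RegionSet", function(x) x@regions)

#' @describeIn RegionSet-class integer label image (0 = background).
#' @export
setMethod("labelImage", "RegionSet", function(x) x@labels)

#' @describeIn RegionSet-class micrometres per pixel used for areas.
#' @export
setMethod("pixelSize", "RegionSet", function(x) x@pixelSizeUm)

setMethod("show", "RegionSet", function(object) {
    cat(sprintf("RegionSet: %d regions on a %d x %d px frame (%.4g um/px)\n",
                nRegions(object), nrow(object@labels), ncol(object@labels),
                object@pixelSizeUm))
    if (nRegions(object) > 0) {
        a <- object@regions$area_um2
        cat(sprintf("  area: %.3g-%.3g um2 (median %.3g)\n",
                    min(a), max(a), stats::median(a)))
    }
})
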