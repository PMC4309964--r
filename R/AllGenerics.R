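#' @include AllGenerics.R
NULL

#' @title Generics for adhesion analysis containers
#' @description Accessor generics shared by the core classes
#'   ([ImageStack-class], [RegionSet-class], [AdhesionTrackSet-class]).
#' @param x an object.
#' @param ... further arguments for methods.
#' @return See individual methods.
#' @name AdhesionDynamics-generics
#' @keywords internal
NULL

#' @rdname AdhesionDynamics-generics
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname AdhesionDynamics-generics
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname AdhesionDynamics-generics
#' @export
setGeneric("zStep", function(x) standardGeneric("zStep"))

#' @rdname AdhesionDynamics-generics
#' @export
setGeneric("isVolumetric", function(x) standardGeneric("isVolumetric"))

#' @rdname AdhesionDynamics-generics
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname AdhesionDynamics-generics
#' @export
setGeneric("nPlanes", function(x) standardGeneric("nPlanes"))

#' @rdname AdhesionDynamics-generics
#' @export
setGeneric("getFrame", function(x, t, z) standardGeneric("getFrame"))

#' @rdname AdhesionDynamics-generics
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname AdhesionDynamics-generics
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname AdhesionDynamics-generics
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))

#' @rdname AdhesionDynamics-generics
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' @rdname AdhesionDynamics-generics
#' @export
setGeneric("trackIds", function(x) standardGeneric("trackIds"))

#' @rdname AdhesionDynamics-generics
#' @export
setGeneric("observations", function(x, ...) standardGeneric("observations"))

#' @rdname AdhesionDynamics-generics
#' @export
setGeneric("lifetimes", function(x) standardGeneric("lifetimes"))
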