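#' Accessors for ApicalQuant data classes
#'
#' Small accessor generics in the Bioconductor style; use these rather than
#' reaching into slots.
#'
#' @param x an ApicalQuant object.
#' @return The requested component (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("zSpacing", function(x) standardGeneric("zSpacing"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("hasZ", function(x) standardGeneric("hasZ"))

#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, t, z = NULL) standardGeneric("getFrame"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))

#' @rdname accessors
#' @export
setGeneric("maskAreaFraction", function(x) standardGeneric("maskAreaFraction"))

#' @rdname accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname accessors
#' @export
setGeneric("punctaCounts", function(x) standardGeneric("punctaCounts"))

#' @rdname accessors
#' @export
setGeneric("integratedIntensity", function(x) standardGeneric("integratedIntensity"))

#' @rdname accessors
#' @export
setGeneric("normalizedCounts", function(x) standardGeneric("normalizedCounts"))

#' @rdname accessors
#' @export
setGeneric("normalizedIntensity", function(x) standardGeneric("normalizedIntensity"))

#' @rdname accessors
#' @export
setGeneric("trackTable", function(x) standardGeneric("trackTable"))

#' @rdname accessors
#' @export
setGeneric("trackSummary", function(x) standardGeneric("trackSummary"))

#' @rdname accessors
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' @rdname accessors
#' @export
setGeneric("apicalReference", function(x) standardGeneric("apicalReference"))
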