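# Accessor and show methods.

#' @rdname accessors
#' @aliases stackData,ImageStack-method
setMethod("stackData", "ImageStack", function(x) x@data)

#' @rdname accessors
setMethod("pixelSize", "ImageStack", function(x) x@pixelSizeUm)

#' @rdname accessors
setMethod("frameInterval", "ImageStack", function(x) x@frameIntervalS)

#' @rdname accessors
setMethod("zSpacing", "ImageStack", function(x) x@zSpacingUm)

#' @rdname accessors
setMethod("nFrames", "ImageStack", function(x) dim(x@data)[1L])

#' @rdname accessors
setMethod("hasZ", "ImageStack", function(x) length(dim(x@data)) == 4L)

#' @rdname accessors
#' @param t frame index (1-based).
#' @param z z-plane index (1-based), for z-resolved stacks.
setMethod("getFrame", "ImageStack", function(x, t, z = NULL) {
  d <- x@data
  if (length(dim(d)) == 3L) {
    if (!is.null(z)) stop("stack has no z dimension")
    return(d[t, , , drop = TRUE])
  }
  if (is.null(z)) stop("z-plane index required for a z-resolved stack")
  d[t, z, , , drop = TRUE]
})

#' @rdname accessors
setMethod("frameTimes", "ImageStack", function(x) {
  (seq_len(nFrames(x)) - 1) * x@frameIntervalS
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  geom <- if (length(d) == 4L) {
    sprintf("%d frames x %d z x %d x %d px", d[1], d[2], d[3], d[4])
  } else {
    sprintf("%d frames x %d x %d px", d[1], d[2], d[3])
  }
  cat("ImageStack:", geom, "\n")
  cat(sprintf(
    "  pixel size %.4g um/px, frame interval %.4g s%s\n",
    object@pixelSizeUm, object@frameIntervalS,
    if (length(d) == 4L) sprintf(", z spacing %.4g um", object@zSpacingUm) else ""
  ))
  cat(sprintf(
    "  intensity range [%.4g, %.4g]\n",
    min(object@data), max(object@data)
  ))
})

#' @rdname accessors
setMethod("coverage", "CoverageSeries", function(x) x@coverage)

#' @rdname accessors
setMethod("maskAreaFraction", "CoverageSeries", function(x) x@maskAreaFraction)

#' @rdname accessors
setMethod("condition", "CoverageSeries", function(x) x@condition)

#' @rdname accessors
setMethod("frameTimes", "CoverageSeries", function(x) x@timeS)

setMethod("show", "CoverageSeries", function(object) {
  cat(sprintf(
    "CoverageSeries (%s): %d frames, coverage %.4f -> %.4f\n",
    object@condition, length(object@coverage),
    object@coverage[1], object@coverage[length(object@coverage)]
  ))
})

#' Convert a CoverageSeries to a data.frame
#' @param x a [CoverageSeries-class].
#' @param ... ignored.
#' @return data.frame with columns time_s, coverage, mask_area_fraction,
#'   condition.
#' @export
as.data.frame.CoverageSeries <- function(x, ...) {
  data.frame(
    time_s = x@timeS, coverage = x@coverage,
    mask_area_fraction = x@maskAreaFraction,
    condition = x@condition, stringsAsFactors = FALSE
  )
}

#' @rdname accessors
setMethod("punctaCounts", "PunctaSeries", function(x) x@counts)

#' @rdname accessors
setMethod("integratedIntensity", "PunctaSeries", function(x) x@integratedIntensity)

#' @rdname accessors
setMethod("normalizedCounts", "PunctaSeries", function(x) x@normalizedCounts)

#' @rdname accessors
setMethod("normalizedIntensity", "PunctaSeries", function(x) x@normalizedIntensity)

#' @rdname accessors
setMethod("frameTimes", "PunctaSeries", function(x) x@timeS)

setMethod("show", "PunctaSeries", function(object) {
  cat(sprintf(
    "PunctaSeries: %d frames, baseline window %d frames\n",
    length(object@counts), object@baselineWindow
  ))
  cat(sprintf(
    "  counts %d -> %d (normalized %.2f -> %.2f)\n",
    object@counts[1], object@counts[length(object@counts)],
    object@normalizedCounts[1],
    object@normalizedCounts[length(object@normalizedCounts)]
  ))
})

#' Convert a PunctaSeries to a data.frame
#' @param x a [PunctaSeries-class].
#' @param ... ignored.
#' @return data.frame with per-frame raw and normalized series.
#' @export
as.data.frame.PunctaSeries <- function(x, ...) {
  data.frame(
    t = seq_along(x@counts) - 1L, time_s = x@timeS, count = x@counts,
    integrated_intensity = x@integratedIntensity,
    normalized_count = x@normalizedCounts,
    normalized_intensity = x@normalizedIntensity
  )
}

#' @rdname accessors
setMethod("trackTable", "TrackSet", function(x) x@detections)

#' @rdname accessors
setMethod("trackSummary", "TrackSet", function(x) x@summary)

#' @rdname accessors
setMethod("nTracks", "TrackSet", function(x) nrow(x@summary))

#' @rdname accessors
setMethod("apicalReference", "TrackSet", function(x) x@apicalReferenceUm)

setMethod("show", "TrackSet", function(object) {
  smr <- object@summary
  cat(sprintf(
    "TrackSet: %d tracks, %d detections, apical reference %.3g um\n",
    nrow(smr), nrow(object@detections), object@apicalReferenceUm
  ))
  if (nrow(smr) && !all(is.na(smr$class))) {
    tab <- table(smr$class, useNA = "no")
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})
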