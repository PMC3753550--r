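#' @useDynLib ApicalQuant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Calibrated fluorescence image stack
#'
#' The universal input container of the package: a T x Y x X (planar
#' time-lapse) or T x Z x Y x X (z-resolved time-lapse) non-negative
#' intensity array together with its spatial and temporal calibration.
#' Row index (Y) increases from apical to basal in sagittal views.
#'
#' @slot data numeric array, `T x Y x X` or `T x Z x Y x X`; finite,
#'   non-negative intensities.
#' @slot pixelSizeUm numeric(1), lateral pixel size in micrometres per pixel.
#' @slot frameIntervalS numeric(1), time between frames in seconds.
#' @slot zSpacingUm numeric(1), spacing between z sections in micrometres;
#'   `NA` for planar stacks.
#'
#' @seealso [ImageStack()], [readStack()], [writeStack()]
#' @exportClass ImageStack
setClass("ImageStack",
  representation(
    data = "array",
    pixelSizeUm = "numeric",
    frameIntervalS = "numeric",
    zSpacingUm = "numeric"
  )
)

setValidity("ImageStack", function(object) {
  d <- object@data
  nd <- length(dim(d))
  if (!nd %in% c(3L, 4L))
    return("data must be a T x Y x X or T x Z x Y x X array")
  if (dim(d)[1] < 1L) return("at least one frame (T >= 1) is required")
  sp <- dim(d)[(nd - 1L):nd]
  if (any(sp < 8L)) return("spatial dimensions must be at least 8 px")
  if (!all(is.finite(d))) return("intensities must be finite")
  if (any(d < 0)) return("intensities must be non-negative")
  for (fld in c("pixelSizeUm", "frameIntervalS")) {
    v <- slot(object, fld)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      return(sprintf("%s must be a single strictly positive number", fld))
  }
  z <- object@zSpacingUm
  if (nd == 4L) {
    if (length(z) != 1L || !is.finite(z) || z <= 0)
      return("zSpacingUm must be strictly positive for a z-resolved stack")
  } else if (length(z) != 1L || (!is.na(z) && z <= 0)) {
    return("zSpacingUm must be NA or strictly positive")
  }
  TRUE
})

#' Construct an ImageStack
#'
#' A 2-D matrix is promoted to a single-frame (`T = 1`) stack.
#'
#' @param data numeric matrix or 3-D/4-D array of intensities
#'   (`Y x X`, `T x Y x X`, or `T x Z x Y x X`).
#' @param pixelSizeUm lateral pixel size (um/px), strictly positive.
#' @param frameIntervalS frame interval (s), strictly positive.
#' @param zSpacingUm z-section spacing (um), required for 4-D data.
#' @return An [ImageStack-class] object.
#' @examples
#' s <- ImageStack(array(1, c(2, 16, 16)), pixelSizeUm = 0.16,
#'                 frameIntervalS = 40)
#' nFrames(s)
#' @export
ImageStack <- function(data, pixelSizeUm, frameIntervalS, zSpacingUm = NA_real_) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  storage.mode(data) <- "double"
  new("ImageStack",
    data = data,
    pixelSizeUm = as.numeric(pixelSizeUm),
    frameIntervalS = as.numeric(frameIntervalS),
    zSpacingUm = as.numeric(zSpacingUm)
  )
}

#' Per-frame fractional protrusion coverage
#'
#' Output of [coverageTimeseries()]: for each frame, the fraction of the
#' field occupied by the skeleton of segmented protrusions (the flattening
#' readout), plus the binary-mask area fraction as a secondary measure.
#'
#' @slot timeS numeric, frame times in seconds.
#' @slot coverage numeric in `[0, 1]`, skeleton-pixel density per frame.
#' @slot maskAreaFraction numeric in `[0, 1]`, segmented-mask area fraction.
#' @slot condition character(1) label, e.g. `"wt"` or `"shibire"`.
#' @exportClass CoverageSeries
setClass("CoverageSeries",
  representation(
    timeS = "numeric",
    coverage = "numeric",
    maskAreaFraction = "numeric",
    condition = "character"
  )
)

setValidity("CoverageSeries", function(object) {
  n <- length(object@timeS)
  if (length(object@coverage) != n || length(object@maskAreaFraction) != n)
    return("timeS, coverage and maskAreaFraction must have equal length")
  if (any(object@coverage < 0 | object@coverage > 1))
    return("coverage must lie in [0, 1]")
  if (any(object@maskAreaFraction < 0 | object@maskAreaFraction > 1))
    return("maskAreaFraction must lie in [0, 1]")
  if (length(object@condition) != 1L)
    return("condition must be a single label")
  TRUE
})

#' Per-frame puncta counts and integrated intensities
#'
#' Output of [punctaTimeseries()]: raw per-frame object counts and summed
#' intensities, and the same series normalized to the mean of the first
#' `baselineWindow` frames (the early-cellularization baseline).
#'
#' @slot timeS numeric frame times (s).
#' @slot counts numeric raw object count per frame.
#' @slot integratedIntensity numeric summed object intensity per frame.
#' @slot normalizedCounts numeric, `counts / mean(counts[1:baselineWindow])`.
#' @slot normalizedIntensity numeric, analogous for intensity.
#' @slot baselineWindow integer(1), baseline length in frames (default 20).
#' @exportClass PunctaSeries
setClass("PunctaSeries",
  representation(
    timeS = "numeric",
    counts = "numeric",
    integratedIntensity = "numeric",
    normalizedCounts = "numeric",
    normalizedIntensity = "numeric",
    baselineWindow = "integer"
  )
)

setValidity("PunctaSeries", function(object) {
  n <- length(object@counts)
  lens <- c(
    length(object@timeS), length(object@integratedIntensity),
    length(object@normalizedCounts), length(object@normalizedIntensity)
  )
  if (any(lens != n)) return("all series must have equal length")
  w <- object@baselineWindow
  if (length(w) != 1L || w < 1L || w > n)
    return("baselineWindow must lie in [1, length(series)]")
  bl <- mean(object@normalizedCounts[seq_len(w)])
  if (abs(bl - 1) > 1e-9)
    return("mean of normalizedCounts over the baseline window must be 1")
  TRUE
})

#' Linked particle trajectories
#'
#' Output of [linkDetections()]: per-detection track assignments plus a
#' per-track summary (duration, origin depth, maximal depth below the apical
#' reference, net displacement, and -- after [classifyTracks()] -- a
#' persistent/descending class label).
#'
#' @slot detections data.frame with columns `track_id`, `t`, `y_um`, `x_um`,
#'   `intensity`.
#' @slot summary data.frame with one row per track: `track_id`,
#'   `duration_frames`, `origin_depth_um`, `max_depth_um`,
#'   `net_displacement_um`, `class` (`NA` until classified).
#' @slot apicalReferenceUm numeric(1), the apical surface line (um) depths
#'   are measured from.
#' @slot params list of tracking parameters used (see [trackingParams()]).
#' @exportClass TrackSet
setClass("TrackSet",
  representation(
    detections = "data.frame",
    summary = "data.frame",
    apicalReferenceUm = "numeric",
    params = "list"
  )
)

setValidity("TrackSet", function(object) {
  det <- object@detections
  need <- c("track_id", "t", "y_um", "x_um", "intensity")
  if (!all(need %in% names(det)))
    return(paste("detections must have columns:", paste(need, collapse = ", ")))
  smr <- object@summary
  needS <- c(
    "track_id", "duration_frames", "origin_depth_um", "max_depth_um",
    "net_displacement_um", "class"
  )
  if (!all(needS %in% names(smr)))
    return(paste("summary must have columns:", paste(needS, collapse = ", ")))
  if (nrow(smr) && any(smr$duration_frames < 1))
    return("track durations must be >= 1 frame")
  if (nrow(det)) {
    # frames within each track must be strictly consecutive (no gaps)
    byTrack <- split(det$t, det$track_id)
    ok <- vapply(byTrack, function(tt) all(diff(sort(tt)) == 1L) || length(tt) == 1L, logical(1))
    if (!all(ok)) return("track frames must be strictly consecutive")
  }
  if (length(object@apicalReferenceUm) != 1L)
    return("apicalReferenceUm must be a single number")
  TRUE
})
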