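#' Robust-background thresholding parameters
#'
#' Global threshold computed as mean + `kSd` x population SD of the pixel
#' intensities that remain after discarding `trimFraction` of pixels from
#' each intensity tail (counts rounded down). Trimming 5% per tail with
#' k = 2 reproduces the published description of the Robust Background
#' method used for spot segmentation.
#'
#' @param trimFraction fraction trimmed from each tail, in `[0, 0.5)`.
#' @param kSd SD multiplier, `> 0`.
#' @return Parameter list of class `RobustBackgroundParams`.
#' @export
robustBackgroundParams <- function(trimFraction = 0.05, kSd = 2.0) {
  if (trimFraction < 0 || trimFraction >= 0.5)
    stop("trimFraction must lie in [0, 0.5)")
  if (kSd <= 0) stop("kSd must be > 0")
  structure(list(trimFraction = trimFraction, kSd = kSd),
            class = "RobustBackgroundParams")
}

#' Robust-background intensity threshold
#'
#' @param frame 2-D numeric matrix with at least 20 pixels.
#' @param params a [robustBackgroundParams()] list.
#' @return The scalar threshold mean + kSd * population-SD of the trimmed
#'   intensities.
#' @export
robustBackgroundThreshold <- function(frame, params = robustBackgroundParams()) {
  v <- sort(as.vector(frame))
  n <- length(v)
  if (n < 20L) stop("frame must have at least 20 pixels")
  k <- floor(params$trimFraction * n)
  kept <- v[(k + 1L):(n - k)]
  if (length(kept) == 0L) stop("trimming removed all pixels")
  mean(kept) + params$kSd * .popSd(kept)
}

#' Detect puncta in a single frame
#'
#' 8-connected components of `frame > threshold` with area inside
#' `[minArea, maxArea]` pixels. Integrated intensity is the sum of member
#' pixel values; centroids are reported in micrometres (pixel index x
#' `pixelSizeUm`, 0-based). An eccentricity column (from second-order
#' moments) is emitted for optional downstream tubule/vesicle splitting.
#'
#' @param frame 2-D numeric matrix.
#' @param threshold finite intensity threshold.
#' @param minArea,maxArea object area bounds in pixels (defaults 2 and 200,
#'   spanning diffraction-limited puncta to small vacuoles at 0.1-0.2 um/px).
#' @param pixelSizeUm pixel size used to convert centroids to um (default 1,
#'   i.e. pixel units).
#' @return data.frame with columns `id`, `y_um`, `x_um`, `area_px`,
#'   `integrated_intensity`, `eccentricity`; attribute `"labels"` carries
#'   the filtered label matrix.
#' @export
detectPuncta <- function(frame, threshold, minArea = 2L, maxArea = 200L,
                         pixelSizeUm = 1) {
  stopifnot(is.matrix(frame), is.finite(threshold))
  lab <- .label8(matrix(as.integer(frame > threshold), nrow(frame), ncol(frame)))
  nlab <- max(lab)
  empty <- data.frame(
    id = integer(0), y_um = numeric(0), x_um = numeric(0),
    area_px = integer(0), integrated_intensity = numeric(0),
    eccentricity = numeric(0)
  )
  if (nlab == 0L) {
    attr(empty, "labels") <- lab
    return(empty)
  }
  area <- tabulate(lab, nbins = nlab)
  keep <- which(area >= minArea & area <= maxArea)
  if (length(keep) == 0L) {
    lab[] <- 0L
    attr(empty, "labels") <- lab
    return(empty)
  }
  idx <- which(lab > 0)
  lv <- lab[idx]
  ry <- (idx - 1L) %% nrow(frame)        # 0-based row (y)
  cx <- (idx - 1L) %/% nrow(frame)       # 0-based column (x)
  iv <- frame[idx]
  sy <- rowsum(ry, lv); sx <- rowsum(cx, lv); si <- rowsum(iv, lv)
  syy <- rowsum(ry^2, lv); sxx <- rowsum(cx^2, lv); sxy <- rowsum(ry * cx, lv)
  labIds <- as.integer(rownames(sy))
  sel <- match(keep, labIds)
  n <- area[keep]
  my <- sy[sel] / n; mx <- sx[sel] / n
  # central second moments -> eccentricity of the equivalent ellipse
  vyy <- syy[sel] / n - my^2
  vxx <- sxx[sel] / n - mx^2
  vxy <- sxy[sel] / n - my * mx
  tr <- vyy + vxx
  det2 <- sqrt(pmax((vyy - vxx)^2 + 4 * vxy^2, 0))
  l1 <- (tr + det2) / 2; l2 <- pmax((tr - det2) / 2, 0)
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0)
  # relabel kept objects 1..K in ascending original label order
  remap <- integer(nlab)
  remap[keep] <- seq_along(keep)
  lab[idx] <- remap[lv]
  out <- data.frame(
    id = seq_along(keep),
    y_um = my * pixelSizeUm, x_um = mx * pixelSizeUm,
    area_px = as.integer(n),
    integrated_intensity = si[sel],
    eccentricity = ecc
  )
  attr(out, "labels") <- lab
  out
}

#' Normalize a series to its early baseline
#'
#' Divides a series by the mean of its first `window` frames, the
#' early-cellularization baseline convention.
#'
#' @param x numeric series of length `>= window`.
#' @param window baseline length in frames (default 20).
#' @return `x / mean(x[1:window])`.
#' @export
normalizeToBaseline <- function(x, window = 20L) {
  window <- as.integer(window)
  if (length(x) < window)
    stop("series shorter than the baseline window (mean value of the first ",
         window, " frames)")
  bl <- mean(x[seq_len(window)])
  if (bl == 0) stop("baseline mean is zero; cannot normalize")
  x / bl
}

#' Per-frame puncta counts and intensities over a movie
#'
#' Applies the robust-background threshold and puncta detection to every
#' frame, then normalizes counts and integrated intensities to the mean of
#' the first `baselineWindow` frames.
#'
#' @param stack a planar [ImageStack-class] with at least `baselineWindow`
#'   frames.
#' @param params a [robustBackgroundParams()] list.
#' @param minArea,maxArea object area bounds (px).
#' @param baselineWindow baseline length in frames (default 20).
#' @return A [PunctaSeries-class].
#' @export
punctaTimeseries <- function(stack, params = robustBackgroundParams(),
                             minArea = 2L, maxArea = 200L,
                             baselineWindow = 20L) {
  stopifnot(is(stack, "ImageStack"))
  if (hasZ(stack)) stop("punctaTimeseries expects a planar (T x Y x X) stack")
  nt <- nFrames(stack)
  baselineWindow <- as.integer(baselineWindow)
  if (nt < baselineWindow)
    stop("movie has ", nt, " frames; normalization requires the mean value of the first ",
         baselineWindow, " frames")
  counts <- numeric(nt)
  inten <- numeric(nt)
  for (t in seq_len(nt)) {
    fr <- getFrame(stack, t)
    th <- robustBackgroundThreshold(fr, params)
    det <- detectPuncta(fr, th, minArea, maxArea, pixelSize(stack))
    counts[t] <- nrow(det)
    inten[t] <- sum(det$integrated_intensity)
  }
  .logStage("puncta_timeseries", "%d frames, counts %d -> %d", nt,
            counts[1], counts[nt])
  new("PunctaSeries",
    timeS = frameTimes(stack), counts = counts, integratedIntensity = inten,
    normalizedCounts = normalizeToBaseline(counts, baselineWindow),
    normalizedIntensity = normalizeToBaseline(inten, baselineWindow),
    baselineWindow = baselineWindow
  )
}

#' Sub-apical ROI configuration
#'
#' Calibrated counting regions for sub-apical endocytic structures:
#' square regions of `roiSideUm^2` (default 25 x 25 um = 625 um^2) counted
#' independently in `zPlanes` z sections separated by `zSpacingUm`
#' (defaults 5 sections, 0.2 um apart, sampling the band 4-5 um below the
#' apical membrane).
#'
#' @param roiSideUm side of the square ROI (um), default 25.
#' @param nRois number of regions (default 3).
#' @param zPlanes number of z sections counted per ROI (default 5).
#' @param zSpacingUm section spacing (um), default 0.2.
#' @param depthBandUm the depth band below the apical membrane the sections
#'   sample (um), default `c(4, 5)` (metadata, not used in counting).
#' @param roiOriginsUm optional `nRois x 2` matrix of (y, x) upper-left ROI
#'   corners in um; by default ROIs are spread evenly along x at the field's
#'   vertical centre.
#' @return Parameter list of class `SubapicalROIConfig`.
#' @export
subapicalROIConfig <- function(roiSideUm = 25, nRois = 3L, zPlanes = 5L,
                               zSpacingUm = 0.2, depthBandUm = c(4, 5),
                               roiOriginsUm = NULL) {
  stopifnot(roiSideUm > 0, nRois >= 1L, zPlanes >= 1L, zSpacingUm > 0)
  structure(
    list(roiSideUm = roiSideUm, nRois = as.integer(nRois),
         zPlanes = as.integer(zPlanes), zSpacingUm = zSpacingUm,
         depthBandUm = depthBandUm, roiOriginsUm = roiOriginsUm),
    class = "SubapicalROIConfig"
  )
}

# Default ROI placement: evenly spaced along x, vertically centred.
.placeRois <- function(cfg, H, W, pixelSizeUm) {
  side <- round(cfg$roiSideUm / pixelSizeUm)
  if (side > H || side > W)
    stop("ROI of ", cfg$roiSideUm, " um does not fit in the field")
  if (!is.null(cfg$roiOriginsUm)) {
    org <- round(cfg$roiOriginsUm / pixelSizeUm)
    if (any(org < 0) || any(org[, 1] + side > H) || any(org[, 2] + side > W))
      stop("ROI outside the field")
    return(cbind(org, side))
  }
  n <- cfg$nRois
  gap <- floor((W - n * side) / (n + 1))
  if (gap < 0) stop(n, " ROIs of ", cfg$roiSideUm, " um do not fit in the field")
  x0 <- gap + (seq_len(n) - 1L) * (side + gap)
  y0 <- rep(floor((H - side) / 2), n)
  cbind(y0, x0, side)
}

#' Count sub-apical structures in calibrated ROIs
#'
#' Detects objects independently in each of `cfg$zPlanes` z sections within
#' each square ROI (no cross-z merging, matching per-section manual counts)
#' and reports per-plane counts plus their mean per ROI (per 625 um^2 at
#' the default ROI side).
#'
#' @param zstack a z-resolved [ImageStack-class] (`T x Z x Y x X`); counting
#'   uses frame `t`.
#' @param cfg a [subapicalROIConfig()].
#' @param params a [robustBackgroundParams()] list.
#' @param minArea,maxArea object area bounds (px).
#' @param t frame index to count (default 1).
#' @return List with `perPlane` (data.frame roi, z, count) and `perRoi`
#'   (data.frame roi, mean_count).
#' @export
countSubapicalStructures <- function(zstack, cfg = subapicalROIConfig(),
                                     params = robustBackgroundParams(),
                                     minArea = 2L, maxArea = 200L, t = 1L) {
  stopifnot(is(zstack, "ImageStack"))
  if (!hasZ(zstack)) stop("countSubapicalStructures expects a z-resolved stack")
  d <- dim(zstack@data)
  if (cfg$zPlanes > d[2])
    stop("config requests ", cfg$zPlanes, " z planes but stack has ", d[2])
  rois <- .placeRois(cfg, d[3], d[4], pixelSize(zstack))
  rows <- list()
  for (r in seq_len(nrow(rois))) {
    y0 <- rois[r, 1]; x0 <- rois[r, 2]; side <- rois[r, 3]
    for (z in seq_len(cfg$zPlanes)) {
      fr <- getFrame(zstack, t, z)[(y0 + 1):(y0 + side), (x0 + 1):(x0 + side)]
      th <- robustBackgroundThreshold(fr, params)
      det <- detectPuncta(fr, th, minArea, maxArea)
      rows[[length(rows) + 1L]] <- data.frame(roi = r, z = z, count = nrow(det))
    }
  }
  perPlane <- do.call(rbind, rows)
  perRoi <- stats::aggregate(count ~ roi, perPlane, mean)
  names(perRoi)[2] <- "mean_count"
  .logStage("count_subapical", "%d ROIs x %d planes, mean count %.2f",
            nrow(rois), cfg$zPlanes, mean(perRoi$mean_count))
  list(perPlane = perPlane, perRoi = perRoi)
}
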