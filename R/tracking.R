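#' Tracking parameters
#'
#' @param maxLinkDistUm hard gate on per-frame displacement (um), default 2.
#' @param minDurationFrames minimum track duration kept by [filterTracks()],
#'   default 6 (inclusive: a 6-frame track is kept).
#' @param apicalBandUm the apical band (um): tracks must originate within it
#'   (inclusive) and tracks whose maximal depth exceeds it are classified
#'   as descending, default 5.
#' @param apicalReferenceUm apical surface line in um, or `"auto"` to
#'   estimate it from an image with [autoApicalReference()].
#' @return Parameter list of class `TrackingParams`.
#' @export
trackingParams <- function(maxLinkDistUm = 2.0, minDurationFrames = 6L,
                           apicalBandUm = 5.0, apicalReferenceUm = "auto") {
  if (maxLinkDistUm <= 0) stop("maxLinkDistUm must be > 0")
  minDurationFrames <- as.integer(minDurationFrames)
  if (minDurationFrames < 1L) stop("minDurationFrames must be >= 1")
  if (apicalBandUm <= 0) stop("apicalBandUm must be > 0")
  structure(
    list(maxLinkDistUm = maxLinkDistUm, minDurationFrames = minDurationFrames,
         apicalBandUm = apicalBandUm, apicalReferenceUm = apicalReferenceUm),
    class = "TrackingParams"
  )
}

#' Estimate the apical reference line from an image
#'
#' The apical membrane is the dominant bright structure in sagittal views:
#' the reference is the intensity-weighted mean row of the brightest 1% of
#' pixels in frame 1, converted to micrometres.
#'
#' @param stack a planar [ImageStack-class] in sagittal orientation (row
#'   index increases basally).
#' @return Apical reference depth in um.
#' @export
autoApicalReference <- function(stack) {
  stopifnot(is(stack, "ImageStack"))
  fr <- getFrame(stack, 1L)
  q <- stats::quantile(fr, 0.99)
  idx <- which(fr >= q)
  w <- fr[idx]
  rows0 <- (idx - 1L) %% nrow(fr)  # 0-based row index
  ref <- sum(rows0 * w) / sum(w) * pixelSize(stack)
  .logStage("apical_reference", "auto reference %.3f um", ref)
  ref
}

# Gated minimum-total-displacement one-to-one assignment between two point
# sets, as a maximum-weight bipartite matching. The offset C exceeds
# (min(n, m) + 1) * gate, so maximum cardinality dominates and, among
# maximum matchings, total displacement is minimized.
.assignGated <- function(A, B, gate) {
  nA <- nrow(A); nB <- nrow(B)
  if (nA == 0L || nB == 0L) return(cbind(integer(0), integer(0)))
  dmat <- sqrt(outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2)
  ok <- which(dmat <= gate, arr.ind = TRUE)
  if (nrow(ok) == 0L) return(cbind(integer(0), integer(0)))
  C <- (min(nA, nB) + 1) * gate + 1
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nA), rep(TRUE, nB)),
    edges = as.vector(t(cbind(ok[, 1], nA + ok[, 2])))
  )
  igraph::E(g)$weight <- C - dmat[ok]
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)$matching
  ai <- seq_len(nA)
  bi <- m[ai] - nA
  keep <- !is.na(bi)
  cbind(ai[keep], bi[keep])
}

#' Link per-frame detections into trajectories
#'
#' For each consecutive frame pair, a globally optimal one-to-one
#' assignment among detection pairs within the distance gate (maximum
#' number of links, minimum total Euclidean displacement). Unmatched
#' detections start new tracks; tracks end when unmatched -- there is no
#' gap closing, so track frames are strictly consecutive. The result is
#' invariant to the ordering of detections within a frame.
#'
#' @param detections data.frame with columns `t` (integer frame), `y_um`,
#'   `x_um` (positions; y increases basally) and optionally `intensity`.
#' @param params a [trackingParams()] list with a resolved (numeric)
#'   `apicalReferenceUm`.
#' @return A [TrackSet-class].
#' @export
linkDetections <- function(detections, params = trackingParams(apicalReferenceUm = 0)) {
  ref <- params$apicalReferenceUm
  if (!is.numeric(ref))
    stop("apicalReferenceUm must be resolved to a number before linking ",
         "(see autoApicalReference)")
  if (!"intensity" %in% names(detections))
    detections[["intensity"]] <- rep(NA_real_, nrow(detections))
  det <- detections[order(detections$t, detections$y_um, detections$x_um,
                          detections$intensity), , drop = FALSE]
  det[["track_id"]] <- rep(NA_integer_, nrow(det))
  frames <- sort(unique(det$t))
  nextId <- 0L
  prevIdx <- integer(0)  # row indices of previous frame's detections
  allIdx <- seq_len(nrow(det))
  for (f in seq_along(frames)) {
    curIdx <- allIdx[det$t == frames[f]]
    linkedCur <- integer(0)
    if (length(prevIdx) && f > 1L && frames[f] == frames[f - 1L] + 1L) {
      A <- cbind(det$y_um[prevIdx], det$x_um[prevIdx])
      B <- cbind(det$y_um[curIdx], det$x_um[curIdx])
      pairs <- .assignGated(A, B, params$maxLinkDistUm)
      if (nrow(pairs)) {
        det$track_id[curIdx[pairs[, 2]]] <- det$track_id[prevIdx[pairs[, 1]]]
        linkedCur <- pairs[, 2]
      }
    }
    newIdx <- if (length(linkedCur)) curIdx[-linkedCur] else curIdx
    if (length(newIdx)) {
      det$track_id[newIdx] <- nextId + seq_along(newIdx)
      nextId <- nextId + length(newIdx)
    }
    prevIdx <- curIdx
  }
  det <- det[order(det$track_id, det$t), c("track_id", "t", "y_um", "x_um", "intensity")]
  rownames(det) <- NULL
  smr <- .summarizeTracks(det, ref)
  .logStage("link_detections", "%d detections -> %d tracks (gate %.2f um)",
            nrow(det), nrow(smr), params$maxLinkDistUm)
  new("TrackSet", detections = det, summary = smr,
      apicalReferenceUm = ref, params = unclass(params))
}

.summarizeTracks <- function(det, ref) {
  if (nrow(det) == 0L) {
    return(data.frame(
      track_id = integer(0), duration_frames = integer(0),
      origin_depth_um = numeric(0), max_depth_um = numeric(0),
      net_displacement_um = numeric(0), class = character(0),
      stringsAsFactors = FALSE
    ))
  }
  sp <- split(seq_len(nrow(det)), det$track_id)
  ids <- as.integer(names(sp))
  dur <- lengths(sp)
  firstY <- vapply(sp, function(i) det$y_um[i[1]], numeric(1))
  lastY <- vapply(sp, function(i) det$y_um[i[length(i)]], numeric(1))
  maxY <- vapply(sp, function(i) max(det$y_um[i]), numeric(1))
  out <- data.frame(
    track_id = ids, duration_frames = as.integer(dur),
    origin_depth_um = firstY - ref, max_depth_um = maxY - ref,
    net_displacement_um = lastY - firstY,
    class = NA_character_, stringsAsFactors = FALSE
  )
  out[order(out$track_id), , drop = FALSE]
}

#' Filter tracks on duration and apical origin
#'
#' Keeps tracks lasting `minDurationFrames` frames or more whose origin
#' lies within `apicalBandUm` of the apical reference (both inclusive).
#'
#' @param tracks a [TrackSet-class].
#' @param params a [trackingParams()] list.
#' @return A filtered [TrackSet-class].
#' @export
filterTracks <- function(tracks, params = tracks@params) {
  stopifnot(is(tracks, "TrackSet"))
  smr <- tracks@summary
  keep <- smr$duration_frames >= params$minDurationFrames &
    smr$origin_depth_um <= params$apicalBandUm
  kept <- smr$track_id[keep]
  out <- tracks
  out@summary <- smr[keep, , drop = FALSE]
  out@detections <- tracks@detections[tracks@detections$track_id %in% kept, ,
                                      drop = FALSE]
  rownames(out@summary) <- rownames(out@detections) <- NULL
  .logStage("filter_tracks",
            "%d/%d tracks kept (duration >= %d frames, origin <= %.1f um)",
            sum(keep), nrow(smr), params$minDurationFrames, params$apicalBandUm)
  out
}

#' Classify tracks as apically persistent or basally descending
#'
#' A track is `descending` if its maximal depth below the apical reference
#' exceeds the apical band (strictly past `apicalBandUm`), otherwise
#' `persistent`.
#'
#' @param tracks a [TrackSet-class] (normally filtered).
#' @param params a [trackingParams()] list.
#' @return The [TrackSet-class] with the summary `class` column set.
#' @export
classifyTracks <- function(tracks, params = tracks@params) {
  stopifnot(is(tracks, "TrackSet"))
  out <- tracks
  out@summary$class <- ifelse(
    out@summary$max_depth_um > params$apicalBandUm, "descending", "persistent"
  )
  if (nrow(out@summary)) {
    tab <- table(out@summary$class)
    .logStage("classify_tracks", "%s",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  out
}

#' Per-stage displacement profile against the furrow front
#'
#' Assigns each classified track to the stage window containing its first
#' frame and reports, per window and class, the number of tracks and the
#' mean and population SD of maximal depth below the apical reference,
#' together with the mean furrow-front depth over the window. Windows with
#' no tracks report `n = 0` and missing means.
#'
#' @param tracks a classified [TrackSet-class].
#' @param windows data.frame with columns `label`, `start_frame`,
#'   `end_frame` (inclusive, 1-based; see [stageWindowsFrames()]). The
#'   windows must jointly cover every track's first frame.
#' @param furrow numeric vector of per-frame furrow depth (um below the
#'   apical reference); must be non-negative and non-decreasing.
#' @return data.frame with one row per window x class: `label`, `class`,
#'   `n`, `mean_max_depth_um`, `sd_max_depth_um`, `mean_furrow_depth_um`.
#' @export
displacementProfile <- function(tracks, windows, furrow) {
  stopifnot(is(tracks, "TrackSet"))
  if (any(furrow < 0) || any(diff(furrow) < 0))
    stop("furrow depth must be non-negative and non-decreasing")
  det <- tracks@detections
  smr <- tracks@summary
  if (nrow(smr) && all(is.na(smr$class)))
    stop("tracks must be classified first (classifyTracks)")
  firstFrame <- vapply(split(det$t, det$track_id), min, numeric(1))
  firstFrame <- firstFrame[match(smr$track_id, as.integer(names(firstFrame)))]
  win <- vapply(firstFrame, function(t0) {
    w <- which(windows$start_frame <= t0 & t0 <= windows$end_frame)
    if (length(w) == 0L) NA_integer_ else w[1]
  }, integer(1))
  if (nrow(smr) && anyNA(win))
    stop("stage windows do not cover the movie: track first frame(s) ",
         paste(unique(firstFrame[is.na(win)]), collapse = ", "), " unassigned")
  classes <- c("persistent", "descending")
  rows <- list()
  for (w in seq_len(nrow(windows))) {
    fr <- seq(windows$start_frame[w], windows$end_frame[w])
    fr <- fr[fr >= 1 & fr <= length(furrow)]
    mf <- if (length(fr)) mean(furrow[fr]) else NA_real_
    for (cl in classes) {
      sel <- which(win == w & smr$class == cl)
      rows[[length(rows) + 1L]] <- data.frame(
        label = windows$label[w], class = cl, n = length(sel),
        mean_max_depth_um = if (length(sel)) mean(smr$max_depth_um[sel]) else NA_real_,
        sd_max_depth_um = if (length(sel)) .popSd(smr$max_depth_um[sel]) else NA_real_,
        mean_furrow_depth_um = mf, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
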