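#' Default run configuration
#'
#' One block per pipeline module, flat keys inside each block. Calibration
#' (pixel size, frame interval, z spacing) has no default: acquisitions
#' never record it in the pixel data, so it must come from the user.
#'
#' Stage windows anchor the early/mid/late phases of cellularization at
#' roughly 5, 20 and 40 minutes.
#'
#' @return Nested list of documented defaults.
#' @seealso [loadRunConfig()]
#' @export
defaultRunConfig <- function() {
  list(
    calibration = list(
      pixel_size_um = NULL,
      frame_interval_s = NULL,
      z_spacing_um = NULL
    ),
    stages = list(
      early_start_s = 0, early_end_s = 600,
      mid_start_s = 600, mid_end_s = 1800,
      late_start_s = 1800, late_end_s = 2700
    ),
    filter_bank = list(
      sigma_x = 7, sigma_y = 1, n_angles = 18L, kernel_halfwidth = NULL
    ),
    thresholding = list(
      trim_fraction = 0.05, k_sd = 2.0, min_area = 2L, max_area = 200L
    ),
    tracking = list(
      max_link_dist_um = 2.0, min_duration_frames = 6L,
      apical_band_um = 5.0, apical_reference_um = "auto"
    ),
    coloc = list(overlap_fraction_min = 0.3),
    synthetic = list(),
    rng_seed = 1L
  )
}

.checkRange <- function(cfg) {
  fb <- cfg$filter_bank
  if (!(fb$sigma_x > fb$sigma_y && fb$sigma_y > 0))
    stop("filter_bank: require sigma_x > sigma_y > 0")
  if (fb$n_angles < 2L) stop("filter_bank: n_angles must be >= 2")
  th <- cfg$thresholding
  if (th$trim_fraction < 0 || th$trim_fraction >= 0.5)
    stop("thresholding: trim_fraction must lie in [0, 0.5)")
  if (th$k_sd <= 0) stop("thresholding: k_sd must be > 0")
  if (th$min_area < 1L || th$max_area < th$min_area)
    stop("thresholding: require 1 <= min_area <= max_area")
  tr <- cfg$tracking
  if (tr$max_link_dist_um <= 0) stop("tracking: max_link_dist_um must be > 0")
  if (tr$min_duration_frames < 1L)
    stop("tracking: min_duration_frames must be >= 1")
  if (tr$apical_band_um <= 0) stop("tracking: apical_band_um must be > 0")
  if (!identical(tr$apical_reference_um, "auto") &&
      !(is.numeric(tr$apical_reference_um) && length(tr$apical_reference_um) == 1L))
    stop("tracking: apical_reference_um must be a number or \"auto\"")
  cl <- cfg$coloc
  if (cl$overlap_fraction_min <= 0 || cl$overlap_fraction_min > 1)
    stop("coloc: overlap_fraction_min must lie in (0, 1]")
  st <- cfg$stages
  w <- matrix(unlist(st[c(
    "early_start_s", "early_end_s", "mid_start_s", "mid_end_s",
    "late_start_s", "late_end_s"
  )]), ncol = 2, byrow = TRUE)
  if (any(w[, 2] <= w[, 1]) || any(diff(as.vector(t(w))) < 0))
    stop("stages: windows must be ordered, non-overlapping, with end > start")
  cal <- cfg$calibration
  for (k in names(cal)) {
    if (!is.null(cal[[k]]) && (!is.numeric(cal[[k]]) || cal[[k]] <= 0))
      stop("calibration: ", k, " must be strictly positive")
  }
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file with one block per module, fills documented defaults
#' for absent keys, rejects unknown keys (catching typos), validates ranges,
#' and echoes the full effective configuration to the log. The result is a
#' pure function of the file contents.
#'
#' @param path YAML configuration file; an empty file yields the defaults.
#' @return The effective configuration list (see [defaultRunConfig()]).
#' @export
loadRunConfig <- function(path) {
  user <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("config file not found: ", path)
  if (is.null(user)) user <- list()
  cfg <- defaultRunConfig()
  badTop <- setdiff(names(user), names(cfg))
  if (length(badTop))
    stop("unknown config block(s): ", paste(badTop, collapse = ", "))
  for (blk in names(user)) {
    if (blk %in% c("rng_seed", "synthetic")) {
      cfg[[blk]] <- user[[blk]]
      next
    }
    bad <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
    if (length(bad))
      stop("unknown key(s) in block '", blk, "': ", paste(bad, collapse = ", "))
    for (k in names(user[[blk]])) cfg[[blk]][[k]] <- user[[blk]][[k]]
  }
  for (k in c("n_angles")) {
    cfg$filter_bank[[k]] <- as.integer(cfg$filter_bank[[k]])
  }
  cfg$thresholding$min_area <- as.integer(cfg$thresholding$min_area)
  cfg$thresholding$max_area <- as.integer(cfg$thresholding$max_area)
  cfg$tracking$min_duration_frames <- as.integer(cfg$tracking$min_duration_frames)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  .checkRange(cfg)
  .logStage("load_run_config", "effective config:\n%s", yaml::as.yaml(cfg))
  cfg
}

#' Stage windows in frame indices
#'
#' Converts the early/mid/late second-based stage windows of a run
#' configuration into inclusive 1-based frame-index windows for a movie of
#' `nframes` frames at `frameIntervalS` seconds per frame.
#'
#' @param cfg a run configuration list.
#' @param nframes number of frames in the movie.
#' @param frameIntervalS frame interval (s).
#' @return data.frame with columns `label`, `start_frame`, `end_frame`.
#' @export
stageWindowsFrames <- function(cfg, nframes, frameIntervalS) {
  st <- cfg$stages
  lab <- c("early", "mid", "late")
  out <- data.frame(
    label = lab,
    start_frame = vapply(lab, function(l)
      floor(st[[paste0(l, "_start_s")]] / frameIntervalS) + 1, numeric(1)),
    end_frame = vapply(lab, function(l)
      ceiling(st[[paste0(l, "_end_s")]] / frameIntervalS), numeric(1)),
    stringsAsFactors = FALSE
  )
  out$end_frame <- pmin(out$end_frame, nframes)
  out$start_frame <- pmin(out$start_frame, nframes)
  rownames(out) <- NULL
  out
}
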