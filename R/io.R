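#' Read a calibrated image stack from a multi-page TIFF
#'
#' Pages are interpreted as frames (`T x Y x X`); with `nz > 1`, pages are
#' grouped z-fastest into a `T x Z x Y x X` stack (page `(t-1)*nz + z`).
#' Grayscale 8/16-bit integer pages are read at their native integer values;
#' 32-bit float pages are read as stored. RGB input is rejected.
#'
#' @param path path to a TIFF file.
#' @param pixelSizeUm lateral pixel size (um/px); acquisition calibration is
#'   never guessed from the file, it must be supplied.
#' @param frameIntervalS frame interval (s).
#' @param zSpacingUm z spacing (um), required when `nz > 1`.
#' @param nz number of z planes per time point (default 1).
#' @return An [ImageStack-class].
#' @seealso [writeStack()]
#' @export
readStack <- function(path, pixelSizeUm, frameIntervalS,
                      zSpacingUm = NA_real_, nz = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) stop("unreadable TIFF '", path, "': ", conditionMessage(e))
  )
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    stop("RGB/multi-channel TIFF not supported; supply single-channel grayscale pages")
  nz <- as.integer(nz)
  np <- length(pages)
  if (nz > 1L) {
    if (np %% nz != 0L)
      stop(sprintf("page count %d is not a multiple of nz = %d", np, nz))
    nt <- np %/% nz
    d <- dim(pages[[1]])
    arr <- array(0, c(nt, nz, d[1], d[2]))
    for (t in seq_len(nt)) for (z in seq_len(nz)) {
      arr[t, z, , ] <- pages[[(t - 1L) * nz + z]]
    }
  } else {
    d <- dim(pages[[1]])
    arr <- array(0, c(np, d[1], d[2]))
    for (t in seq_len(np)) arr[t, , ] <- pages[[t]]
  }
  stk <- ImageStack(arr, pixelSizeUm, frameIntervalS, zSpacingUm)
  .logStage("read_stack", "%s: %s", path, paste(dim(arr), collapse = " x "))
  stk
}

#' Write an image stack as a 16-bit multi-page TIFF
#'
#' Stacks are stored as 16-bit unsigned integers (the camera ADU
#' convention), one page per frame (z-fastest for z-resolved stacks), so an
#' integer-valued stack round-trips through [readStack()] bit-for-bit.
#' Non-integer or out-of-range intensities are rejected rather than silently
#' quantized.
#'
#' @param stack an [ImageStack-class] with integer-valued intensities in
#'   `[0, 65535]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  d <- stack@data
  if (any(d != floor(d)) || max(d) > 65535)
    stop("writeStack stores 16-bit integer ADU; round/clip intensities to 0..65535 first")
  nd <- length(dim(d))
  pages <- list()
  if (nd == 4L) {
    k <- 0L
    for (t in seq_len(dim(d)[1])) for (z in seq_len(dim(d)[2])) {
      k <- k + 1L
      pages[[k]] <- d[t, z, , ] / 65535
    }
  } else {
    for (t in seq_len(dim(d)[1])) pages[[t]] <- d[t, , ] / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a table of keyed rows to CSV
#'
#' Rows must share one schema; they are written in input order with a header
#' and full floating-point precision (15 significant digits).
#'
#' @param records a data.frame, or a list of named lists/vectors sharing the
#'   same keys.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeResultsTable <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    if (length(records) == 0L)
      stop("cannot infer a schema from an empty list; pass a 0-row data.frame")
    keys <- names(records[[1]])
    if (is.null(keys) || any(!nzchar(keys)))
      stop("records must have named fields")
    ok <- vapply(records, function(r) identical(names(r), keys), logical(1))
    if (!all(ok))
      stop("heterogeneous record schemas: row(s) ",
           paste(which(!ok), collapse = ", "), " do not match the first row")
    df <- do.call(rbind, lapply(records, function(r) as.data.frame(as.list(r))))
  } else {
    stop("records must be a data.frame or list of named rows")
  }
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-frame detection table
#'
#' @param path CSV with columns `t`, `y_um`, `x_um` and optionally
#'   `intensity`.
#' @return data.frame with those columns (`intensity` filled with `NA` if
#'   absent).
#' @seealso [linkDetections()]
#' @export
readDetections <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "y_um", "x_um")
  if (!all(need %in% names(df)))
    stop("detection table must have columns: ", paste(need, collapse = ", "))
  if (!"intensity" %in% names(df)) df$intensity <- NA_real_
  df[c("t", "y_um", "x_um", "intensity")]
}
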