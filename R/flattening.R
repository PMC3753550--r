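#' Oriented Mexican-hat filter bank parameters
#'
#' The ridge detector is a Gaussian profile of scale `sigmaX` along the
#' ridge axis multiplied by a Ricker (Mexican-hat) profile of scale `sigmaY`
#' across it, rotated through `nAngles` orientations covering `[0, pi)`
#' (undirected ridges are pi-periodic). Defaults `sigmaX = 7`, `sigmaY = 1`
#' pixels match thin villous protrusions a few pixels wide and tens of
#' pixels long.
#'
#' @param sigmaX Gaussian scale along the ridge axis (px), `> sigmaY`.
#' @param sigmaY Ricker scale across the ridge (px), `> 0`.
#' @param nAngles number of orientations, `theta_k = k*pi/nAngles`,
#'   `k = 0..nAngles-1` (default 18, i.e. 10-degree steps).
#' @param kernelHalfwidth half-width of the square kernel support (px);
#'   default `ceiling(4 * max(sigmaX, sigmaY))`.
#' @return A validated parameter list of class `FilterBankParams`.
#' @export
filterBankParams <- function(sigmaX = 7, sigmaY = 1, nAngles = 18L,
                             kernelHalfwidth = NULL) {
  if (!(sigmaX > sigmaY && sigmaY > 0))
    stop("require sigmaX > sigmaY > 0")
  nAngles <- as.integer(nAngles)
  if (nAngles < 2L) stop("nAngles must be >= 2")
  if (is.null(kernelHalfwidth)) kernelHalfwidth <- ceiling(4 * max(sigmaX, sigmaY))
  kernelHalfwidth <- as.integer(kernelHalfwidth)
  if (kernelHalfwidth < 1L) stop("kernelHalfwidth must be >= 1")
  structure(
    list(sigmaX = sigmaX, sigmaY = sigmaY, nAngles = nAngles,
         kernelHalfwidth = kernelHalfwidth),
    class = "FilterBankParams"
  )
}

#' Photobleaching correction by mean-intensity fixing
#'
#' Multiplies every frame by `mean(frame_1) / mean(frame_t)` so that each
#' frame's mean intensity equals that of the initial image.
#'
#' @param stack an [ImageStack-class].
#' @return A corrected [ImageStack-class]; per-frame means equal the
#'   frame-1 mean to relative tolerance 1e-9.
#' @export
bleachCorrect <- function(stack) {
  stopifnot(is(stack, "ImageStack"))
  d <- stack@data
  nd <- length(dim(d))
  nt <- dim(d)[1L]
  means <- vapply(seq_len(nt), function(t) {
    if (nd == 3L) mean(d[t, , ]) else mean(d[t, , , ])
  }, numeric(1))
  zero <- which(means == 0)
  if (length(zero))
    stop("frame ", zero[1], " has zero mean intensity; cannot bleach-correct")
  for (t in seq_len(nt)) {
    f <- means[1] / means[t]
    if (nd == 3L) d[t, , ] <- d[t, , ] * f else d[t, , , ] <- d[t, , , ] * f
  }
  out <- stack
  out@data <- d
  .logStage("bleach_correct", "%d frames, frame-1 mean %.6g", nt, means[1])
  out
}

#' Oriented Mexican-hat (Ricker x Gaussian) kernel
#'
#' At orientation `theta` the kernel is `G(u; sigmaX) * R(v; sigmaY)` with
#' `u = x cos(theta) + y sin(theta)` the ridge axis and
#' `R(v) = (1 - v^2/sigmaY^2) exp(-v^2 / (2 sigmaY^2))` the Ricker profile
#' across it. After discrete sampling the kernel is shifted to exact zero
#' mean, so uniform regions give zero response.
#'
#' @param theta orientation in radians, in `[0, pi)`.
#' @param params a [filterBankParams()] list.
#' @return A `(2*halfwidth+1)^2` matrix (rows = y, columns = x) with zero
#'   mean.
#' @export
mexicanHatKernel <- function(theta, params = filterBankParams()) {
  if (!is.finite(theta) || theta < 0 || theta >= pi)
    stop("theta must lie in [0, pi)")
  hw <- params$kernelHalfwidth
  ax <- seq(-hw, hw)
  x <- matrix(ax, 2 * hw + 1, 2 * hw + 1, byrow = TRUE)  # column = x
  y <- matrix(ax, 2 * hw + 1, 2 * hw + 1)                # row = y
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  k <- exp(-u^2 / (2 * params$sigmaX^2)) *
    (1 - v^2 / params$sigmaY^2) * exp(-v^2 / (2 * params$sigmaY^2))
  k - mean(k)
}

# Wrap a centered (2hw+1)^2 kernel into an nr x nc matrix for circular FFT
# cross-correlation.
.wrapKernel <- function(k, nr, nc) {
  hw <- (nrow(k) - 1L) %/% 2L
  big <- matrix(0, nr, nc)
  idx <- seq(-hw, hw)
  ri <- (idx %% nr) + 1L
  ci <- (idx %% nc) + 1L
  big[ri, ci] <- k
  big
}

# Precompute conjugated kernel FFTs for a given padded frame geometry.
.bankFFTs <- function(params, nr, nc) {
  angles <- (seq_len(params$nAngles) - 1L) * pi / params$nAngles
  lapply(angles, function(th) Conj(stats::fft(.wrapKernel(
    mexicanHatKernel(th, params), nr, nc
  ))))
}

#' Orientation filter bank responses and their maximum projection
#'
#' Cross-correlates a frame with the oriented kernel at each angle
#' `theta_k = k*pi/nAngles` (reflective boundary handling) and takes the
#' per-pixel maximum over angles (the orientation MIP), which enhances
#' protrusions regardless of their direction.
#'
#' @param frame 2-D numeric matrix, at least kernel-sized.
#' @param params a [filterBankParams()] list.
#' @return List with `responses` (array `Y x X x nAngles`), `mip` (matrix),
#'   and `angles` (radians).
#' @export
orientationFilterBank <- function(frame, params = filterBankParams()) {
  stopifnot(is.matrix(frame))
  hw <- params$kernelHalfwidth
  P <- .reflectPad(frame, hw)
  nr <- nrow(P); nc <- ncol(P)
  kf <- .bankFFTs(params, nr, nc)
  Fp <- stats::fft(P)
  H <- nrow(frame); W <- ncol(frame)
  resp <- array(0, c(H, W, params$nAngles))
  for (i in seq_along(kf)) {
    r <- Re(stats::fft(Fp * kf[[i]], inverse = TRUE)) / (nr * nc)
    resp[, , i] <- r[(hw + 1L):(hw + H), (hw + 1L):(hw + W)]
  }
  mip <- apply(resp, c(1, 2), max)
  list(
    responses = resp, mip = mip,
    angles = (seq_len(params$nAngles) - 1L) * pi / params$nAngles
  )
}

#' Segment the orientation MIP into a protrusion mask
#'
#' Thresholds the orientation maximum-projection at the larger of (a) the
#' Otsu threshold computed on the positive part of the response histogram
#' (256 bins) and (b) a robust noise floor, `median + 4 * MAD` of the full
#' response. The floor plays the role of the background rejection a trained
#' pixel classifier would learn: on a structure-free frame the Otsu split of
#' the unimodal noise response would otherwise label a large noise fraction
#' as foreground. Constant input yields an empty mask.
#'
#' @param mip 2-D response matrix (finite values).
#' @return Logical matrix of the same shape.
#' @export
segmentResponse <- function(mip) {
  stopifnot(is.matrix(mip), all(is.finite(mip)))
  pos <- mip[mip > 0]
  if (length(pos) == 0L || diff(range(mip)) == 0)
    return(matrix(FALSE, nrow(mip), ncol(mip)))
  thOtsu <- .otsuOnValues(pos, levels = 256L)
  floorTh <- stats::median(mip) + 4 * stats::mad(mip)
  th <- max(thOtsu, floorTh)
  mask <- mip > th
  .logStage("segment_response", "otsu %.4g, noise floor %.4g -> %d px foreground",
            thOtsu, floorTh, sum(mask))
  mask
}

#' Morphological skeleton of a binary mask
#'
#' Zhang-Suen thinning to a 1-px-wide skeleton; single-pixel-wide lines are
#' their own skeleton.
#'
#' @param mask logical (or 0/1) matrix.
#' @return Logical matrix of the same shape.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  .zhangSuenThin(m) != 0L
}

#' Skeleton coverage fraction
#'
#' The flattening readout: number of skeleton pixels of the protrusion mask
#' divided by the total pixel count of the frame. Insensitive to protrusion
#' thickness, unlike the raw mask area.
#'
#' @param mask logical matrix (protrusion segmentation).
#' @return Fraction in `[0, 1]`.
#' @export
skeletonCoverage <- function(mask) {
  sum(skeletonize(mask)) / length(mask)
}

#' Fractional protrusion coverage over time
#'
#' Runs the full flattening pipeline per frame: bleach correction, oriented
#' Mexican-hat filter bank, orientation MIP, segmentation, skeleton
#' coverage. The binary-mask area fraction is reported alongside as a
#' secondary readout.
#'
#' @param stack a planar time-lapse [ImageStack-class].
#' @param params a [filterBankParams()] list.
#' @param condition label stored with the series (e.g. `"wt"`,
#'   `"shibire"`).
#' @return A [CoverageSeries-class].
#' @export
coverageTimeseries <- function(stack, params = filterBankParams(),
                               condition = "wt") {
  stopifnot(is(stack, "ImageStack"))
  if (hasZ(stack)) stop("coverageTimeseries expects a planar (T x Y x X) stack")
  stack <- bleachCorrect(stack)
  nt <- nFrames(stack)
  hw <- params$kernelHalfwidth
  d <- stack@data
  H <- dim(d)[2]; W <- dim(d)[3]
  kf <- .bankFFTs(params, H + 2L * hw, W + 2L * hw)
  cov <- numeric(nt)
  areaFrac <- numeric(nt)
  for (t in seq_len(nt)) {
    P <- .reflectPad(d[t, , ], hw)
    Fp <- stats::fft(P)
    mip <- matrix(-Inf, H, W)
    for (i in seq_along(kf)) {
      r <- Re(stats::fft(Fp * kf[[i]], inverse = TRUE)) / length(P)
      mip <- pmax(mip, r[(hw + 1L):(hw + H), (hw + 1L):(hw + W)])
    }
    mask <- suppressMessages(segmentResponse(mip))
    cov[t] <- skeletonCoverage(mask)
    areaFrac[t] <- mean(mask)
  }
  .logStage("coverage_timeseries", "%d frames, coverage %.4f -> %.4f",
            nt, cov[1], cov[nt])
  new("CoverageSeries",
    timeS = frameTimes(stack), coverage = cov,
    maskAreaFraction = areaFrac, condition = condition
  )
}

# Two-sample KS statistic D = sup |ECDF_a - ECDF_b| (tie-safe).
.ksStatistic <- function(a, b) {
  z <- sort(unique(c(a, b)))
  Fa <- findInterval(z, sort(a)) / length(a)
  Fb <- findInterval(z, sort(b)) / length(b)
  max(abs(Fa - Fb))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D = sup |ECDF_a - ECDF_b|`. For `n * m <= 100` the two-sided p-value is
#' computed exactly by enumerating all `choose(n + m, n)` assignments of the
#' pooled sample (valid under ties); otherwise the asymptotic KS
#' distribution is used. At `n = m = 3`, full separation gives the smallest
#' achievable exact p of 0.1 (= 2/20).
#'
#' @param a,b numeric samples (non-empty).
#' @return List with elements `statistic` (D) and `p.value`.
#' @export
ksCompare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  n <- length(a); m <- length(b)
  D <- .ksStatistic(a, b)
  if (n * m <= 100) {
    pooled <- c(a, b)
    N <- n + m
    combos <- utils::combn(N, n)
    Dperm <- apply(combos, 2L, function(ix) .ksStatistic(pooled[ix], pooled[-ix]))
    p <- mean(Dperm >= D - 1e-12)
  } else {
    p <- stats::psmirnov(D, sizes = c(n, m), exact = FALSE, lower.tail = FALSE)
  }
  list(statistic = D, p.value = min(1, p))
}
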