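# Robust-background thresholding, puncta detection, baseline normalization
# and sub-apical ROI counting.

test_that("robust-background threshold matches its closed forms", {
  # uniform frame: SD 0, threshold equals the constant
  expect_equal(robustBackgroundThreshold(matrix(7, 10, 10)), 7)

  # integers 0..99, trim 0.05, k = 2: keep 5..94, SD of 90 consecutive
  # integers is sqrt((90^2 - 1) / 12)
  fr <- matrix(0:99, 10, 10)
  expect_equal(robustBackgroundThreshold(fr),
               49.5 + 2 * sqrt((90^2 - 1) / 12), tolerance = 1e-12)

  # trim 0 reduces to mean + 2 * population SD of all pixels
  withr::with_seed(2, v <- matrix(rnorm(100, 50, 4), 10, 10))
  expect_equal(
    robustBackgroundThreshold(v, robustBackgroundParams(trimFraction = 0)),
    mean(v) + 2 * sqrt(mean((v - mean(v))^2)), tolerance = 1e-12
  )
  expect_error(robustBackgroundThreshold(matrix(1, 2, 2)), "20 pixels")
})

test_that("threshold equals the brute-force oracle on random arrays", {
  withr::with_seed(11, {
    for (i in 1:200) {
      n <- sample(20:400, 1)
      x <- rgamma(n, shape = 2, scale = sample(1:50, 1))
      tf <- runif(1, 0, 0.2)
      k <- runif(1, 0.5, 4)
      p <- robustBackgroundParams(trimFraction = tf, kSd = k)
      expect_equal(robustBackgroundThreshold(matrix(x, 1), p),
                   oracleRobustThreshold(x, tf, k), tolerance = 1e-9)
    }
  })
})

test_that("puncta detection follows 8-connectivity and area bounds", {
  fr <- matrix(0, 30, 30)
  fr[2:4, 2:4] <- 10; fr[10:12, 10:12] <- 10; fr[20:22, 25:27] <- 10
  det <- detectPuncta(fr, threshold = 5)
  expect_equal(nrow(det), 3L)
  expect_true(all(det$area_px == 9L))
  expect_equal(sort(det$integrated_intensity), rep(90, 3))

  # a single above-threshold pixel fails min_area = 2
  fr1 <- matrix(0, 10, 10); fr1[5, 5] <- 10
  expect_equal(nrow(detectPuncta(fr1, 5, minArea = 2)), 0L)

  # diagonal touch is one object under 8-connectivity
  fr2 <- matrix(0, 10, 10); fr2[3, 3] <- 10; fr2[4, 4] <- 10
  det2 <- detectPuncta(fr2, 5, minArea = 2)
  expect_equal(nrow(det2), 1L)
  expect_equal(det2$area_px, 2L)

  # centroids in um: object pixels rows 2:4, cols 2:4 (1-based) ->
  # 0-based centre (2, 2) times pixel size
  det3 <- detectPuncta(fr, 5, pixelSizeUm = 0.2)
  expect_equal(det3$y_um[1], 2 * 0.2)
  expect_equal(det3$x_um[1], 2 * 0.2)

  # raising the threshold never increases the object count on a spot
  # image (level sets of unimodal blobs stay connected)
  frN <- matrix(0, 64, 64)
  cy <- rep(c(12, 28, 44, 60) - 4, 3)          # grid, 16-px separation
  cx <- rep(c(12, 32, 52), each = 4)
  withr::with_seed(3, amp <- runif(12, 50, 150))
  for (i in 1:12) {
    for (r in 1:64) frN[r, ] <- frN[r, ] +
        amp[i] * exp(-((r - cy[i])^2 + ((1:64) - cx[i])^2) / 8)
  }
  counts <- vapply(c(5, 15, 30, 60, 100, 140),
                   function(th) nrow(detectPuncta(frN, th, minArea = 1)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("baseline normalization is exact and scale-invariant", {
  expect_equal(normalizeToBaseline(rep(4, 25)), rep(1, 25))
  x <- c(rep(10, 20), 30)
  expect_equal(normalizeToBaseline(x)[21], 3)
  expect_error(normalizeToBaseline(rep(0, 25)), "zero")
  expect_error(normalizeToBaseline(1:10, window = 20), "20 frames")
  withr::with_seed(8, x <- rpois(40, 30))
  expect_equal(normalizeToBaseline(x * 17), normalizeToBaseline(x))
  expect_equal(mean(normalizeToBaseline(x)[1:20]), 1, tolerance = 1e-9)
})

test_that("puncta detection is complete on well-separated bright spots", {
  # packed blob fields (centre separation 12 px, peak SNR >= 5)
  for (s in 1:4) {
    pair <- genColocPair(colocPairConfig(nObjects = 60L, overlapFraction = 0,
                                         nDistractors = 0L, seed = s))
    fr <- getFrame(pair$ref, 1)
    th <- robustBackgroundThreshold(fr, calibratedRB())
    det <- detectPuncta(fr, th, minArea = CAL_MIN_AREA,
                        pixelSizeUm = pixelSize(pair$ref))
    tr <- pair$truth
    d2 <- outer(det$y_um, tr$y_um, "-")^2 + outer(det$x_um, tr$x_um, "-")^2
    tol2 <- (3 * pixelSize(pair$ref))^2
    recall <- mean(apply(d2, 2, min) < tol2)
    precision <- mean(apply(d2, 1, min) < tol2)
    expect_gte(recall, 0.95)
    expect_gte(precision, 0.95)
  }
})

test_that("puncta time series normalizes to the first-20-frame baseline", {
  m <- suppressMessages(genPunctaMovie(punctaMovieConfig(
    T = 24L, height = 128L, width = 128L, baseBirthRate = 8,
    stageMultipliers = c(1, 1, 1), seed = 4
  )))
  ps <- suppressMessages(punctaTimeseries(m$stack, params = calibratedRB(),
                                          minArea = CAL_MIN_AREA))
  expect_equal(mean(normalizedCounts(ps)[1:20]), 1, tolerance = 1e-9)
  expect_equal(mean(normalizedIntensity(ps)[1:20]), 1, tolerance = 1e-9)
  expect_length(punctaCounts(ps), 24)

  short <- ImageStack(array(10, c(19, 16, 16)), 0.1, 1)
  expect_error(suppressMessages(punctaTimeseries(short)), "first 20 frames")
})

test_that("sub-apical counts are per-plane, windowed and calibrated", {
  # construct a z-stack with exactly k separated blobs per plane inside
  # each ROI; blobs outside the ROI must not be counted
  H <- 200L; W <- 200L; px <- 0.5  # ROI 25 um = 50 px
  cfg <- subapicalROIConfig(nRois = 2L, zPlanes = 3L)
  arr <- array(100, c(1, 3, H, W))
  rois <- ApicalQuant:::.placeRois(cfg, H, W, px)
  k <- 4L
  for (z in 1:3) {
    for (r in 1:2) {
      y0 <- rois[r, 1]; x0 <- rois[r, 2]
      for (i in 1:k) {
        yy <- y0 + 8 * i; xx <- x0 + 10 * i
        arr[1, z, (yy):(yy + 1), (xx):(xx + 1)] <- 500
      }
    }
    # a blob far outside both ROIs
    arr[1, z, 2:3, 2:3] <- 500
  }
  zs <- ImageStack(arr, px, 1, zSpacingUm = 0.2)
  res <- suppressMessages(countSubapicalStructures(zs, cfg, minArea = 2L))
  expect_true(all(res$perPlane$count == k))
  expect_equal(res$perRoi$mean_count, c(k, k))

  # ROI outside the field errors
  bad <- subapicalROIConfig(nRois = 1L, zPlanes = 3L,
                            roiOriginsUm = matrix(c(90, 90), 1))
  expect_error(suppressMessages(countSubapicalStructures(zs, bad)), "outside")
  # more planes than the stack has
  deep <- subapicalROIConfig(zPlanes = 9L)
  expect_error(suppressMessages(countSubapicalStructures(zs, deep)), "z planes")
})
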