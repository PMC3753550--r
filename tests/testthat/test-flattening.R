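# Bleach correction, oriented filter bank, segmentation, skeleton coverage,
# and the exact small-sample KS comparison.

test_that("bleach correction fixes every frame mean to the first frame", {
  # constant stack is unchanged (scale factor exactly 1)
  s <- ImageStack(array(42, c(3, 16, 16)), 0.1, 1)
  expect_identical(stackData(suppressMessages(bleachCorrect(s))), stackData(s))

  # a frame with half the mean is scaled by exactly 2
  arr <- array(100, c(2, 16, 16))
  arr[2, , ] <- 50
  out <- suppressMessages(bleachCorrect(ImageStack(arr, 0.1, 1)))
  expect_equal(stackData(out)[2, , ], matrix(100, 16, 16))

  # random stacks: per-frame means equal frame-1 mean to 1e-9 relative
  for (seed in 1:3) {
    withr::with_seed(seed, {
      arr <- array(rexp(5 * 16 * 16, rate = 1 / 50), c(5, 16, 16))
    })
    out <- suppressMessages(bleachCorrect(ImageStack(arr, 0.1, 1)))
    m <- apply(stackData(out), 1, mean)
    expect_lt(max(abs(m - m[1]) / m[1]), 1e-9)
  }

  # all-zero frame is an error naming the frame
  arr <- array(10, c(3, 16, 16))
  arr[2, , ] <- 0
  expect_error(suppressMessages(bleachCorrect(ImageStack(arr, 0.1, 1))),
               "frame 2")
})

test_that("oriented kernels are zero-mean, rotation-consistent, ridge-peaked", {
  p <- filterBankParams()  # sigma 7 / 1
  for (th in c(0, 0.4, pi / 2, 2.8)) {
    expect_lt(abs(sum(mexicanHatKernel(th, p))), 1e-12)
  }
  expect_lt(max(abs(mexicanHatKernel(pi / 2, p) - t(mexicanHatKernel(0, p)))),
            1e-9)
  expect_error(mexicanHatKernel(pi, p), "theta")
  expect_error(mexicanHatKernel(-0.1, p), "theta")

  # the centre sample is the maximum for theta = 0: recompute the closed
  # form independently on the sampling grid
  k <- mexicanHatKernel(0, p)
  hw <- p$kernelHalfwidth
  ref <- matrix(0, 2 * hw + 1, 2 * hw + 1)
  for (iy in seq_len(2 * hw + 1)) for (ix in seq_len(2 * hw + 1)) {
    u <- ix - hw - 1  # ridge axis = x at theta 0
    v <- iy - hw - 1
    ref[iy, ix] <- exp(-u^2 / (2 * 49)) * (1 - v^2) * exp(-v^2 / 2)
  }
  ref <- ref - mean(ref)
  expect_equal(k, ref, tolerance = 1e-12)
  expect_equal(which.max(k), which(row(k) == hw + 1 & col(k) == hw + 1))
})

test_that("filter bank responds to ridges at the matching angle bin", {
  p <- filterBankParams()
  # uniform frame: zero-mean kernels give zero response everywhere
  b <- orientationFilterBank(matrix(5, 64, 64), p)
  expect_lt(max(abs(b$responses)), 1e-9)

  # a 1-px ridge at 40 degrees is maximal in the 40-degree bin (k = 4)
  fr <- matrix(0, 128, 128)
  th <- 40 * pi / 180
  s <- seq(-50, 50, by = 0.25)
  py <- round(64.5 + s * sin(th)); px <- round(64.5 + s * cos(th))
  keep <- py >= 1 & py <= 128 & px >= 1 & px <= 128
  fr[cbind(py[keep], px[keep])] <- 100
  b <- orientationFilterBank(fr, p)
  onRidge <- fr > 0
  meanResp <- vapply(seq_len(p$nAngles),
                     function(i) mean(b$responses[, , i][onRidge]), numeric(1))
  expect_equal(which.max(meanResp), 5L)  # theta_k = 40 deg is k = 4 (1-based 5)

  # the MIP dominates every per-angle response
  for (i in seq_len(p$nAngles)) {
    expect_true(all(b$mip - b$responses[, , i] >= -1e-12))
  }

  # undersized frame is an error
  expect_error(orientationFilterBank(matrix(0, 10, 10), p), "kernel")
})

test_that("rotating the image by 90 degrees permutes the angle responses", {
  p <- filterBankParams(sigmaX = 4, sigmaY = 1, nAngles = 18,
                        kernelHalfwidth = 12)
  withr::with_seed(3, {
    fr <- matrix(0, 96, 96)
    for (i in 1:20) {
      th <- runif(1, 0, pi)
      s <- seq(-12, 12, by = 0.25)
      py <- round(runif(1, 20, 76) + s * sin(th))
      px <- round(runif(1, 20, 76) + s * cos(th))
      keep <- py >= 1 & py <= 96 & px >= 1 & px <= 96
      fr[cbind(py[keep], px[keep])] <- 100
    }
  })
  rot <- t(fr)[96:1, ]  # exact 90-degree rotation
  bA <- orientationFilterBank(fr, p)
  bB <- orientationFilterBank(rot, p)
  j <- 9L  # 90 deg = 9 bins of 10 deg
  interior <- 20:77
  rng <- diff(range(bA$responses))
  for (k in c(1L, 4L, 10L)) {
    kk <- ((k - 1L + j) %% p$nAngles) + 1L
    expected <- t(bA$responses[, , k])[96:1, ]  # rotate the response map
    rms <- sqrt(mean((bB$responses[interior, interior, kk] -
                        expected[interior, interior])^2))
    expect_lt(rms / rng, 0.05)
  }
})

test_that("response segmentation separates modes and rejects noise", {
  # constant input: empty mask
  expect_false(any(suppressMessages(segmentResponse(matrix(3, 20, 20)))))

  # two-valued mip: exactly the ridge pixels
  mip <- matrix(0, 30, 30)
  mip[10:12, 5:25] <- 4
  mask <- suppressMessages(segmentResponse(mip))
  expect_identical(mask, mip > 0)

  # bimodal mixture: misclassification < 2% against the true labels, and
  # the threshold agrees with exhaustive-search Otsu on the same histogram
  withr::with_seed(9, {
    lab <- matrix(runif(80 * 80) < 0.3, 80, 80)
    mip <- matrix(rnorm(80 * 80, mean = 2, sd = 0.5), 80, 80)
    mip[lab] <- rnorm(sum(lab), mean = 10, sd = 1)
    mip <- pmax(mip, 0.01)
  })
  mask <- suppressMessages(segmentResponse(mip))
  expect_lt(mean(mask != lab), 0.02)
  thOracle <- oracleOtsu(mip[mip > 0])
  expect_gt(thOracle, max(mip[!lab]) - 2)  # oracle lies between the modes
  expect_equal(ApicalQuant:::.otsuOnValues(mip[mip > 0]), thOracle,
               tolerance = 1e-9)
})

test_that("skeleton coverage is the thinning density and stays in [0, 1]", {
  # empty mask
  expect_identical(skeletonCoverage(matrix(FALSE, 10, 10)), 0)

  # a 1-px line is its own skeleton: coverage L / (H * W)
  m <- matrix(FALSE, 20, 30)
  m[10, 4:18] <- TRUE
  expect_identical(skeletonize(m), m)
  expect_equal(skeletonCoverage(m), 15 / 600)

  # filled disk: coverage equals the independent thinning oracle
  d <- matrix(FALSE, 31, 31)
  for (r in 1:31) for (c in 1:31) d[r, c] <- (r - 16)^2 + (c - 16)^2 <= 100
  expect_identical(skeletonize(d), oracleThin(d))
  expect_equal(skeletonCoverage(d), sum(oracleThin(d)) / length(d))

  # monotone under adding a disjoint line
  m2 <- m
  m2[3, 5:25] <- TRUE
  expect_gte(skeletonCoverage(m2), skeletonCoverage(m))

  # bounded for random masks
  withr::with_seed(1, {
    for (i in 1:5) {
      rm <- matrix(runif(400) < 0.4, 20, 20)
      cv <- skeletonCoverage(rm)
      expect_gte(cv, 0)
      expect_lte(cv, 1)
    }
  })
})

test_that("KS comparison is exact for small samples and matches brute force", {
  # identical samples
  r <- ksCompare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  # fully separated n = m = 3: D = 1, exact p = 2 / choose(6, 3) = 0.1
  r <- ksCompare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$statistic, 1)
  expect_equal(r$p.value, 0.1)

  # interleaved example against the exhaustive-permutation oracle
  a <- c(1, 2, 3); b <- c(1.5, 2.5, 3.5)
  r <- ksCompare(a, b)
  o <- oracleKs(a, b)
  expect_equal(r$statistic, o$statistic)
  expect_equal(r$p.value, o$p.value)

  # untied case agrees with stats::ks.test exact p-value
  withr::with_seed(4, {
    a <- rnorm(5); b <- rnorm(6, mean = 1)
  })
  r <- ksCompare(a, b)
  k <- suppressWarnings(stats::ks.test(a, b, exact = TRUE))
  expect_equal(r$statistic, unname(k$statistic))
  expect_equal(r$p.value, k$p.value, tolerance = 1e-12)

  # large samples fall back to the asymptotic tail
  withr::with_seed(5, {
    a <- rnorm(40); b <- rnorm(40, mean = 0.8)
  })
  r <- ksCompare(a, b)
  expect_equal(
    r$p.value,
    stats::psmirnov(r$statistic, sizes = c(40, 40), exact = FALSE,
                    lower.tail = FALSE),
    tolerance = 1e-12
  )
  expect_error(ksCompare(numeric(0), 1), "non-empty")
})

test_that("coverage pipeline returns bounded per-frame series", {
  m <- suppressMessages(genProtrusionMovie(protrusionMovieConfig(
    T = 6L, height = 96L, width = 96L, nProtrusions0 = 40L, seed = 2
  )))
  cs <- suppressMessages(coverageTimeseries(
    m$stack, filterBankParams(sigmaX = 4, sigmaY = 1, kernelHalfwidth = 16)
  ))
  expect_length(coverage(cs), 6)
  expect_true(all(coverage(cs) >= 0 & coverage(cs) <= 1))
  expect_true(all(maskAreaFraction(cs) >= coverage(cs) - 1e-12))
  expect_equal(frameTimes(cs), (0:5) * 40)
})
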