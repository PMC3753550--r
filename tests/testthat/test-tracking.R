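# Gated optimal-assignment linking, duration/origin filters, persistent vs
# descending classification, displacement profiles.

tp0 <- function(...) trackingParams(apicalReferenceUm = 0, ...)

test_that("linking follows the gate and the optimal assignment", {
  # one detection per frame within the gate: a single track
  det <- data.frame(t = 1:5, y_um = seq(0, 2, length.out = 5), x_um = 0)
  ts <- suppressMessages(linkDetections(det, tp0()))
  expect_equal(nTracks(ts), 1L)
  expect_equal(trackSummary(ts)$duration_frames, 5L)

  # a 3-um jump against a 2-um gate is refused: two tracks
  det <- data.frame(t = 1:2, y_um = c(0, 3), x_um = 0)
  ts <- suppressMessages(linkDetections(det, tp0()))
  expect_equal(nTracks(ts), 2L)

  # greedy nearest-neighbour would claim the 0.1-um pair (a2 -> b1) and
  # strand a1, whose remaining partner lies past the gate; the optimal
  # assignment links both particles (enumerating the 2 x 2 cost matrix:
  # a1b1 + a2b2 = 1.9 + 0.1 beats one-link alternatives)
  det <- data.frame(
    t = c(1, 1, 2, 2),
    y_um = c(0, 2, 1.9, 2.1),
    x_um = 0
  )
  ts <- suppressMessages(linkDetections(det, tp0()))
  expect_equal(nTracks(ts), 2L)
  expect_true(all(trackSummary(ts)$duration_frames == 2L))
  tt <- trackTable(ts)
  id0 <- tt$track_id[tt$t == 1 & tt$y_um == 0]
  expect_equal(tt$y_um[tt$t == 2 & tt$track_id == id0], 1.9)

  # no gap closing: a skipped frame starts a new track
  det <- data.frame(t = c(1, 2, 4, 5), y_um = 0.01 * (1:4), x_um = 0)
  ts <- suppressMessages(linkDetections(det, tp0()))
  expect_equal(sort(trackSummary(ts)$duration_frames), c(2L, 2L))
})

test_that("linking is invariant to detection order within frames", {
  sc <- genTrackScene(trackSceneConfig(T = 40L, seed = 6))
  det <- sc$detections[c("t", "y_um", "x_um", "intensity")]
  ts1 <- suppressMessages(linkDetections(det, tp0()))
  withr::with_seed(1, detShuf <- det[sample(nrow(det)), ])
  ts2 <- suppressMessages(linkDetections(detShuf, tp0()))
  expect_identical(trackTable(ts1), trackTable(ts2))
  expect_identical(trackSummary(ts1), trackSummary(ts2))
})

test_that("duration and origin filters are inclusive at their boundaries", {
  mk <- function(n, y0) data.frame(t = seq_len(n), y_um = y0, x_um = 0)
  ulp <- 5 * .Machine$double.eps
  det <- rbind(
    cbind(mk(6, 4.9), g = 1),    # duration 6, origin 4.9: kept
    cbind(mk(5, 20.0), g = 2),   # duration 5: removed
    cbind(mk(10, 5 + ulp), g = 3),  # origin just past 5 um: removed
    cbind(mk(7, 5.0), g = 4)     # origin exactly 5 um: kept
  )
  det$x_um <- det$g * 20  # separate the groups spatially
  ts <- suppressMessages(linkDetections(det[c("t", "y_um", "x_um")], tp0()))
  expect_equal(nTracks(ts), 4L)
  f <- suppressMessages(filterTracks(ts))
  expect_equal(sort(trackSummary(f)$origin_depth_um), c(4.9, 5.0))
})

test_that("classification splits at 5 um of maximal depth", {
  det <- rbind(
    data.frame(t = 1:6, y_um = 4.9, x_um = 0),    # persistent
    data.frame(t = 1:8, y_um = seq(1, 15, length.out = 8), x_um = 30)
  )
  ts <- suppressMessages(classifyTracks(suppressMessages(
    filterTracks(suppressMessages(linkDetections(det, tp0())))
  )))
  smr <- trackSummary(ts)
  expect_equal(smr$class[smr$max_depth_um < 5], "persistent")
  expect_equal(smr$class[smr$max_depth_um > 5], "descending")

  # empty track sets classify to empty labels
  e <- suppressMessages(linkDetections(
    data.frame(t = integer(0), y_um = numeric(0), x_um = numeric(0)), tp0()
  ))
  expect_equal(nTracks(suppressMessages(classifyTracks(e))), 0L)
})

test_that("displacement profile reports per-window class statistics", {
  det <- rbind(
    data.frame(t = 1:11, y_um = seq(0, 10, by = 1), x_um = 0),
    data.frame(t = 1:11, y_um = seq(0, 20, by = 2), x_um = 30)
  )
  ts <- suppressMessages(classifyTracks(suppressMessages(
    filterTracks(suppressMessages(linkDetections(det, tp0())))
  )))
  win <- data.frame(label = c("a", "b"), start_frame = c(1, 12),
                    end_frame = c(11, 12))
  furrow <- seq(0, 11, length.out = 12)
  prof <- displacementProfile(ts, win, furrow)
  d <- prof[prof$class == "descending" & prof$label == "a", ]
  expect_equal(d$n, 2L)
  expect_equal(d$mean_max_depth_um, 15)  # depths 10 and 20
  expect_equal(d$sd_max_depth_um, 5)     # population SD
  empty <- prof[prof$label == "b", ]
  expect_true(all(empty$n == 0))
  expect_true(all(is.na(empty$mean_max_depth_um)))

  # windows must cover every track start
  badWin <- data.frame(label = "a", start_frame = 3, end_frame = 12)
  expect_error(displacementProfile(ts, badWin, furrow), "cover")
  # furrow must be non-decreasing and non-negative
  expect_error(displacementProfile(ts, win, rev(furrow)), "non-decreasing")
})

test_that("auto apical reference finds the dominant bright row", {
  arr <- array(10, c(1, 64, 64))
  arr[1, 21, ] <- 1000  # bright membrane line at row index 20 (0-based)
  s <- ImageStack(arr, pixelSizeUm = 0.25, frameIntervalS = 1)
  expect_equal(suppressMessages(autoApicalReference(s)), 20 * 0.25,
               tolerance = 0.01)
  # linking demands a resolved reference
  expect_error(
    suppressMessages(linkDetections(
      data.frame(t = 1, y_um = 0, x_um = 0), trackingParams()
    )),
    "resolved"
  )
})

test_that("tracks recover exactly on noiseless well-spaced scenes", {
  sc <- genTrackScene(trackSceneConfig(birthRate = 0.15, fieldWidthUm = 150,
                                       detectionNoiseSdUm = 0, seed = 2))
  ts <- suppressMessages(linkDetections(
    sc$detections[c("t", "y_um", "x_um", "intensity")],
    tp0()
  ))
  expect_equal(linkAccuracy(sc$detections, ts), 1)
  expect_equal(nTracks(ts), nrow(sc$truth))
})
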