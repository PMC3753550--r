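# Seeded synthetic-scene generators. Each generator is a pure function of
# (config, seed): identical inputs give bit-identical outputs. Ground truth
# is computed on the noiseless latent structure (for coverage, on the latent
# binary protrusion mask), never on rendered pixels.

#' Protrusion movie configuration
#'
#' Emulates TIRF imaging of the apical surface: thin, dynamic, villous
#' protrusions over a textured membrane background, with photobleaching and
#' mixed Poisson-Gaussian camera noise. Under the `"wildtype"` profile the
#' protrusion count decays exponentially to `finalFraction` (default 10%)
#' of its initial value by the end of the movie (progressive apical
#' flattening); under `"persistent"` it stays constant (the
#' dynamin-blocked, shibire-like phenotype).
#'
#' @param T frames (default 60; at 40 s/frame this spans the ~40 min of
#'   cellularization).
#' @param height,width field size (px), default 256.
#' @param pixelSizeUm um/px, default 0.16 (typical 100x TIRF sampling).
#' @param frameIntervalS seconds per frame, default 40.
#' @param nProtrusions0 protrusion count at t = 0, default 150.
#' @param profile `"wildtype"` (exponential decay) or `"persistent"`.
#' @param finalFraction remaining fraction at the last frame under
#'   `"wildtype"`, default 0.1.
#' @param lengthMeanUm,lengthSdLog lognormal protrusion length (um),
#'   defaults mean 2 um, sdlog 0.4.
#' @param background mean membrane background (ADU), default 100.
#' @param textureRelSd relative amplitude of the static membrane texture,
#'   default 0.05.
#' @param amplitude protrusion line amplitude before PSF blur (ADU),
#'   default 400 (peak ridge SNR ~ 10 over the shot+read noise).
#' @param bleachRate multiplicative bleaching rate per frame (exp(-rate*t)),
#'   default 0.005.
#' @param gain,readNoiseSd camera model: Poisson(gain*signal)/gain plus
#'   Gaussian read noise, defaults 1 and 3 ADU.
#' @param seed RNG seed.
#' @return Config list of class `ProtrusionMovieConfig`.
#' @export
protrusionMovieConfig <- function(T = 60L, height = 256L, width = 256L,
                                  pixelSizeUm = 0.16, frameIntervalS = 40,
                                  nProtrusions0 = 150L,
                                  profile = c("wildtype", "persistent"),
                                  finalFraction = 0.1, lengthMeanUm = 2,
                                  lengthSdLog = 0.4, background = 100,
                                  textureRelSd = 0.05, amplitude = 400,
                                  bleachRate = 0.005, gain = 1,
                                  readNoiseSd = 3, seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(T >= 1, height >= 8, width >= 8, pixelSizeUm > 0,
            nProtrusions0 >= 0, finalFraction > 0, finalFraction <= 1,
            lengthMeanUm > 0, background > 0, amplitude >= 0,
            bleachRate >= 0, gain > 0, readNoiseSd >= 0)
  structure(as.list(environment()), class = "ProtrusionMovieConfig")
}

# Rasterize a 1-px-wide segment by dense sub-pixel sampling.
.drawSegment <- function(mask, cy, cx, angle, lenPx) {
  s <- seq(-lenPx / 2, lenPx / 2, by = 0.25)
  py <- round(cy + s * sin(angle))
  px <- round(cx + s * cos(angle))
  ok <- py >= 1 & py <= nrow(mask) & px >= 1 & px <= ncol(mask)
  mask[cbind(py[ok], px[ok])] <- TRUE
  mask
}

#' Generate a synthetic protrusion movie with ground truth
#'
#' @param cfg a [protrusionMovieConfig()].
#' @return List with `stack` (an [ImageStack-class]), `truth` (data.frame
#'   `t`, `n_protrusions`, `true_coverage`, with coverage computed as the
#'   skeleton density of the noiseless latent protrusion mask), and
#'   `config`.
#' @export
genProtrusionMovie <- function(cfg = protrusionMovieConfig()) {
  stopifnot(inherits(cfg, "ProtrusionMovieConfig"))
  withr::with_seed(cfg$seed, {
    H <- cfg$height; W <- cfg$width
    decay <- if (cfg$profile == "wildtype" && cfg$T > 1L)
      cfg$finalFraction^(1 / (cfg$T - 1)) else 1
    counts <- if (cfg$profile == "wildtype")
      round(cfg$nProtrusions0 * decay^(seq_len(cfg$T) - 1))
    else rep(cfg$nProtrusions0, cfg$T)
    texture <- cfg$background *
      (1 + cfg$textureRelSd * EBImage::imageData(EBImage::gblur(
        EBImage::Image(matrix(stats::rnorm(H * W), H, W)), sigma = 8
      )))
    texture <- pmax(texture, 1)
    arr <- array(0, c(cfg$T, H, W))
    truth <- data.frame(t = seq_len(cfg$T) - 1L, n_protrusions = counts,
                        true_coverage = 0)
    lenMu <- log(cfg$lengthMeanUm)
    for (t in seq_len(cfg$T)) {
      mask <- matrix(FALSE, H, W)
      n <- counts[t]
      if (n > 0) {
        cy <- stats::runif(n, 2, H - 1)
        cx <- stats::runif(n, 2, W - 1)
        ang <- stats::runif(n, 0, pi)
        lenPx <- stats::rlnorm(n, lenMu, cfg$lengthSdLog) / cfg$pixelSizeUm
        for (i in seq_len(n))
          mask <- .drawSegment(mask, cy[i], cx[i], ang[i], lenPx[i])
      }
      truth$true_coverage[t] <- sum(skeletonize(mask)) / (H * W)
      lines <- EBImage::imageData(EBImage::gblur(
        EBImage::Image(matrix(as.numeric(mask), H, W)), sigma = 1
      ))
      signal <- (texture + cfg$amplitude * lines) * exp(-cfg$bleachRate * (t - 1))
      arr[t, , ] <- pmin(.cameraNoise(signal, cfg$gain, cfg$readNoiseSd), 65535)
    }
    list(
      stack = ImageStack(arr, cfg$pixelSizeUm, cfg$frameIntervalS),
      truth = truth, config = cfg
    )
  })
}

#' Puncta movie configuration
#'
#' Emulates apical endosome imaging: diffraction-limited Gaussian spots
#' born at a Poisson rate that follows a piecewise-constant stage schedule
#' (early/mid/late thirds of the movie; default multipliers 1/3/5, so the
#' late/early structure ratio is 5; use `c(1, 2, 3)` for a threefold
#' regime). With `zPlanes > 1` the generator instead renders independent
#' object sets per z section (expected count `baseBirthRate * lifetime *
#' multiplier` per plane) for sub-apical per-section counting.
#'
#' @param T frames, default 60.
#' @param height,width field (px), default 512 (an 82 x 82 um field at the
#'   default sampling, large enough that per-frame occupancies concentrate
#'   and dense late-stage frames stay below the crowding regime).
#' @param pixelSizeUm um/px, default 0.16.
#' @param frameIntervalS s/frame, default 40.
#' @param baseBirthRate expected births per frame in the early stage,
#'   default 16 (early-stage occupancy ~ 48 objects per field).
#' @param stageMultipliers length-3 positive multipliers (early, mid,
#'   late), default `c(1, 3, 5)`.
#' @param lifetimeFrames frames each object persists, default 3.
#' @param peakIntensity mean spot peak amplitude (ADU), default 120 (peak
#'   SNR ~ 10).
#' @param psfSigmaPx Gaussian PSF sigma (px), default 1.5.
#' @param background mean background (ADU), default 100.
#' @param gain,readNoiseSd camera model, defaults 1 and 3.
#' @param zPlanes z sections per time point (default 1 = planar movie).
#' @param zSpacingUm z spacing (um), default 0.2.
#' @param ratePerFrame optional length-`T` per-frame birth rates overriding
#'   the stage schedule.
#' @param seed RNG seed.
#' @return Config list of class `PunctaMovieConfig`.
#' @export
punctaMovieConfig <- function(T = 60L, height = 512L, width = 512L,
                              pixelSizeUm = 0.16, frameIntervalS = 40,
                              baseBirthRate = 16, stageMultipliers = c(1, 3, 5),
                              lifetimeFrames = 3L, peakIntensity = 120,
                              psfSigmaPx = 1.5, background = 100, gain = 1,
                              readNoiseSd = 3, zPlanes = 1L, zSpacingUm = 0.2,
                              ratePerFrame = NULL, seed = 1L) {
  stopifnot(T >= 1, height >= 8, width >= 8, baseBirthRate >= 0,
            length(stageMultipliers) == 3, all(stageMultipliers > 0),
            lifetimeFrames >= 1, psfSigmaPx > 0, background > 0, zPlanes >= 1)
  if (!is.null(ratePerFrame) && length(ratePerFrame) != T)
    stop("ratePerFrame must have length T (schedule must cover all frames)")
  structure(as.list(environment()), class = "PunctaMovieConfig")
}

# Per-frame birth rates under the early/mid/late thirds schedule.
.stageRates <- function(cfg) {
  if (!is.null(cfg$ratePerFrame)) return(cfg$ratePerFrame)
  stage <- pmin(ceiling(3 * seq_len(cfg$T) / cfg$T), 3)
  cfg$baseBirthRate * cfg$stageMultipliers[stage]
}

.renderSpots <- function(H, W, y, x, amp, sigma) {
  img <- matrix(0, H, W)
  r <- ceiling(4 * sigma)
  for (i in seq_along(y)) {
    y0 <- max(1, floor(y[i] - r)); y1 <- min(H, ceiling(y[i] + r))
    x0 <- max(1, floor(x[i] - r)); x1 <- min(W, ceiling(x[i] + r))
    if (y0 > y1 || x0 > x1) next
    yy <- y0:y1; xx <- x0:x1
    img[yy, xx] <- img[yy, xx] + amp[i] * outer(
      exp(-(yy - y[i])^2 / (2 * sigma^2)),
      exp(-(xx - x[i])^2 / (2 * sigma^2))
    )
  }
  img
}

#' Generate a synthetic puncta movie (or z-stack) with ground truth
#'
#' @param cfg a [punctaMovieConfig()].
#' @return List with `stack` (planar `T x Y x X`, or `T x Z x Y x X` when
#'   `zPlanes > 1`), `truth` (data.frame of every latent object: `t`,
#'   optionally `z`, `id`, `y_um`, `x_um`, `peak`), and `config`.
#' @export
genPunctaMovie <- function(cfg = punctaMovieConfig()) {
  stopifnot(inherits(cfg, "PunctaMovieConfig"))
  withr::with_seed(cfg$seed, {
    H <- cfg$height; W <- cfg$width
    rates <- .stageRates(cfg)
    if (cfg$zPlanes > 1L) {
      arr <- array(0, c(cfg$T, cfg$zPlanes, H, W))
      rows <- list()
      id <- 0L
      for (t in seq_len(cfg$T)) for (z in seq_len(cfg$zPlanes)) {
        n <- stats::rpois(1, rates[t] * cfg$lifetimeFrames)
        y <- stats::runif(n, 5, H - 4); x <- stats::runif(n, 5, W - 4)
        amp <- cfg$peakIntensity * stats::runif(n, 0.8, 1.2)
        sig <- cfg$background + .renderSpots(H, W, y, x, amp, cfg$psfSigmaPx)
        arr[t, z, , ] <- pmin(.cameraNoise(sig, cfg$gain, cfg$readNoiseSd), 65535)
        if (n > 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            t = t - 1L, z = z, id = id + seq_len(n),
            y_um = (y - 1) * cfg$pixelSizeUm, x_um = (x - 1) * cfg$pixelSizeUm,
            peak = amp
          )
          id <- id + n
        }
      }
      truth <- if (length(rows)) do.call(rbind, rows) else
        data.frame(t = integer(0), z = integer(0), id = integer(0),
                   y_um = numeric(0), x_um = numeric(0), peak = numeric(0))
      return(list(
        stack = ImageStack(arr, cfg$pixelSizeUm, cfg$frameIntervalS,
                           cfg$zSpacingUm),
        truth = truth, config = cfg
      ))
    }
    # planar movie: Poisson births, objects persist lifetimeFrames frames.
    # Births start lifetime-1 frames before frame 1 (at the early-stage
    # rate), so the expected occupancy is stationary from the first frame.
    t0s <- (2L - cfg$lifetimeFrames):cfg$T
    births <- stats::rpois(length(t0s), rates[pmax(t0s, 1L)])
    ob <- list()
    id <- 0L
    for (j in seq_along(t0s)) {
      t <- t0s[j]
      n <- births[j]
      if (n == 0) next
      ob[[length(ob) + 1L]] <- data.frame(
        id = id + seq_len(n), born = max(t, 1L),
        dies = pmin(t + cfg$lifetimeFrames - 1L, cfg$T),
        y = stats::runif(n, 5, H - 4), x = stats::runif(n, 5, W - 4),
        peak = cfg$peakIntensity * stats::runif(n, 0.8, 1.2)
      )
      id <- id + n
    }
    objects <- if (length(ob)) do.call(rbind, ob) else
      data.frame(id = integer(0), born = integer(0), dies = integer(0),
                 y = numeric(0), x = numeric(0), peak = numeric(0))
    arr <- array(0, c(cfg$T, H, W))
    rows <- list()
    for (t in seq_len(cfg$T)) {
      live <- objects[objects$born <= t & objects$dies >= t, , drop = FALSE]
      sig <- cfg$background +
        .renderSpots(H, W, live$y, live$x, live$peak, cfg$psfSigmaPx)
      arr[t, , ] <- pmin(.cameraNoise(sig, cfg$gain, cfg$readNoiseSd), 65535)
      if (nrow(live))
        rows[[length(rows) + 1L]] <- data.frame(
          t = t - 1L, id = live$id,
          y_um = (live$y - 1) * cfg$pixelSizeUm,
          x_um = (live$x - 1) * cfg$pixelSizeUm, peak = live$peak
        )
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(t = integer(0), id = integer(0), y_um = numeric(0),
                 x_um = numeric(0), peak = numeric(0))
    rownames(truth) <- NULL
    list(
      stack = ImageStack(arr, cfg$pixelSizeUm, cfg$frameIntervalS),
      truth = truth, config = cfg
    )
  })
}

#' Track scene configuration
#'
#' Emulates a sagittal view of apical endosome dynamics: particles are born
#' within the apical band; a fraction descends basally at constant speed to
#' a per-particle target depth (default mean 15 um, SD 2) and terminates,
#' the rest random-walk within the band. The furrow front descends linearly
#' and independently. Births stop `birthMarginFrames` before the movie end
#' so descents complete within the recording. The descending fraction
#' (default 0.7) is an order-of-magnitude choice, not a measured value.
#'
#' @param T frames, default 100.
#' @param fieldDepthUm,fieldWidthUm sagittal field size (um), defaults 40
#'   and 50.
#' @param apicalReferenceUm apical surface depth coordinate (um), default 2.
#' @param birthRate expected particle births per frame, default 1.2.
#' @param birthMarginFrames no births in the last this-many frames,
#'   default 30.
#' @param fractionDescending probability a particle descends, default 0.7.
#' @param descentSpeedUmPerFrame basal speed of descending particles,
#'   default 1.
#' @param targetDepthMeanUm,targetDepthSdUm normal target depth below the
#'   reference (um), defaults 15 and 2 (truncated at 6 so every descending
#'   particle exits the 5-um band).
#' @param birthBandUm particles are born within this depth of the
#'   reference, default 4.5 (inside the 5-um origin filter with margin for
#'   detection jitter).
#' @param persistentStepSdUm random-walk step SD of persistent particles
#'   (um/frame), default 0.3, reflected within the birth band.
#' @param persistentMeanLifetime mean persistent-track lifetime (frames),
#'   default 20 (minimum 6).
#' @param detectionNoiseSdUm Gaussian jitter added to emitted detections
#'   (um), default 0.1.
#' @param furrowStartUm,furrowEndUm linear furrow-front schedule (um below
#'   the reference), defaults 0 and 30.
#' @param seed RNG seed.
#' @return Config list of class `TrackSceneConfig`.
#' @export
trackSceneConfig <- function(T = 100L, fieldDepthUm = 40, fieldWidthUm = 50,
                             apicalReferenceUm = 2, birthRate = 1.2,
                             birthMarginFrames = 30L, fractionDescending = 0.7,
                             descentSpeedUmPerFrame = 1.0,
                             targetDepthMeanUm = 15, targetDepthSdUm = 2,
                             birthBandUm = 4.5, persistentStepSdUm = 0.3,
                             persistentMeanLifetime = 20,
                             detectionNoiseSdUm = 0.1,
                             furrowStartUm = 0, furrowEndUm = 30, seed = 1L) {
  stopifnot(T >= 2, fieldDepthUm > 0, fieldWidthUm > 0, birthRate >= 0,
            fractionDescending >= 0, fractionDescending <= 1,
            descentSpeedUmPerFrame > 0, targetDepthMeanUm > 0,
            targetDepthSdUm >= 0, birthBandUm > 0, detectionNoiseSdUm >= 0,
            furrowStartUm >= 0, furrowEndUm >= furrowStartUm)
  structure(as.list(environment()), class = "TrackSceneConfig")
}

#' Generate a synthetic tracking scene with ground truth
#'
#' @param cfg a [trackSceneConfig()].
#' @return List with `detections` (data.frame `t`, `y_um`, `x_um`,
#'   `intensity`, plus the ground-truth column `true_track_id`, which the
#'   tracker must ignore), `truth` (per-track: `track_id`, `class`,
#'   `birth_frame`, `death_frame`, `origin_depth_um`, `max_depth_um`),
#'   `furrow` (per-frame depth, um), and `config`.
#' @export
genTrackScene <- function(cfg = trackSceneConfig()) {
  stopifnot(inherits(cfg, "TrackSceneConfig"))
  withr::with_seed(cfg$seed, {
    lastBirth <- max(1L, cfg$T - cfg$birthMarginFrames)
    births <- stats::rpois(lastBirth, cfg$birthRate)
    detRows <- list()
    truthRows <- list()
    id <- 0L
    for (t0 in seq_len(lastBirth)) {
      for (b in seq_len(births[t0])) {
        id <- id + 1L
        descending <- stats::runif(1) < cfg$fractionDescending
        depth0 <- stats::runif(1, 0, cfg$birthBandUm)
        x0 <- stats::runif(1, 1, cfg$fieldWidthUm - 1)
        if (descending) {
          target <- max(6, stats::rnorm(1, cfg$targetDepthMeanUm,
                                        cfg$targetDepthSdUm))
          target <- min(target, cfg$fieldDepthUm - cfg$apicalReferenceUm - 1)
          nstep <- ceiling((target - depth0) / cfg$descentSpeedUmPerFrame)
          depths <- pmin(depth0 + (0:nstep) * cfg$descentSpeedUmPerFrame, target)
        } else {
          life <- 6L + stats::rpois(1, max(cfg$persistentMeanLifetime - 6, 0))
          steps <- stats::rnorm(life - 1L, 0, cfg$persistentStepSdUm)
          depths <- numeric(life)
          depths[1] <- depth0
          for (k in 2:life) {
            d <- depths[k - 1] + steps[k - 1]
            # reflect within [0, birthBandUm]
            d <- abs(d)
            if (d > cfg$birthBandUm) d <- 2 * cfg$birthBandUm - d
            depths[k] <- min(max(d, 0), cfg$birthBandUm)
          }
        }
        tt <- t0 + seq_along(depths) - 1L
        keep <- tt <= cfg$T
        tt <- tt[keep]; depths <- depths[keep]
        if (length(tt) == 0L) next
        xs <- x0 + cumsum(c(0, stats::rnorm(length(tt) - 1L, 0, 0.1)))
        truthRows[[id]] <- data.frame(
          track_id = id, class = if (descending) "descending" else "persistent",
          birth_frame = tt[1], death_frame = tt[length(tt)],
          origin_depth_um = depths[1], max_depth_um = max(depths)
        )
        detRows[[id]] <- data.frame(
          t = tt,
          y_um = cfg$apicalReferenceUm + depths +
            stats::rnorm(length(tt), 0, cfg$detectionNoiseSdUm),
          x_um = xs + stats::rnorm(length(tt), 0, cfg$detectionNoiseSdUm),
          intensity = 100 + stats::rnorm(length(tt), 0, 5),
          true_track_id = id
        )
      }
    }
    detections <- if (length(detRows)) do.call(rbind, detRows) else
      data.frame(t = integer(0), y_um = numeric(0), x_um = numeric(0),
                 intensity = numeric(0), true_track_id = integer(0))
    detections <- detections[order(detections$t, detections$y_um,
                                   detections$x_um), , drop = FALSE]
    rownames(detections) <- NULL
    truth <- if (length(truthRows)) do.call(rbind, truthRows) else
      data.frame(track_id = integer(0), class = character(0),
                 birth_frame = integer(0), death_frame = integer(0),
                 origin_depth_um = numeric(0), max_depth_um = numeric(0))
    furrow <- seq(cfg$furrowStartUm, cfg$furrowEndUm, length.out = cfg$T)
    list(detections = detections, truth = truth, furrow = furrow, config = cfg)
  })
}

#' Colocalization pair configuration
#'
#' Two-channel object scenes with a known labelled-overlap fraction:
#' exactly `n` non-overlapping Gaussian blobs in the reference channel, of
#' which `floor(f * n)` are duplicated at the same positions in the partner
#' channel (full overlap by construction) alongside `nDistractors`
#' partner-only blobs at disjoint positions.
#'
#' @param nObjects reference object count, default 100.
#' @param overlapFraction true positive fraction `f`, in `[0, 1]`,
#'   default 0.8.
#' @param height,width field (px), default 256.
#' @param pixelSizeUm um/px, default 0.16.
#' @param blobSigmaPx Gaussian blob sigma (px), default 2.
#' @param peakIntensity blob peak (ADU), default 150.
#' @param background mean background (ADU), default 100.
#' @param nDistractors partner-only objects, default 30.
#' @param minSeparationPx minimum centre-to-centre distance, default 12.
#' @param gain,readNoiseSd camera model, defaults 1 and 3.
#' @param seed RNG seed.
#' @return Config list of class `ColocPairConfig`.
#' @export
colocPairConfig <- function(nObjects = 100L, overlapFraction = 0.8, height = 256L,
                            width = 256L, pixelSizeUm = 0.16, blobSigmaPx = 2,
                            peakIntensity = 150, background = 100,
                            nDistractors = 30L, minSeparationPx = 12,
                            gain = 1, readNoiseSd = 3, seed = 1L) {
  stopifnot(nObjects >= 1, overlapFraction >= 0, overlapFraction <= 1,
            height >= 8, width >= 8, blobSigmaPx > 0, minSeparationPx > 0)
  structure(as.list(environment()), class = "ColocPairConfig")
}

# Poisson-disk style rejection sampling of k centres at >= minSep from each
# other and from existing points.
.packCentres <- function(k, H, W, minSep, existing = NULL, margin = 8) {
  pts <- existing
  out <- matrix(0, 0, 2)
  tries <- 0L
  maxTries <- 400L * k
  while (nrow(out) < k) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("infeasible packing: cannot place ", k,
           " objects at separation ", minSep, " px in a ", H, " x ", W, " field")
    p <- c(stats::runif(1, margin, H - margin), stats::runif(1, margin, W - margin))
    all <- rbind(pts, out)
    if (is.null(all) || nrow(all) == 0L ||
        min((all[, 1] - p[1])^2 + (all[, 2] - p[2])^2) >= minSep^2) {
      out <- rbind(out, p)
    }
  }
  out
}

#' Generate a synthetic two-channel colocalization pair with ground truth
#'
#' @param cfg a [colocPairConfig()].
#' @return List with `ref` and `partner` (single-frame
#'   [ImageStack-class]s), `truth` (data.frame `id`, `y_um`, `x_um`,
#'   `positive`; exactly `floor(f * n)` positives), and `config`.
#' @export
genColocPair <- function(cfg = colocPairConfig()) {
  stopifnot(inherits(cfg, "ColocPairConfig"))
  withr::with_seed(cfg$seed, {
    H <- cfg$height; W <- cfg$width
    refC <- .packCentres(cfg$nObjects, H, W, cfg$minSeparationPx)
    k <- floor(cfg$overlapFraction * cfg$nObjects)
    pos <- sort(sample.int(cfg$nObjects, k))
    distC <- .packCentres(cfg$nDistractors, H, W, cfg$minSeparationPx,
                          existing = refC)
    amp <- cfg$peakIntensity * stats::runif(cfg$nObjects, 0.8, 1.2)
    ampD <- cfg$peakIntensity * stats::runif(cfg$nDistractors, 0.8, 1.2)
    refImg <- cfg$background +
      .renderSpots(H, W, refC[, 1], refC[, 2], amp, cfg$blobSigmaPx)
    partC <- rbind(refC[pos, , drop = FALSE], distC)
    partAmp <- c(amp[pos], ampD)
    partImg <- cfg$background +
      .renderSpots(H, W, partC[, 1], partC[, 2], partAmp, cfg$blobSigmaPx)
    refA <- array(pmin(.cameraNoise(refImg, cfg$gain, cfg$readNoiseSd), 65535),
                  c(1, H, W))
    partA <- array(pmin(.cameraNoise(partImg, cfg$gain, cfg$readNoiseSd), 65535),
                   c(1, H, W))
    truth <- data.frame(
      id = seq_len(cfg$nObjects),
      y_um = (refC[, 1] - 1) * cfg$pixelSizeUm,
      x_um = (refC[, 2] - 1) * cfg$pixelSizeUm,
      positive = seq_len(cfg$nObjects) %in% pos
    )
    list(
      ref = ImageStack(refA, cfg$pixelSizeUm, 1),
      partner = ImageStack(partA, cfg$pixelSizeUm, 1),
      truth = truth, config = cfg
    )
  })
}
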