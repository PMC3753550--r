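# Independent oracles used to cross-check the package implementations.
# These are deliberately written from the definitions, with different code
# paths (explicit loops, ecdf(), exhaustive search) than the package.

# Trim both intensity tails, then mean + k * population SD.
oracleRobustThreshold <- function(x, trimFraction = 0.05, kSd = 2) {
  v <- sort(as.numeric(x))
  k <- floor(trimFraction * length(v))
  kept <- v[(k + 1):(length(v) - k)]
  m <- sum(kept) / length(kept)
  s <- sqrt(sum((kept - m)^2) / length(kept))
  m + kSd * s
}

# Exhaustive-permutation two-sample KS test.
oracleKs <- function(a, b) {
  Dof <- function(x, y) {
    z <- sort(unique(c(x, y)))
    max(abs(stats::ecdf(x)(z) - stats::ecdf(y)(z)))
  }
  pooled <- c(a, b)
  n <- length(a)
  D <- Dof(a, b)
  combos <- utils::combn(length(pooled), n)
  Dp <- apply(combos, 2, function(ix) Dof(pooled[ix], pooled[-ix]))
  list(statistic = D, p.value = mean(Dp >= D - 1e-12))
}

# Zhang-Suen thinning, plain-R re-implementation with explicit loops.
oracleThin <- function(mask) {
  img <- mask != 0
  nr <- nrow(img); nc <- ncol(img)
  at <- function(r, c) {
    if (r < 1 || r > nr || c < 1 || c > nc) 0L else as.integer(img[r, c])
  }
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      del <- matrix(FALSE, nr, nc)
      for (r in seq_len(nr)) for (c in seq_len(nc)) {
        if (!img[r, c]) next
        p <- c(at(r - 1, c), at(r - 1, c + 1), at(r, c + 1), at(r + 1, c + 1),
               at(r + 1, c), at(r + 1, c - 1), at(r, c - 1), at(r - 1, c - 1))
        B <- sum(p)
        if (B < 2 || B > 6) next
        A <- sum(p == 0 & c(p[-1], p[1]) == 1)
        if (A != 1) next
        if (step == 0) {
          if (p[1] * p[3] * p[5] != 0 || p[3] * p[5] * p[7] != 0) next
        } else {
          if (p[1] * p[3] * p[7] != 0 || p[1] * p[5] * p[7] != 0) next
        }
        del[r, c] <- TRUE
      }
      if (any(del)) {
        img[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

# Exhaustive-search Otsu threshold on a 256-bin histogram of v: the
# bin-edge threshold maximizing between-class variance.
oracleOtsu <- function(v, levels = 256L) {
  br <- seq(min(v), max(v), length.out = levels + 1L)
  h <- graphics::hist(v, breaks = br, plot = FALSE)
  best <- -Inf
  bestTh <- br[2]
  n <- sum(h$counts)
  for (k in seq_len(levels - 1L)) {
    w0 <- sum(h$counts[1:k]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h$counts[1:k] * h$mids[1:k]) / sum(h$counts[1:k])
    mu1 <- sum(h$counts[(k + 1):levels] * h$mids[(k + 1):levels]) /
      sum(h$counts[(k + 1):levels])
    vb <- w0 * w1 * (mu0 - mu1)^2
    if (vb > best) {
      best <- vb
      bestTh <- br[k + 1L]
    }
  }
  bestTh
}

# Fraction of ground-truth consecutive-frame links recovered by a TrackSet.
# `det` must carry a true_track_id column; recovered ids are matched to
# detections by (t, y, x).
linkAccuracy <- function(det, trackset) {
  rec <- trackTable(trackset)
  key <- paste(det$t, round(det$y_um, 9), round(det$x_um, 9))
  recKey <- paste(rec$t, round(rec$y_um, 9), round(rec$x_um, 9))
  recId <- rec$track_id[match(key, recKey)]
  total <- 0L
  ok <- 0L
  for (id in unique(det$true_track_id)) {
    i <- which(det$true_track_id == id)
    if (length(i) < 2) next
    total <- total + length(i) - 1L
    ok <- ok + sum(recId[i[-1]] == recId[i[-length(i)]], na.rm = TRUE)
  }
  ok / total
}

# Majority-vote map from recovered tracks to true track ids, then the
# fraction of recovered tracks whose class matches the truth table.
classAgreement <- function(det, trackset, truth) {
  rec <- trackTable(trackset)
  key <- paste(det$t, round(det$y_um, 9), round(det$x_um, 9))
  recKey <- paste(rec$t, round(rec$y_um, 9), round(rec$x_um, 9))
  trueId <- det$true_track_id[match(recKey, key)]
  smr <- trackSummary(trackset)
  maj <- vapply(split(trueId, rec$track_id), function(v)
    as.integer(names(sort(table(v), decreasing = TRUE))[1]), integer(1))
  trueClass <- truth$class[match(maj[as.character(smr$track_id)], truth$track_id)]
  mean(smr$class == trueClass)
}

# Detection settings calibrated for the synthetic study conditions
# (3-sigma limit, minimum area ~ half the PSF above-half-max area).
calibratedRB <- function() robustBackgroundParams(kSd = 3)
CAL_MIN_AREA <- 5L
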