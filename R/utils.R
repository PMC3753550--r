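# Internal helpers shared across modules.

# One line per pipeline stage to standard error, for auditability of the
# filter rules applied to a run.
.logStage <- function(stage, fmt, ...) {
  message(sprintf("[ApicalQuant] %s: %s", stage, sprintf(fmt, ...)))
}

# Symmetric (mirror) padding of a matrix by hw pixels on every side.
.reflectPad <- function(m, hw) {
  nr <- nrow(m); nc <- ncol(m)
  if (hw >= nr || hw >= nc)
    stop("frame smaller than filter kernel: increase frame size or reduce kernel_halfwidth")
  ri <- c(hw:1, seq_len(nr), nr:(nr - hw + 1L))
  ci <- c(hw:1, seq_len(nc), nc:(nc - hw + 1L))
  m[ri, ci, drop = FALSE]
}

# Mixed Poisson-Gaussian camera model: shot noise on gain-scaled signal plus
# additive read noise, clamped at zero and quantized to integer ADU.
.cameraNoise <- function(signal, gain = 1, readSd = 3) {
  n <- length(signal)
  shot <- stats::rpois(n, lambda = pmax(gain * signal, 0)) / gain
  out <- shot + stats::rnorm(n, sd = readSd)
  out <- round(pmax(out, 0))
  array(out, dim = dim(signal) %||% n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Population (not sample) standard deviation.
.popSd <- function(x) sqrt(mean((x - mean(x))^2))

# Otsu threshold on a fixed-bin histogram via the cumulative-moment form of
# the between-class variance; returns the bin-edge threshold. Used on the
# positive part of filter responses; an exhaustive-search oracle verifies it
# in the tests.
.otsuOnValues <- function(v, levels = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(v[1] / 2)
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = levels + 1L),
                      plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  w <- counts / sum(counts)
  mu <- cumsum(w * mids)
  om <- cumsum(w)
  muT <- mu[length(mu)]
  # between-class variance for threshold after bin k
  sigmaB <- (muT * om - mu)^2 / (om * (1 - om))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  k <- which.max(sigmaB[-length(sigmaB)])
  h$breaks[k + 1L]
}

# Deterministic seed derivation for sub-streams, kept below 2^31.
.deriveSeed <- function(seed, offset) {
  (as.integer(seed) %% 100000L) * 1000L + as.integer(offset) %% 1000L
}
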