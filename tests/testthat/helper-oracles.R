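# Independent reference implementations used as oracles. These deliberately
# avoid the vectorised/incremental code paths of the package: convolution is
# a double loop, the detector recomputes its threshold naively over the
# trailing window at every sample.

# Brute-force causal convolution with zero-padded history.
naive_convolve <- function(x, taps) {
  n <- length(x)
  L <- length(taps)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_len(L)) {
      j <- i - (k - 1L)
      if (j >= 1L) acc <- acc + taps[k] * x[j]
    }
    y[i] <- acc
  }
  y
}

# Naive per-sample dynamic threshold: mean/variance/RMS recomputed from the
# raw trailing window (partial during warm-up).
naive_gradient <- function(x, window, gain = 1, cv_mode = "variance") {
  n <- length(x)
  g <- numeric(n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - window + 1L):i]
    m <- sum(w) / length(w)
    cv <- sum((w - m)^2) / length(w)
    if (cv_mode == "std") cv <- sqrt(cv)
    rms <- sqrt(sum(w^2) / length(w))
    g[i] <- rms * cv / 100 * gain
  }
  g
}

# Offline re-derivation of the hysteresis peak set: walks the samples with
# explicit running extrema and the naive per-sample gradient. Returns peak
# indices only.
naive_peaks <- function(x, window, gain = 1) {
  g <- naive_gradient(x, window, gain)
  peaks <- integer(0)
  state <- "undecided"
  hi_i <- 1L; hi_v <- x[1L]
  lo_i <- 1L; lo_v <- x[1L]
  i <- 2L
  n <- length(x)
  while (i <= n) {
    if (state != "falling" && x[i] > hi_v) { hi_v <- x[i]; hi_i <- i }
    if (state != "rising" && x[i] < lo_v) { lo_v <- x[i]; lo_i <- i }
    if (state != "falling" && x[i] < hi_v - g[i]) {
      peaks <- c(peaks, hi_i)
      state <- "falling"
      lo_v <- x[i]; lo_i <- i
    } else if (state != "rising" && x[i] > lo_v + g[i]) {
      state <- "rising"
      hi_v <- x[i]; hi_i <- i
    }
    i <- i + 1L
  }
  peaks
}

# Smooth random test signal: integrated white noise, detrended and lightly
# smoothed so it develops genuine peaks and troughs at many scales.
random_smooth_signal <- function(n, seed) {
  set.seed(seed)
  x <- cumsum(rnorm(n))
  x <- x - seq(x[1L], x[n], length.out = n)
  k <- 9L
  as.numeric(stats::filter(c(rep(x[1L], k), x, rep(x[n], k)),
                           rep(1 / (2 * k + 1), 2 * k + 1),
                           sides = 2))[(k + 1L):(k + n)]
}
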