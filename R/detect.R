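# Dynamic-threshold (hysteresis) pulse peak/trough detection. The threshold
# ("gradient") is recomputed at every sample from the trailing window:
# gradient = RMS * CV / 100 * gain, where CV is the population variance of
# the window (units mV^2) and RMS its root-mean-square level. The detector is
# a two-state machine: a peak is emitted when the signal falls `gradient`
# below the running local maximum; a trough when it rises `gradient` above
# the running local minimum.

#' Threshold parameters for the dynamic-gradient detector
#'
#' @param sample_rate_hz Sampling rate, used for the default window.
#' @param window_samples Trailing window length; default half the sampling
#'   rate (0.5 s), which sets the responsiveness of the threshold.
#' @param gain Multiplicative level adjustment, default 1. Raising the gain
#'   suppresses false peaks on low-SNR signals.
#' @param cv_mode `"variance"` (default) evaluates CV as the population
#'   variance in mV^2, making the gradient scale with amplitude cubed;
#'   `"std"` uses the standard deviation instead (gradient scales with
#'   amplitude squared). See the methods vignette for the scale analysis.
#' @param update `"sliding"` (default) recomputes the gradient at every
#'   sample over the trailing window; `"block"` recomputes once per window
#'   and holds it constant in between.
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(sample_rate_hz = 5000,
                             window_samples = round(sample_rate_hz / 2),
                             gain = 1,
                             cv_mode = c("variance", "std"),
                             update = c("sliding", "block")) {
  cv_mode <- match.arg(cv_mode)
  update <- match.arg(update)
  window_samples <- as.integer(window_samples)
  if (window_samples < 2L) stop("threshold_params: window_samples must be >= 2", call. = FALSE)
  if (!is.finite(gain) || gain <= 0) stop("threshold_params: gain must be > 0", call. = FALSE)
  structure(list(window_samples = window_samples, gain = gain,
                 cv_mode = cv_mode, update = update),
            class = "threshold_params")
}

#' Mean amplitude of a window
#' @param values Non-empty numeric window (mV).
#' @return Arithmetic mean (mV).
#' @export
window_mean <- function(values) {
  if (length(values) == 0L) stop("window_mean: empty window", call. = FALSE)
  mean(values)
}

#' Amplitude variability (CV) of a window
#'
#' Population variance `sum((x - mean)^2) / N`, in mV^2. Despite the name
#' "CV" used in the threshold formula this is a variance, not a coefficient
#' of variation; it measures how strongly the recent signal has been moving.
#'
#' @param values Non-empty numeric window (mV).
#' @return Population variance (mV^2).
#' @export
window_cv <- function(values) {
  if (length(values) == 0L) stop("window_cv: empty window", call. = FALSE)
  m <- mean(values)
  mean((values - m)^2)
}

#' Root-mean-square level of a window
#' @param values Non-empty numeric window (mV).
#' @return `sqrt(mean(x^2))` (mV).
#' @export
window_rms <- function(values) {
  if (length(values) == 0L) stop("window_rms: empty window", call. = FALSE)
  sqrt(mean(values^2))
}

#' Dynamic threshold over one window
#'
#' `gradient = RMS * CV / 100 * gain` with CV per [window_cv()] (or its
#' square root when `cv_mode = "std"`). Always non-negative; zero for a
#' constant window.
#'
#' @param values Non-empty numeric window (mV).
#' @param params A [threshold_params()].
#' @return Threshold value (mV in "std" mode; mV^3/100-scaled in the literal
#'   "variance" mode).
#' @export
dynamic_gradient <- function(values, params = threshold_params()) {
  cv <- window_cv(values)
  if (params$cv_mode == "std") cv <- sqrt(cv)
  window_rms(values) * cv / 100 * params$gain
}

#' Per-sample gradient series over a trace
#'
#' Vectorised trailing-window evaluation of [dynamic_gradient()] at every
#' sample. During warm-up (the first `window_samples - 1` samples) the window
#' is the partial history available so far.
#'
#' @param x Numeric sample vector.
#' @param params A [threshold_params()].
#' @return Numeric vector, `length(x)` gradients (non-negative).
#' @export
gradient_series <- function(x, params = threshold_params()) {
  n <- length(x)
  W <- params$window_samples
  cs <- cumsum(x)
  cs2 <- cumsum(x * x)
  i <- seq_len(n)
  lo <- pmax(i - W, 0L)
  len <- i - lo
  sum1 <- cs - c(0, cs)[lo + 1L]
  sum2 <- cs2 - c(0, cs2)[lo + 1L]
  m <- sum1 / len
  ms2 <- sum2 / len
  cv <- pmax(ms2 - m * m, 0)
  if (params$cv_mode == "std") cv <- sqrt(cv)
  g <- sqrt(ms2) * cv / 100 * params$gain
  if (params$update == "block") {
    # hold the gradient computed at each window boundary
    anchor <- pmax(W, (ceiling(i / W) - 1L) * W)
    anchor[i <= W] <- i[i <= W]  # warm-up: use current partial value
    g <- g[anchor]
  }
  g
}

#' Detect pulse-wave rise/peak/fall/trough events
#'
#' Streaming two-state hysteresis detector. In rising mode the running local
#' maximum is updated while the signal climbs; when the signal drops below
#' `local_max - gradient` a `peak` event is emitted at the local maximum and a
#' `fall_onset` at the current sample, and the machine switches to falling
#' mode. Symmetrically, in falling mode a `trough` and a `rise_onset` are
#' emitted when the signal rises above `local_min + gradient`. The gradient is
#' the per-sample dynamic threshold of [gradient_series()].
#'
#' The machine starts undecided at the first sample with both running extrema
#' initialised there; the first hysteresis condition to trigger decides the
#' initial mode. Plateau ties resolve to the first sample of the plateau
#' (updates require strict inequality). Events within the warm-up prefix
#' (`warmup_samples`, default the threshold window) are flagged so callers can
#' exclude them from scoring while the threshold is still settling.
#'
#' @param trace A [pulse_trace()] at least `window_samples` long.
#' @param params A [threshold_params()].
#' @param warmup_samples Events at or before this index are flagged
#'   `warmup = TRUE`. Default `params$window_samples`; pipelines add the FIR
#'   group delay on top.
#' @return A data frame with columns `kind` (`rise_onset`/`peak`/`fall_onset`/
#'   `trough`), `index` (1-based), `time_s`, `amplitude` (mV), `warmup`.
#' @export
detect_events <- function(trace, params = threshold_params(trace$sample_rate_hz),
                          warmup_samples = params$window_samples) {
  stopifnot(inherits(trace, "pulse_trace"))
  x <- trace$samples
  n <- length(x)
  if (n < params$window_samples) {
    stop(sprintf("detect_events: trace (%d samples) shorter than threshold window (%d)",
                 n, params$window_samples), call. = FALSE)
  }
  g <- gradient_series(x, params)

  cap <- max(16L, 8L * ceiling(n / 1000L))
  ev_kind <- character(cap); ev_idx <- integer(cap); ev_amp <- numeric(cap)
  n_ev <- 0L
  push <- function(kind, idx, amp) {
    n_ev <<- n_ev + 1L
    if (n_ev > length(ev_idx)) {
      ev_kind <<- c(ev_kind, character(length(ev_kind)))
      ev_idx <<- c(ev_idx, integer(length(ev_idx)))
      ev_amp <<- c(ev_amp, numeric(length(ev_amp)))
    }
    ev_kind[n_ev] <<- kind; ev_idx[n_ev] <<- idx; ev_amp[n_ev] <<- amp
  }

  mode <- 0L  # 0 undecided, 1 rising, -1 falling
  max_i <- 1L; max_v <- x[1L]
  min_i <- 1L; min_v <- x[1L]
  for (i in 2:n) {
    v <- x[i]
    gi <- g[i]
    if (mode >= 0L && v > max_v) { max_v <- v; max_i <- i }
    if (mode <= 0L && v < min_v) { min_v <- v; min_i <- i }
    if (mode >= 0L && v < max_v - gi) {
      push("peak", max_i, max_v)
      push("fall_onset", i, v)
      mode <- -1L
      min_v <- v; min_i <- i
    } else if (mode <= 0L && v > min_v + gi) {
      push("trough", min_i, min_v)
      push("rise_onset", i, v)
      mode <- 1L
      max_v <- v; max_i <- i
    }
  }

  kind <- ev_kind[seq_len(n_ev)]
  idx <- ev_idx[seq_len(n_ev)]
  data.frame(
    kind = kind,
    index = idx,
    time_s = index_to_time(idx, trace$sample_rate_hz),
    amplitude = ev_amp[seq_len(n_ev)],
    warmup = idx <= warmup_samples,
    stringsAsFactors = FALSE
  )
}

#' Extract peak indices from an event table
#'
#' @param events Data frame from [detect_events()].
#' @param include_warmup Keep warm-up peaks? Default `FALSE`.
#' @return Integer vector of peak sample indices.
#' @export
event_peaks <- function(events, include_warmup = FALSE) {
  keep <- events$kind == "peak"
  if (!include_warmup) keep <- keep & !events$warmup
  events$index[keep]
}
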