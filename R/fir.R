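# Kaiser-window FIR band-pass design and application. The design chain is
# authored from its primitives (series I0, window, ideal band-pass sinc)
# because the chain itself is the method under test; application uses the
# C convolution behind stats::filter, checked against a brute-force oracle
# in the test suite.

#' Modified Bessel function of the first kind, order zero
#'
#' Power-series evaluation `I0(x) = sum_i ((x/2)^i / i!)^2`, truncated when a
#' term falls below 1e-16 of the running sum. This is the kernel of the Kaiser
#' window shape.
#'
#' @param x Non-negative real, vectorised.
#' @return `I0(x)`.
#' @examples
#' bessel_i0(1)           # 1.266066
#' besselI(1, 0)          # same, base R
#' @export
bessel_i0 <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("bessel_i0: x must be finite and >= 0", call. = FALSE)
  }
  vapply(x, function(xi) {
    term <- 1.0
    total <- 1.0
    i <- 1L
    half <- xi / 2
    repeat {
      term <- term * (half / i)^2
      total <- total + term
      if (term < 1e-16 * total) break
      i <- i + 1L
      if (i > 1000L) break  # safety; never reached for sane x
    }
    total
  }, numeric(1))
}

#' Kaiser window of length N + 1
#'
#' `w[n] = I0(beta * sqrt(1 - (2n/N - 1)^2)) / I0(beta)` for `0 <= n <= N`.
#' Symmetric, with `w[N/2] = 1` and endpoints `1 / I0(beta)`. `beta = 0`
#' degenerates to the rectangular window.
#'
#' @param N Window size (even integer >= 2); the window has `N + 1` points.
#' @param beta Shape parameter, >= 0. Larger beta lowers sidelobes at the cost
#'   of a wider main lobe.
#' @return Numeric vector of `N + 1` weights.
#' @export
kaiser_window <- function(N, beta) {
  if (N < 2 || N %% 2 != 0) stop("kaiser_window: N must be an even integer >= 2", call. = FALSE)
  if (!is.finite(beta) || beta < 0) stop("kaiser_window: beta must be >= 0", call. = FALSE)
  n <- 0:N
  arg <- 1 - (2 * n / N - 1)^2
  arg[arg < 0] <- 0  # guard fp round-off at the endpoints
  bessel_i0(beta * sqrt(arg)) / bessel_i0(beta)
}

#' FIR band-pass design specification
#'
#' Defaults follow the pulse-wave acquisition chain: 5 kHz sampling, pass band
#' 0.7-9.5 Hz covering the pulse fundamental and its first harmonics, and a
#' 128-tap window. Note that 128 taps at 5 kHz span only 25.6 ms, so the
#' realised transition band is of order `fs / N` (tens of Hz): the filter then
#' acts as a gentle low-pass with in-band gain well below one rather than a
#' resolved band-pass. See the methods vignette; `N` of order `4 * fs` is
#' needed before the 0.7 and 9.5 Hz corners are actually realised.
#'
#' @param f_c1 Lower cut-off (Hz), default 0.7.
#' @param f_c2 Upper cut-off (Hz), default 9.5.
#' @param N Window size (even), default 128; the filter has `N + 1` taps.
#' @param beta Kaiser shape parameter, default 6 (about -63 dB sidelobes when
#'   the band is resolved).
#' @param sample_rate_hz Sampling rate (Hz), default 5000.
#' @return An object of class `fir_spec`.
#' @export
fir_spec <- function(f_c1 = 0.7, f_c2 = 9.5, N = 128L, beta = 6.0,
                     sample_rate_hz = 5000) {
  if (!(f_c1 > 0 && f_c1 < f_c2 && f_c2 < sample_rate_hz / 2)) {
    stop("fir_spec: need 0 < f_c1 < f_c2 < sample_rate_hz / 2", call. = FALSE)
  }
  if (N < 2 || N %% 2 != 0) stop("fir_spec: N must be an even integer >= 2", call. = FALSE)
  if (beta < 0) stop("fir_spec: beta must be >= 0", call. = FALSE)
  structure(list(f_c1 = f_c1, f_c2 = f_c2, N = as.integer(N), beta = beta,
                 sample_rate_hz = sample_rate_hz),
            class = "fir_spec")
}

#' Ideal (un-windowed) band-pass impulse response
#'
#' Difference of two sinc low-pass responses centred at `N/2`:
#' `h_d[n] = sin(w2 (n - N/2)) / (pi (n - N/2)) - sin(w1 (n - N/2)) / (pi (n - N/2))`
#' with the removable singularity `h_d[N/2] = (w2 - w1) / pi`, where
#' `w_i = 2 pi f_ci / fs` are the cut-offs in radians per sample.
#'
#' @param spec A [fir_spec()] (its `N` is used unless overridden).
#' @param N Optional window size overriding `spec$N`.
#' @return Numeric vector of `N + 1` coefficients, symmetric about `N/2`.
#' @export
ideal_bandpass <- function(spec, N = spec$N) {
  stopifnot(inherits(spec, "fir_spec"))
  w1 <- 2 * pi * spec$f_c1 / spec$sample_rate_hz
  w2 <- 2 * pi * spec$f_c2 / spec$sample_rate_hz
  m <- (0:N) - N / 2
  h <- numeric(N + 1)
  nz <- m != 0
  h[nz] <- sin(w2 * m[nz]) / (pi * m[nz]) - sin(w1 * m[nz]) / (pi * m[nz])
  h[!nz] <- (w2 - w1) / pi
  h
}

#' Design the Kaiser-window FIR band-pass taps
#'
#' Elementwise product of the Kaiser window and the ideal band-pass response:
#' `b[n] = w[n] * h_d[n]`. The taps are symmetric, hence exactly linear phase
#' with group delay `N/2` samples.
#'
#' @param spec A [fir_spec()].
#' @return Numeric vector of `N + 1` taps.
#' @export
design_fir <- function(spec) {
  stopifnot(inherits(spec, "fir_spec"))
  kaiser_window(spec$N, spec$beta) * ideal_bandpass(spec)
}

#' Magnitude response of an FIR tap set
#'
#' Evaluates `|sum_n b[n] exp(-j 2 pi f n / fs)|` directly.
#'
#' @param taps Numeric tap vector.
#' @param f Frequencies in Hz (vectorised).
#' @param sample_rate_hz Sampling rate in Hz.
#' @return Magnitude at each frequency.
#' @export
fir_magnitude <- function(taps, f, sample_rate_hz) {
  n <- seq_along(taps) - 1
  vapply(f, function(fi) {
    Mod(sum(taps * exp(-1i * 2 * pi * fi * n / sample_rate_hz)))
  }, numeric(1))
}

#' Apply an FIR filter to a trace (causal, zero-padded history)
#'
#' Streaming convolution `y[n] = sum_k b[k] x[n - k]` with `x[m] = 0` for
#' `m < 1`. Output length equals input length; the first `length(taps) - 1`
#' samples are start-up transient, and a symmetric tap set delays the signal
#' by `(length(taps) - 1) / 2` samples.
#'
#' @param trace A [pulse_trace()] at least as long as `taps`.
#' @param taps Numeric coefficient vector.
#' @return A new `pulse_trace` with filtered samples.
#' @export
apply_fir <- function(trace, taps) {
  stopifnot(inherits(trace, "pulse_trace"))
  L <- length(taps)
  n <- length(trace$samples)
  if (n < L) {
    stop(sprintf("apply_fir: trace (%d samples) shorter than taps (%d)", n, L),
         call. = FALSE)
  }
  xpad <- c(rep(0, L - 1), trace$samples)
  y <- stats::filter(xpad, taps, method = "convolution", sides = 1)
  y <- as.numeric(y)[L:(L + n - 1)]
  pulse_trace(y, trace$sample_rate_hz,
              paste0(trace$channel_id, "_filt"))
}

#' Group delay of a symmetric FIR tap set, in samples
#'
#' @param taps Numeric tap vector (odd length, symmetric).
#' @return Delay in samples, `(length(taps) - 1) / 2`.
#' @export
fir_group_delay <- function(taps) {
  (length(taps) - 1) / 2
}
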