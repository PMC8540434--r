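test_that("series I0 matches the independent Bessel implementation", {
  expect_identical(bessel_i0(0), 1)
  expect_equal(bessel_i0(1), 1.26606587775, tolerance = 1e-11)
  # base R besselI as the independent oracle over the range used by windows
  x <- seq(0, 12, by = 0.37)
  expect_equal(bessel_i0(x), besselI(x, 0), tolerance = 1e-13)
  # strictly increasing
  expect_true(all(diff(bessel_i0(seq(0, 9, by = 0.1))) > 0))
  expect_error(bessel_i0(-0.1), ">= 0")
})

test_that("Kaiser window has unit centre, correct endpoints and symmetry", {
  expect_equal(kaiser_window(8, 0), rep(1, 9))  # beta = 0 is rectangular

  for (beta in c(2, 6, 8.5)) {
    for (N in c(4L, 16L, 128L)) {
      w <- kaiser_window(N, beta)
      expect_length(w, N + 1L)
      expect_identical(w[N / 2 + 1], 1)
      expect_equal(w[1], 1 / bessel_i0(beta), tolerance = 1e-14)
      expect_equal(w, rev(w), tolerance = 1e-14)
    }
  }

  # frozen values, computed independently with base besselI and numpy.kaiser(5, 6)
  expect_equal(kaiser_window(4, 6),
               c(0.0148733371048, 0.4829556064106, 1,
                 0.4829556064106, 0.0148733371048),
               tolerance = 1e-10)
})

test_that("ideal band-pass response is symmetric with the analytic centre value", {
  spec <- fir_spec()
  h <- ideal_bandpass(spec)
  w1 <- 2 * pi * 0.7 / 5000
  w2 <- 2 * pi * 9.5 / 5000
  expect_equal(h[spec$N / 2 + 1], (w2 - w1) / pi, tolerance = 1e-15)
  expect_equal(h, rev(h), tolerance = 1e-15)
})

test_that("designed taps are symmetric (exactly linear phase) across specs", {
  for (beta in c(4, 6, 9)) {
    for (N in c(64L, 128L, 256L)) {
      taps <- design_fir(fir_spec(N = N, beta = beta))
      expect_length(taps, N + 1L)
      expect_equal(taps, rev(taps), tolerance = 1e-15)
    }
  }
})

test_that("a band-resolving tap length realises the 0.7-9.5 Hz corners", {
  # At 5 kHz the transition width is of order fs/N, so the printed N = 128
  # cannot separate 0 Hz from the pass band (see the methods vignette); a
  # window spanning ~3.3 s can. This pins down that the design procedure,
  # not the formulas, limits the short filter.
  spec <- fir_spec(N = 16384L)
  taps <- design_fir(spec)
  expect_lt(abs(sum(taps)), 0.02)                       # DC rejection
  expect_equal(fir_magnitude(taps, 5, 5000), 1, tolerance = 0.05)  # mid-band
  expect_lt(fir_magnitude(taps, 25, 5000), 0.01)        # stop band
})

test_that("short default filter behaves as a gentle attenuator in the pulse band", {
  taps <- design_fir(fir_spec())
  g <- fir_magnitude(taps, c(1e-6, 0.7, 5, 9.5), 5000)
  # nearly flat across the whole pulse band, gain far below unity
  expect_true(all(g > 0.2 & g < 0.25))
  expect_equal(max(g) - min(g), 0, tolerance = 0.01)
})

test_that("causal convolution matches identity, linearity and the brute-force oracle", {
  taps <- design_fir(fir_spec())
  fs <- 5000

  # unit impulse reproduces the taps
  imp <- pulse_trace(c(1, rep(0, 200)), fs)
  expect_equal(apply_fir(imp, taps)$samples[seq_along(taps)], taps,
               tolerance = 1e-14)

  # linearity
  set.seed(42)
  a <- rnorm(500); b <- rnorm(500)
  ya <- apply_fir(pulse_trace(a, fs), taps)$samples
  yb <- apply_fir(pulse_trace(b, fs), taps)$samples
  yab <- apply_fir(pulse_trace(a + b, fs), taps)$samples
  expect_equal(yab, ya + yb, tolerance = 1e-10)

  # brute-force double-loop oracle
  expect_equal(ya, naive_convolve(a, taps), tolerance = 1e-12)

  expect_error(apply_fir(pulse_trace(rnorm(50), fs), taps), "shorter")
})

test_that("symmetric taps delay a pass-band sinusoid by exactly N/2 samples", {
  spec <- fir_spec(N = 2048L)
  taps <- design_fir(spec)
  fs <- 5000
  f0 <- 5
  n <- 0:19999
  x <- sin(2 * pi * f0 * n / fs)
  y <- apply_fir(pulse_trace(x, fs), taps)$samples
  gd <- fir_group_delay(taps)
  gain <- fir_magnitude(taps, f0, fs)
  steady <- (length(taps) + 1):20000
  expected <- gain * sin(2 * pi * f0 * (n - gd) / fs)
  expect_equal(y[steady], expected[steady], tolerance = 1e-6)
})
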