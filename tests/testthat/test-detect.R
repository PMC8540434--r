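test_that("window statistics evaluate their printed formulas", {
  expect_equal(window_mean(c(1, 3)), 2)
  expect_equal(window_mean(c(0, 1, 2, 3)), 1.5)
  expect_equal(window_mean(rep(4.2, 9)), 4.2)

  expect_equal(window_cv(c(1, 3)), 1)          # ((1-2)^2 + (3-2)^2) / 2
  expect_equal(window_cv(rep(7, 5)), 0)
  x <- c(2.5, -1, 0.25, 4)
  expect_equal(window_cv(x + 100), window_cv(x), tolerance = 1e-9)  # translation

  expect_equal(window_rms(c(1, 3)), sqrt(5))
  expect_equal(window_rms(rep(0, 4)), 0)
  expect_equal(window_rms(-3 * x), 3 * window_rms(x))               # |k| scaling

  expect_error(window_mean(numeric(0)), "empty")
  expect_error(window_cv(numeric(0)), "empty")
  expect_error(window_rms(numeric(0)), "empty")
})

test_that("dynamic gradient composes RMS and CV and is linear in gain", {
  p1 <- threshold_params(window_samples = 10, gain = 1)
  p2 <- threshold_params(window_samples = 10, gain = 2)
  w <- rep(c(1, 3), 5)
  expect_equal(dynamic_gradient(w, p1), sqrt(5) / 100, tolerance = 1e-12)
  expect_equal(dynamic_gradient(w, p2), 2 * dynamic_gradient(w, p1))
  expect_equal(dynamic_gradient(rep(5, 10), p1), 0)
  # std mode takes the square root of the variance term
  ps <- threshold_params(window_samples = 10, gain = 1, cv_mode = "std")
  expect_equal(dynamic_gradient(w, ps), sqrt(5) * 1 / 100, tolerance = 1e-12)
})

test_that("vectorised gradient series equals the naive per-sample oracle", {
  set.seed(7)
  x <- random_smooth_signal(400, seed = 7)
  for (W in c(10L, 50L)) {
    for (mode in c("variance", "std")) {
      p <- threshold_params(window_samples = W, cv_mode = mode)
      expect_equal(gradient_series(x, p), naive_gradient(x, W, 1, mode),
                   tolerance = 1e-9)
    }
  }
  # non-negative everywhere, including the warm-up prefix
  g <- gradient_series(x, threshold_params(window_samples = 25))
  expect_true(all(g >= 0))
})

test_that("monotone signals yield no peaks and plateaus resolve to their first sample", {
  fs <- 100
  up <- pulse_trace(seq(0, 10, length.out = 200), fs)
  ev <- detect_events(up, threshold_params(fs, window_samples = 10))
  expect_false(any(ev$kind == "peak"))

  # plateau at the maximum: peak index is the plateau's first sample
  x <- c(seq(0, 10, by = 1), rep(10, 5), seq(9.5, 0, by = -0.5))
  tr <- pulse_trace(x, fs)
  ev <- detect_events(tr, threshold_params(fs, window_samples = 4),
                      warmup_samples = 0)
  pk <- ev[ev$kind == "peak", ]
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$index, 11L)  # first sample holding the max value 10
})

test_that("a triangle pulse emits one peak at the apex and a prompt fall onset", {
  fs <- 100
  x <- c(seq(0, 10, by = 0.5), seq(9.5, 0, by = -0.5))
  tr <- pulse_trace(x, fs)
  ev <- detect_events(tr, threshold_params(fs, window_samples = 4),
                      warmup_samples = 0)
  pk <- ev[ev$kind == "peak", ]
  fo <- ev[ev$kind == "fall_onset", ]
  expect_equal(pk$index, which.max(x))
  expect_equal(pk$amplitude, 10)
  # gradient over a window of 4 on a 0.5-step ramp is < 0.05, so the very
  # first descending sample is already below apex - gradient
  expect_equal(fo$index[1], which.max(x) + 1L)
})

test_that("two bumps over a deep trough give two peaks and one interior trough", {
  fs <- 200
  t <- seq(0, 1, length.out = 201)
  bump <- function(c0) exp(-(t - c0)^2 / (2 * 0.03^2))
  x <- 10 * (bump(0.3) + bump(0.7))
  ev <- detect_events(pulse_trace(x, fs), threshold_params(fs, window_samples = 20),
                      warmup_samples = 0)
  pk <- ev[ev$kind == "peak", ]
  tr <- ev[ev$kind == "trough", ]
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$index, c(61L, 141L), tolerance = 1)
  interior <- tr$index > pk$index[1] & tr$index < pk$index[2]
  expect_equal(sum(interior), 1L)
})

test_that("event stream alternates peak/trough and events are ordered", {
  x <- random_smooth_signal(1500, seed = 11)
  ev <- detect_events(pulse_trace(x, 500), threshold_params(500, window_samples = 60),
                      warmup_samples = 0)
  expect_true(all(diff(ev$index) >= 0))
  extrema <- ev$kind[ev$kind %in% c("peak", "trough")]
  expect_true(all(extrema[-1] != extrema[-length(extrema)]))
  # every peak is bracketed by a preceding rise_onset and a following fall_onset
  kinds <- ev$kind
  at <- which(kinds == "peak")
  expect_true(all(vapply(at, function(i) any(kinds[seq_len(i)] == "rise_onset") ||
                           i <= 2, logical(1))))
})

test_that("streaming detector matches the offline hysteresis oracle on random signals", {
  for (trial in 1:20) {
    x <- random_smooth_signal(500, seed = 100 + trial)
    W <- sample(c(20L, 40L, 80L), 1L)
    p <- threshold_params(window_samples = W)
    ev <- detect_events(pulse_trace(x, 500), p, warmup_samples = 0)
    expect_identical(ev$index[ev$kind == "peak"], naive_peaks(x, W),
                     info = sprintf("trial %d (W=%d)", trial, W))
  }
})

test_that("warm-up events are flagged and excluded by event_peaks", {
  x <- random_smooth_signal(800, seed = 5)
  ev <- detect_events(pulse_trace(x, 500), threshold_params(500, window_samples = 50),
                      warmup_samples = 300)
  expect_true(all(ev$warmup[ev$index <= 300]))
  expect_true(all(event_peaks(ev) > 300))
  expect_true(length(event_peaks(ev, include_warmup = TRUE)) >=
                length(event_peaks(ev)))
})

test_that("detector rejects traces shorter than the threshold window", {
  expect_error(detect_events(pulse_trace(1:10, 100),
                             threshold_params(100, window_samples = 50)),
               "shorter")
})
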