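test_that("beat template has a dominant first peak and a scaled dicrotic peak", {
  tpl <- beat_template(100, 0.45, 0.42, 5000)
  seg <- tpl$segment
  expect_equal(which.max(seg) - 1L, tpl$peak_offset, tolerance = 1)
  expect_lt(abs(seg[1]), 0.03 * max(seg))             # starts near zero
  expect_lt(abs(seg[length(seg)]), 0.03 * max(seg))   # runoff decayed at the end

  # exactly two local maxima; second/first amplitude in [0.4, 0.5]
  d <- diff(seg)
  maxima <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  expect_equal(length(maxima), 2L)
  expect_gt(seg[maxima[2]] / seg[maxima[1]], 0.4)
  expect_lt(seg[maxima[2]] / seg[maxima[1]], 0.5)

  # ratio 0 collapses to a single bump
  tpl0 <- beat_template(100, 0, 0.42, 5000)
  d0 <- diff(tpl0$segment)
  expect_equal(sum(d0[-length(d0)] > 0 & d0[-1] <= 0), 1L)
})

test_that("mid-tread quantization is idempotent, zero-preserving and half-step accurate", {
  fs <- 5000
  q <- function(x) quantize_trace(pulse_trace(x, fs), 12L, 400)$samples
  zero <- rep(0, 10)
  expect_identical(q(zero), zero)

  # half-step accuracy over the representable span (the last half step at
  # the positive rail clips, tested below)
  step <- 400 / 2^12
  ramp <- seq(-200 + step / 2, 200 - step / 2, length.out = 8192)
  qr <- q(ramp)
  expect_identical(q(qr), qr)                       # idempotent
  expect_lte(max(abs(qr - ramp)), step / 2 + 1e-12)

  # out-of-range samples clip to the code range
  clipped <- q(c(-1000, 1000))
  expect_equal(clipped, c(-(2^11 - 1) * step, (2^11 - 1) * step))
})

test_that("generation is deterministic in the seed and leaves the caller's RNG alone", {
  cfg <- subject_config(duration_s = 8, seed = 123)
  set.seed(999)
  before <- rnorm(1)
  set.seed(999)
  s1 <- generate_subject(cfg)
  after <- rnorm(1)
  s2 <- generate_subject(cfg)
  expect_identical(s1$proximal$samples, s2$proximal$samples)
  expect_identical(s1$distal$samples, s2$distal$samples)
  expect_identical(s1$truth, s2$truth)
  expect_identical(before, after)  # RNG state restored

  s3 <- generate_subject(subject_config(duration_s = 8, seed = 124))
  expect_false(identical(s1$proximal$samples, s3$proximal$samples))
})

test_that("ground truth aligns labels with peaks and encodes the transit delay", {
  cfg <- subject_config(duration_s = 10, ectopic_rate = 0.1, seed = 2)
  s <- generate_subject(cfg)
  tr <- s$truth
  expect_equal(length(tr$peak_index_proximal), length(tr$label))
  expect_equal(tr$peak_index_distal, tr$peak_index_proximal + 20L)
  expect_true(all(diff(tr$peak_index_proximal) > 0))
  expect_equal(tr$pwv_m_s, 0.025 / (20 / 5000))

  s0 <- generate_subject(subject_config(duration_s = 10, ectopic_rate = 0, seed = 2))
  expect_true(all(s0$truth$label == "normal"))
})

test_that("a one-minute sinus record holds about sixty beats", {
  s <- generate_subject(subject_config(seed = 1))
  expect_gte(length(s$truth$label), 57L)
  expect_lte(length(s$truth$label), 61L)
})

test_that("PAC beats arrive early and PVC beats keep timing but lose first-peak height", {
  pac <- generate_subject(subject_config(duration_s = 30, ectopic_rate = 0.15,
                                         ectopic_type = "pac", noise_mv = 0,
                                         drift_mv = 0, mains_mv = 0, seed = 6))
  iv <- diff(pac$truth$peak_index_proximal) / 5000
  kinds <- pac$truth$ectopic_kind
  # PAC beats that follow a sinus beat; a PAC directly after another PAC
  # sits a full interval after it and is not premature relative to it
  pac_beats <- which(kinds == "pac")
  pac_beats <- pac_beats[pac_beats > 1 & pac_beats <= length(iv) + 1 &
                           kinds[pac_beats - 1] == "none"]
  expect_gt(length(pac_beats), 0)
  # the interval ending at such a PAC beat is clearly premature
  expect_true(all(iv[pac_beats - 1] < 0.8 * median(iv)))

  pvc <- generate_subject(subject_config(duration_s = 30, ectopic_rate = 0.15,
                                         ectopic_type = "pvc", noise_mv = 0,
                                         drift_mv = 0, mains_mv = 0, seed = 6))
  k <- which(pvc$truth$ectopic_kind == "pvc")[1]
  expect_false(is.na(k))
  # amplitudes above the diastolic baseline of the AC-coupled record
  x <- pvc$proximal$samples
  base <- quantile(x, 0.1)
  amp_ect <- x[pvc$truth$peak_index_proximal[k]] - base
  normal_idx <- pvc$truth$peak_index_proximal[pvc$truth$label == "normal"]
  amp_norm <- median(x[normal_idx]) - base
  # first peak attenuated to roughly the dicrotic level
  expect_lt(amp_ect, 0.6 * amp_norm)
  expect_gt(amp_ect, 0.4 * amp_norm)
})

test_that("configuration invariants are enforced", {
  expect_error(subject_config(ectopic_rate = 0.6), "ectopic_rate")
  expect_error(subject_config(pac_prematurity = 1.2), "pac_prematurity")
  expect_error(subject_config(transit_delay_samples = 0), "transit_delay")
  expect_error(subject_config(second_peak_ratio = 1.3), "second_peak_ratio")
  expect_error(subject_config(duration_s = -5), "positive")
})
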