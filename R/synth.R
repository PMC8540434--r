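# Seeded synthetic dual-channel pulse-wave generator. Emulates the full
# acquisition chain: beat train with jittered sinus rhythm, PAC (premature
# timing, normal morphology) and/or PVC (normal timing, attenuated first
# peak) ectopy, a fixed integer-sample inter-channel transit delay, baseline
# drift, mains interference, white sensor noise, and 12-bit quantization.
# Ground truth records the pre-noise first-peak index and the normal/ectopic
# label of every beat, so downstream stages can be scored exactly.

#' Configuration for a synthetic subject
#'
#' Defaults describe a resting subject measured by a wrist-worn dual
#' piezoelectric sensor: 60 s at 5 kHz, 60 bpm with 2% interval jitter,
#' 100 mV first peak with a dicrotic peak at 0.45 of its amplitude, a
#' 20-sample (4 ms) transit delay across a 2.5 cm sensor separation
#' (about 6.25 m/s), mild drift and mains pickup, and a 12-bit ADC over
#' +-200 mV.
#'
#' @param duration_s Record length in seconds (default 60).
#' @param sample_rate_hz Sampling rate (default 5000).
#' @param heart_rate_bpm Mean sinus rate (default 60).
#' @param hr_jitter Fractional SD of the inter-beat interval (default 0.02).
#' @param first_peak_mv Normal first-peak amplitude in mV (default 100).
#' @param second_peak_ratio Dicrotic/first amplitude ratio (default 0.45).
#' @param pvc_first_peak_ratio PVC first-peak attenuation so that the first
#'   peak lands close to the (unattenuated) second peak (default 0.5).
#' @param pac_prematurity PAC beats arrive at this fraction of the current
#'   interval (default 0.6), followed by a compensatory pause back to the
#'   sinus grid.
#' @param ectopic_rate Per-beat ectopy probability in \[0, 0.5) (default 0.05).
#' @param ectopic_type `"pac"`, `"pvc"`, or `"both"` (each ectopic beat drawn
#'   as PAC or PVC with equal probability).
#' @param transit_delay_samples Integer inter-channel delay, >= 1 (default 20).
#' @param sensor_distance_m Sensor separation in metres (default 0.025).
#' @param noise_mv White-noise SD per channel (default 0.1, about one LSB of
#'   the 12-bit converter: the front end delivers noise near the
#'   quantization floor).
#' @param drift_mv,drift_hz Baseline-wander amplitude and frequency
#'   (defaults 2 mV, 0.25 Hz; the 0.58 Hz analog high-pass has already
#'   removed most of the wander).
#' @param mains_mv,mains_hz Mains-interference amplitude and frequency
#'   (defaults 0.1 mV, 60 Hz: the second-order 10.6 Hz analog low-pass
#'   attenuates mains pickup about thirtyfold before the converter).
#' @param adc_bits ADC resolution (default 12).
#' @param adc_fullscale_mv ADC full-scale range in mV (default 400, i.e.
#'   +-200 mV).
#' @param beat_width_s Duration of one beat complex (default 0.42 s).
#' @param seed Integer RNG seed (default 1).
#' @return An object of class `subject_config`.
#' @export
subject_config <- function(duration_s = 60, sample_rate_hz = 5000,
                           heart_rate_bpm = 60, hr_jitter = 0.02,
                           first_peak_mv = 100, second_peak_ratio = 0.45,
                           pvc_first_peak_ratio = 0.5, pac_prematurity = 0.6,
                           ectopic_rate = 0.05,
                           ectopic_type = c("pac", "pvc", "both"),
                           transit_delay_samples = 20L,
                           sensor_distance_m = 0.025,
                           noise_mv = 0.1, drift_mv = 2, drift_hz = 0.25,
                           mains_mv = 0.1, mains_hz = 60,
                           adc_bits = 12L, adc_fullscale_mv = 400,
                           beat_width_s = 0.42, seed = 1L) {
  ectopic_type <- match.arg(ectopic_type)
  if (ectopic_rate < 0 || ectopic_rate >= 0.5) {
    stop("subject_config: ectopic_rate must be in [0, 0.5)", call. = FALSE)
  }
  if (pac_prematurity <= 0 || pac_prematurity >= 1) {
    stop("subject_config: pac_prematurity must be in (0, 1)", call. = FALSE)
  }
  if (transit_delay_samples < 1L) {
    stop("subject_config: transit_delay_samples must be >= 1", call. = FALSE)
  }
  if (second_peak_ratio <= 0 || second_peak_ratio >= 1) {
    stop("subject_config: second_peak_ratio must be in (0, 1)", call. = FALSE)
  }
  if (duration_s <= 0 || sample_rate_hz <= 0 || heart_rate_bpm <= 0 ||
      first_peak_mv <= 0 || beat_width_s <= 0) {
    stop("subject_config: durations, rates and amplitudes must be positive",
         call. = FALSE)
  }
  structure(list(
    duration_s = duration_s, sample_rate_hz = sample_rate_hz,
    heart_rate_bpm = heart_rate_bpm, hr_jitter = hr_jitter,
    first_peak_mv = first_peak_mv, second_peak_ratio = second_peak_ratio,
    pvc_first_peak_ratio = pvc_first_peak_ratio,
    pac_prematurity = pac_prematurity,
    ectopic_rate = ectopic_rate, ectopic_type = ectopic_type,
    transit_delay_samples = as.integer(transit_delay_samples),
    sensor_distance_m = sensor_distance_m,
    noise_mv = noise_mv, drift_mv = drift_mv, drift_hz = drift_hz,
    mains_mv = mains_mv, mains_hz = mains_hz,
    adc_bits = as.integer(adc_bits), adc_fullscale_mv = adc_fullscale_mv,
    beat_width_s = beat_width_s, seed = as.integer(seed)
  ), class = "subject_config")
}

#' Render one beat waveform segment
#'
#' Physiological composite: a dominant systolic (first) peak (Gaussian centred
#' at 0.2 of the beat width, SD 0.07 width), a dicrotic (second) peak at 0.5
#' width scaled by `ratio` (Gaussian rise, SD 0.12 width), and an exponential
#' diastolic runoff from the dicrotic peak (time constant 0.8 width) so the
#' pulse decays continuously toward baseline instead of stopping dead — as an
#' AC-coupled arterial pulse does. The segment starts and ends near zero and
#' its global maximum is the first peak whenever `ratio < 1`.
#'
#' @param first_mv First-peak amplitude in mV.
#' @param ratio Second/first amplitude ratio (`< 1` for normal beats; a PVC
#'   beat passes the attenuated first peak and correspondingly larger ratio).
#' @param width_s Width of the systolic-dicrotic complex in seconds; the
#'   rendered segment extends to `width_s + 3.2 * 0.8 * width_s` to carry the
#'   diastolic runoff.
#' @param rate Sampling rate in Hz.
#' @return A list with `segment` (numeric waveform), and `peak_offset`
#'   (0-based sample offset of the first-peak centre within the segment).
#' @export
beat_template <- function(first_mv, ratio, width_s, rate) {
  tau <- 0.8 * width_s
  m <- round((width_s + 3.2 * tau) * rate)
  t <- (0:m) / rate
  c1 <- 0.20 * width_s; s1 <- 0.07 * width_s
  c2 <- 0.50 * width_s; s2 <- 0.16 * width_s
  dicrotic <- ifelse(t < c2,
                     exp(-(t - c2)^2 / (2 * s2^2)),
                     exp(-(t - c2) / tau))
  seg <- first_mv * (exp(-(t - c1)^2 / (2 * s1^2)) + ratio * dicrotic)
  list(segment = seg, peak_offset = round(c1 * rate))
}

#' Mid-tread uniform quantization of a trace
#'
#' Rounds each sample to the nearest of `2^bits` levels spaced
#' `fullscale_mv / 2^bits` apart, clipping symmetrically at the code range.
#' Idempotent; zero maps to zero; for in-range inputs the error never exceeds
#' half a step.
#'
#' @param trace A [pulse_trace()].
#' @param bits Resolution, >= 2.
#' @param fullscale_mv Full-scale range in mV (the representable span is
#'   about `+-fullscale_mv / 2`).
#' @return A quantized `pulse_trace`.
#' @export
quantize_trace <- function(trace, bits = 12L, fullscale_mv = 400) {
  stopifnot(inherits(trace, "pulse_trace"))
  if (bits < 2L) stop("quantize_trace: bits must be >= 2", call. = FALSE)
  step <- fullscale_mv / 2^bits
  kmax <- 2^(bits - 1L) - 1L
  k <- round(trace$samples / step)
  k <- pmin(pmax(k, -kmax), kmax)
  pulse_trace(k * step, trace$sample_rate_hz, trace$channel_id)
}

#' Generate a synthetic dual-channel subject with ground truth
#'
#' Places beats on a jittered sinus grid; each beat (after the first) is
#' independently ectopic with probability `ectopic_rate`. A PAC beat arrives
#' prematurely at `pac_prematurity` of the current interval and the next
#' sinus beat stays on the grid (compensatory pause); a PVC beat keeps sinus
#' timing but its first peak is attenuated to near the second peak. The
#' distal channel is the clean proximal signal delayed by
#' `transit_delay_samples`; drift, mains, white noise (independent per
#' channel) and ADC quantization are applied after the delay. Fully
#' reproducible from `cfg$seed`; the caller's RNG state is preserved.
#'
#' @param cfg A [subject_config()].
#' @return An object of class `pulse_subject`: list with `proximal` and
#'   `distal` ([pulse_trace()]s) and `truth`, a list holding
#'   `peak_index_proximal`, `peak_index_distal` (pre-noise first-peak sample
#'   indices), `label` (`"normal"`/`"ectopic"` per beat), `ectopic_kind`
#'   (`"none"`/`"pac"`/`"pvc"`), `ptt_samples` and `pwv_m_s`, plus the `config`.
#' @export
generate_subject <- function(cfg = subject_config()) {
  stopifnot(inherits(cfg, "subject_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)

  fs <- cfg$sample_rate_hz
  n <- round(cfg$duration_s * fs)
  T0 <- 60 / cfg$heart_rate_bpm
  d <- cfg$transit_delay_samples

  # sinus grid with jittered intervals; beats must fit in both channels.
  # The record starts mid-rhythm: the first beat sits right at the margin.
  t_margin <- 0.1
  last_ok <- cfg$duration_s - cfg$beat_width_s - (d / fs) - t_margin
  onsets <- t_margin       # beat (template) onset times actually used
  kinds <- "none"          # none / pac / pvc
  prev_grid <- t_margin
  repeat {
    interval <- T0 * (1 + cfg$hr_jitter * stats::rnorm(1))
    interval <- min(max(interval, 0.5 * T0), 1.5 * T0)
    new_grid <- prev_grid + interval
    if (new_grid > last_ok) break
    is_ect <- length(onsets) >= 1L && stats::runif(1) < cfg$ectopic_rate
    kind <- "none"
    if (is_ect) {
      kind <- switch(cfg$ectopic_type,
                     pac = "pac", pvc = "pvc",
                     both = if (stats::runif(1) < 0.5) "pac" else "pvc")
    }
    onset <- if (kind == "pac") prev_grid + cfg$pac_prematurity * interval else new_grid
    onsets <- c(onsets, onset)
    kinds <- c(kinds, kind)
    prev_grid <- new_grid
  }
  if (length(onsets) < 3L) {
    stop("generate_subject: record too short to hold 3 beats", call. = FALSE)
  }

  clean <- numeric(n)

  # The record starts mid-rhythm: lay down the diastolic runoff of the beat
  # that preceded the recording window (not part of the ground truth).
  pre <- beat_template(cfg$first_peak_mv, cfg$second_peak_ratio,
                       cfg$beat_width_s, fs)
  pre_start <- round((t_margin - T0) * fs) + 1L
  pre_keep <- which(pre_start + seq_along(pre$segment) - 1L >= 1L)
  if (length(pre_keep) > 0L) {
    idx <- pre_start + pre_keep - 1L
    idx <- idx[idx <= n]
    clean[idx] <- clean[idx] + pre$segment[pre_keep[seq_along(idx)]]
  }

  peak_idx <- integer(length(onsets))
  for (k in seq_along(onsets)) {
    if (kinds[k] == "pvc") {
      a1 <- cfg$pvc_first_peak_ratio * cfg$first_peak_mv
      r <- cfg$second_peak_ratio * cfg$first_peak_mv / a1
    } else {
      a1 <- cfg$first_peak_mv
      r <- cfg$second_peak_ratio
    }
    tpl <- beat_template(a1, r, cfg$beat_width_s, fs)
    i0 <- round(onsets[k] * fs) + 1L
    i1 <- min(i0 + length(tpl$segment) - 1L, n)
    clean[i0:i1] <- clean[i0:i1] + tpl$segment[seq_len(i1 - i0 + 1L)]
    # truth = argmax of the clean composite near the nominal first-peak centre
    ctr <- i0 + tpl$peak_offset
    hw <- max(1L, round(0.05 * cfg$beat_width_s * fs))
    win <- max(1L, ctr - hw):min(n, ctr + hw)
    peak_idx[k] <- win[which.max(clean[win])]
  }

  # AC coupling of the analog chain: the digitized signal is zero-mean over
  # the record. The same offset is removed from both channels so the distal
  # channel stays an exact delayed copy of the proximal one.
  dc <- mean(clean)
  clean <- clean - dc
  clean_distal <- c(rep(clean[1L], d), clean[seq_len(n - d)])

  # Drift (body motion / contact pressure) and mains pickup couple through
  # the shared wearable front end, so they are common-mode across the two
  # channels; only the per-sensor white noise is independent.
  tt <- (seq_len(n) - 1) / fs
  interference <- numeric(n)
  if (cfg$drift_mv > 0) {
    interference <- interference +
      cfg$drift_mv * sin(2 * pi * cfg$drift_hz * tt + stats::runif(1, 0, 2 * pi))
  }
  if (cfg$mains_mv > 0) {
    interference <- interference +
      cfg$mains_mv * sin(2 * pi * cfg$mains_hz * tt + stats::runif(1, 0, 2 * pi))
  }

  corrupt <- function(x, channel_id) {
    y <- x + interference
    if (cfg$noise_mv > 0) {
      y <- y + stats::rnorm(n, sd = cfg$noise_mv)
    }
    quantize_trace(pulse_trace(y, fs, channel_id),
                   cfg$adc_bits, cfg$adc_fullscale_mv)
  }

  proximal <- corrupt(clean, "proximal")
  distal <- corrupt(clean_distal, "distal")

  truth <- list(
    peak_index_proximal = peak_idx,
    peak_index_distal = peak_idx + d,
    label = ifelse(kinds == "none", "normal", "ectopic"),
    ectopic_kind = kinds,
    ptt_samples = d,
    pwv_m_s = cfg$sensor_distance_m / (d / fs)
  )
  structure(list(proximal = proximal, distal = distal, truth = truth,
                 config = cfg),
            class = "pulse_subject")
}

#' @export
print.pulse_subject <- function(x, ...) {
  cat(sprintf(
    "<pulse_subject: %d beats (%d ectopic), %.0f s @ %g Hz, true PTT %d samples (PWV %.3f m/s)>\n",
    length(x$truth$label), sum(x$truth$label == "ectopic"),
    x$config$duration_s, x$config$sample_rate_hz,
    x$truth$ptt_samples, x$truth$pwv_m_s
  ))
  invisible(x)
}
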