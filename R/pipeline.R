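# End-to-end analysis: filter -> detect -> pair -> flag -> estimate. The
# stages are individually exported; run_analyze() wires them with one
# resolved configuration and returns a per-beat table plus summaries.

#' Full analysis configuration
#'
#' @param sensor_distance_m Sensor separation in metres (default 0.025).
#' @param filter A [fir_spec()].
#' @param threshold A [threshold_params()].
#' @param ectopic An [ectopic_policy()].
#' @param artery An [artery_model()] or `NULL` to skip pressure estimation.
#' @param reference_map Optional cuff-derived reference MAP (mmHg) for
#'   mean-difference reporting.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sensor_distance_m = 0.025,
                       filter = fir_spec(),
                       threshold = threshold_params(filter$sample_rate_hz),
                       ectopic = ectopic_policy(),
                       artery = NULL,
                       reference_map = NULL) {
  stopifnot(inherits(filter, "fir_spec"), inherits(threshold, "threshold_params"),
            inherits(ectopic, "ectopic_policy"))
  if (!is.null(artery)) stopifnot(inherits(artery, "artery_model"))
  if (sensor_distance_m <= 0) {
    stop("run_config: sensor_distance_m must be > 0", call. = FALSE)
  }
  structure(list(sensor_distance_m = sensor_distance_m, filter = filter,
                 threshold = threshold, ectopic = ectopic, artery = artery,
                 reference_map = reference_map),
            class = "run_config")
}

#' Analyze a dual-channel pulse-wave recording
#'
#' Filters both channels with the configured FIR, detects peaks with the
#' dynamic threshold (warm-up = threshold window + FIR group delay), undoes
#' the filter group delay on the detected indices, pairs proximal/distal
#' peaks into PTT/PWV, flags ectopic beats from the proximal inter-beat
#' intervals, and (when an artery model is configured) estimates a per-beat
#' MAP from each PWV. Summaries report mean PWV and mean MAP with all beats
#' and with ectopic beats filtered out, plus mean differences against an
#' optional cuff reference MAP.
#'
#' @param proximal,distal [pulse_trace()] objects sharing one sample rate.
#' @param cfg A [run_config()].
#' @return An object of class `pulse_report`: list with `beats` (per-beat
#'   data frame: indices, interval, label, PTT, PWV, and MAP when an artery
#'   model is present), `summary` (named list), and the resolved `config`.
#' @export
run_analyze <- function(proximal, distal, cfg = run_config()) {
  stopifnot(inherits(proximal, "pulse_trace"), inherits(distal, "pulse_trace"))
  if (proximal$sample_rate_hz != distal$sample_rate_hz) {
    stop("run_analyze: channels have different sample rates", call. = FALSE)
  }
  rate <- proximal$sample_rate_hz
  taps <- design_fir(cfg$filter)
  delay <- fir_group_delay(taps)
  warmup <- cfg$threshold$window_samples + delay

  peaks_of <- function(trace) {
    f <- apply_fir(trace, taps)
    ev <- detect_events(f, cfg$threshold, warmup_samples = warmup)
    event_peaks(ev) - delay  # undo the linear-phase group delay
  }
  pk_prox <- peaks_of(proximal)
  pk_dist <- peaks_of(distal)
  if (length(pk_prox) < 3L) {
    stop(sprintf("run_analyze: only %d beats detected; need at least 3",
                 length(pk_prox)), call. = FALSE)
  }

  pairs <- pair_peaks(pk_prox, pk_dist, rate, distance_m = cfg$sensor_distance_m)
  if (nrow(pairs) < 3L) {
    stop("run_analyze: fewer than 3 proximal/distal beat pairs", call. = FALSE)
  }
  intervals <- intervals_from_peaks(pairs$proximal_peak, rate)
  labels <- flag_ectopic(intervals, cfg$ectopic)

  beats <- data.frame(
    proximal_peak = pairs$proximal_peak,
    distal_peak = pairs$distal_peak,
    interval_prev_s = c(NA_real_, intervals),
    label = labels,
    ptt_s = pairs$ptt_s,
    pwv_m_s = pairs$pwv_m_s,
    stringsAsFactors = FALSE
  )

  normal <- beats$label == "normal"
  summary <- list(
    n_beats = nrow(beats),
    n_ectopic = sum(!normal),
    mean_pwv_all = mean(beats$pwv_m_s),
    mean_pwv_normal = mean(beats$pwv_m_s[normal]),
    sd_pwv_all = stats::sd(beats$pwv_m_s),
    sd_pwv_normal = stats::sd(beats$pwv_m_s[normal])
  )

  if (!is.null(cfg$artery)) {
    # Per-beat MAP; a grossly mis-paired beat can imply a modulus below E0
    # (pressure undefined) — such beats get NA instead of aborting the run.
    e <- elastic_modulus_from_pwv(beats$pwv_m_s, cfg$artery)
    beats$map_mmHg <- ifelse(e > cfg$artery$E0,
                             log(e / cfg$artery$E0) / cfg$artery$xi, NA_real_)
    summary$mean_map_all <- mean(beats$map_mmHg, na.rm = TRUE)
    summary$mean_map_normal <- mean(beats$map_mmHg[normal], na.rm = TRUE)
    if (!is.null(cfg$reference_map)) {
      ok <- !is.na(beats$map_mmHg)
      summary$md_reference_all <-
        mean_difference(cfg$reference_map, beats$map_mmHg[ok])
      summary$md_reference_normal <-
        mean_difference(cfg$reference_map, beats$map_mmHg[normal & ok])
    }
  }

  structure(list(beats = beats, summary = summary, config = cfg),
            class = "pulse_report")
}

#' @export
print.pulse_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pulse_report: %d beats (%d ectopic)>\n", s$n_beats, s$n_ectopic))
  cat(sprintf("  mean PWV  all beats: %.3f m/s (sd %.3f)\n",
              s$mean_pwv_all, s$sd_pwv_all))
  cat(sprintf("  mean PWV  normal:    %.3f m/s (sd %.3f)\n",
              s$mean_pwv_normal, s$sd_pwv_normal))
  if (!is.null(s$mean_map_all)) {
    cat(sprintf("  mean MAP  all beats: %.2f mmHg\n", s$mean_map_all))
    cat(sprintf("  mean MAP  normal:    %.2f mmHg\n", s$mean_map_normal))
  }
  if (!is.null(s$md_reference_all)) {
    cat(sprintf("  MD vs reference, all beats: %.2f mmHg\n", s$md_reference_all))
    cat(sprintf("  MD vs reference, normal:    %.2f mmHg\n", s$md_reference_normal))
  }
  invisible(x)
}

#' Score a report's detections against generator ground truth
#'
#' Convenience wrapper for synthetic subjects: runs the detection stages of
#' [run_analyze()] on the proximal channel and scores the recovered peaks
#' against the subject's ground-truth first-peak indices with
#' [match_events()] and [detection_score()]. Warm-up beats (truth peaks
#' inside the detector warm-up prefix) are excluded from scoring.
#'
#' @param subject A `pulse_subject` from [generate_subject()].
#' @param cfg A [run_config()].
#' @param tol Match tolerance in samples (default 3).
#' @return A list with `score` (the per-class table), `matches`, and the
#'   truth/detected index vectors used.
#' @export
score_detection <- function(subject, cfg = run_config(), tol = 3L) {
  stopifnot(inherits(subject, "pulse_subject"))
  taps <- design_fir(cfg$filter)
  delay <- fir_group_delay(taps)
  warmup <- cfg$threshold$window_samples + delay
  f <- apply_fir(subject$proximal, taps)
  ev <- detect_events(f, cfg$threshold, warmup_samples = warmup)
  detected <- event_peaks(ev) - delay
  keep <- subject$truth$peak_index_proximal > warmup - delay
  truth <- subject$truth$peak_index_proximal[keep]
  labels <- subject$truth$label[keep]
  matches <- match_events(truth, detected, tol = tol)
  list(score = detection_score(matches, labels), matches = matches,
       truth = truth, detected = detected)
}
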