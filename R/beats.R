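# Inter-beat-interval analysis, ectopic flagging, and dual-channel peak
# pairing into pulse transit time (PTT) and pulse wave velocity (PWV).

#' Inter-beat intervals from peak indices
#'
#' @param peaks Strictly increasing integer sample indices (>= 2 peaks).
#' @param rate Sampling rate in Hz.
#' @return Numeric vector of `length(peaks) - 1` intervals in seconds.
#' @export
intervals_from_peaks <- function(peaks, rate) {
  if (length(peaks) < 2L) {
    stop("intervals_from_peaks: need at least 2 peaks", call. = FALSE)
  }
  if (any(diff(peaks) <= 0)) {
    stop("intervals_from_peaks: peaks must be strictly increasing", call. = FALSE)
  }
  diff(peaks) / rate
}

#' Ectopic-flagging policy
#'
#' A beat is flagged ectopic when the interval it terminates deviates from the
#' reference interval by more than `relative_tolerance`. The reference is the
#' median of all intervals by default — robust to the ectopic intervals
#' themselves; `reference = "mean"` reproduces the literal "average" rule.
#'
#' @param relative_tolerance Fraction in (0, 1), default 0.25.
#' @param reference `"median"` (default) or `"mean"`.
#' @param compensatory_pause If `TRUE` (default), a long interval immediately
#'   following a short one is treated as the compensatory pause after a
#'   premature beat and is not itself flagged: only the premature beat is
#'   marked, matching the physiology of PAC.
#' @return An object of class `ectopic_policy`.
#' @export
ectopic_policy <- function(relative_tolerance = 0.25,
                           reference = c("median", "mean"),
                           compensatory_pause = TRUE) {
  reference <- match.arg(reference)
  if (!is.finite(relative_tolerance) || relative_tolerance <= 0 ||
      relative_tolerance >= 1) {
    stop("ectopic_policy: relative_tolerance must be in (0, 1)", call. = FALSE)
  }
  structure(list(relative_tolerance = relative_tolerance,
                 reference = reference,
                 compensatory_pause = isTRUE(compensatory_pause)),
            class = "ectopic_policy")
}

#' Flag ectopic beats from inter-beat intervals
#'
#' Beat `i + 1` terminates interval `i`; it is labelled `"ectopic"` when
#' `interval_i` lies outside `[(1 - tol) * ref, (1 + tol) * ref]`. The first
#' beat (which terminates no interval) inherits the test of the interval that
#' follows it. With `compensatory_pause = TRUE` a long interval directly after
#' a short one does not flag its terminating beat.
#'
#' @param intervals Numeric intervals in seconds (>= 3).
#' @param policy An [ectopic_policy()].
#' @return Character vector of `length(intervals) + 1` labels
#'   (`"normal"` / `"ectopic"`), one per beat.
#' @export
flag_ectopic <- function(intervals, policy = ectopic_policy()) {
  if (length(intervals) < 3L) {
    stop("flag_ectopic: need at least 3 intervals", call. = FALSE)
  }
  if (any(intervals <= 0)) {
    stop("flag_ectopic: intervals must be positive", call. = FALSE)
  }
  ref <- if (policy$reference == "median") stats::median(intervals) else mean(intervals)
  tol <- policy$relative_tolerance
  short <- intervals < (1 - tol) * ref
  long <- intervals > (1 + tol) * ref
  out <- short | long
  if (policy$compensatory_pause) {
    n <- length(intervals)
    compensatory <- long & c(FALSE, short[-n])
    out <- out & !compensatory
  }
  labels <- c(out[1L], out)  # first beat inherits its following interval's test
  ifelse(labels, "ectopic", "normal")
}

#' Pair proximal and distal peaks into beat pairs
#'
#' Greedy forward matching: each proximal peak is paired with the earliest
#' unused distal peak strictly after it and within `max_lag_s`. Unmatched
#' peaks on either side are dropped. The pair carries
#' `ptt_s = (distal - proximal) / rate` and, when `distance_m` is given,
#' `pwv_m_s = distance_m / ptt_s`.
#'
#' @param proximal,distal Sorted integer peak indices for the upstream and
#'   downstream sensor channels.
#' @param rate Sampling rate in Hz.
#' @param max_lag_s Maximum admissible transit lag in seconds. Default
#'   `NULL` uses half the median inter-beat interval of the proximal channel,
#'   which prevents cross-beat mis-pairing.
#' @param distance_m Sensor separation in metres (default 0.025, i.e. 2.5 cm);
#'   set `NULL` to skip the PWV column.
#' @return A data frame with columns `proximal_peak`, `distal_peak`, `ptt_s`
#'   and (if `distance_m` given) `pwv_m_s`. Zero rows when nothing pairs.
#' @export
pair_peaks <- function(proximal, distal, rate, max_lag_s = NULL,
                       distance_m = 0.025) {
  if (is.null(max_lag_s)) {
    if (length(proximal) < 2L) {
      stop("pair_peaks: max_lag_s must be given when fewer than 2 proximal peaks",
           call. = FALSE)
    }
    max_lag_s <- 0.5 * stats::median(diff(proximal)) / rate
  }
  if (!is.finite(max_lag_s) || max_lag_s <= 0) {
    stop("pair_peaks: max_lag_s must be > 0", call. = FALSE)
  }
  max_lag <- max_lag_s * rate
  pp <- integer(0); dd <- integer(0)
  j <- 1L
  nd <- length(distal)
  for (p in proximal) {
    while (j <= nd && distal[j] <= p) j <- j + 1L
    if (j > nd) break
    if (distal[j] - p <= max_lag) {
      pp <- c(pp, p); dd <- c(dd, distal[j])
      j <- j + 1L
    }
  }
  out <- data.frame(proximal_peak = pp, distal_peak = dd,
                    ptt_s = (dd - pp) / rate)
  if (!is.null(distance_m)) out$pwv_m_s <- distance_m / out$ptt_s
  out
}

#' Pulse wave velocity from transit time
#'
#' @param ptt_s Pulse transit time in seconds, > 0 (vectorised).
#' @param distance_m Sensor separation in metres, > 0.
#' @return Velocity in m/s.
#' @export
pwv_from_ptt <- function(ptt_s, distance_m) {
  if (any(!is.finite(ptt_s)) || any(ptt_s <= 0)) {
    stop("pwv_from_ptt: ptt_s must be > 0 (non-positive PTT signals mis-pairing)",
         call. = FALSE)
  }
  if (!is.finite(distance_m) || distance_m <= 0) {
    stop("pwv_from_ptt: distance_m must be > 0", call. = FALSE)
  }
  distance_m / ptt_s
}
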