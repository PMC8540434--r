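# Beat-detection scoring against ground-truth annotations. A truth peak is a
# true positive when a detected peak lies within a small index tolerance
# (default +-3 samples, about 0.6 ms at 5 kHz); otherwise it is a false
# negative. Sensitivity and accuracy coincide in this scheme (no true
# negatives are defined for continuous beat streams) and percentages are
# truncated, not rounded, to one decimal.

#' Match detected peaks to ground-truth peaks
#'
#' Greedy one-to-one matching in index order: each truth peak takes the
#' nearest unused detected peak within `tol` samples (ties resolve to the
#' earlier detection). A detection is consumed by at most one truth peak.
#'
#' @param truth Sorted integer vector of ground-truth peak indices.
#' @param detected Sorted integer vector of detected peak indices.
#' @param tol Tolerance in samples, >= 0; default 3.
#' @return Logical vector, one flag per truth peak (`TRUE` = matched / TP).
#'   The number of unmatched detections (false positives, not part of the
#'   Se/Ac scheme) is attached as attribute `"false_positives"`.
#' @export
match_events <- function(truth, detected, tol = 3L) {
  if (tol < 0) stop("match_events: tol must be >= 0", call. = FALSE)
  used <- rep(FALSE, length(detected))
  matched <- logical(length(truth))
  for (i in seq_along(truth)) {
    if (length(detected) == 0L) break
    d <- abs(detected - truth[i])
    d[used | d > tol] <- NA_real_
    if (all(is.na(d))) next
    j <- which.min(d)  # nearest; which.min takes the first on ties
    used[j] <- TRUE
    matched[i] <- TRUE
  }
  attr(matched, "false_positives") <- sum(!used)
  matched
}

trunc1 <- function(x) floor(x * 10 + 1e-9) / 10

#' Score matched beats per class
#'
#' Splits truth beats into normal and ectopic classes and reports, per class,
#' total beats (TB), true positives (TP), false negatives (FN), sensitivity
#' `Se = TP / (TP + FN) * 100` and accuracy `Ac` (identical to Se in this
#' scheme; both kept for table fidelity). Percentages are truncated to one
#' decimal: 186/187 reports as 99.4, not 99.5.
#'
#' @param matches Logical match flags from [match_events()], one per truth beat.
#' @param labels Character labels (`"normal"` / `"ectopic"`) aligned with
#'   `matches`.
#' @return A data frame with rows `normal` and `ectopic` and columns
#'   `class`, `TB`, `TP`, `FN`, `Se`, `Ac`.
#' @export
detection_score <- function(matches, labels) {
  if (length(matches) != length(labels)) {
    stop("detection_score: matches and labels are not aligned", call. = FALSE)
  }
  one <- function(cls) {
    sel <- labels == cls
    tb <- sum(sel)
    tp <- sum(matches[sel])
    fn <- tb - tp
    se <- if (tb > 0) trunc1(tp / tb * 100) else NA_real_
    data.frame(class = cls, TB = tb, TP = tp, FN = fn, Se = se, Ac = se,
               stringsAsFactors = FALSE)
  }
  rbind(one("normal"), one("ectopic"))
}
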