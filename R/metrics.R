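#' Score QRS marker detection against annotated beats
#'
#' Greedy one-to-one matching in index order: a marker is a true positive if
#' an unmatched annotated R index lies inside the marker or within
#' `tolerance_ms` of it. Unmatched annotated beats are false negatives;
#' unmatched markers are false positives. (True negatives are not defined
#' for event detection and are reported as 0.)
#'
#' @param true_r Sorted integer vector of annotated R indices.
#' @param mk Marker `data.frame` (`start`, `end`), sorted.
#' @param fs Sampling rate in Hz.
#' @param tolerance_ms Matching tolerance around the marker (default 150).
#' @return A list of class `detection_score`: `tp`, `fn`, `fp`, `tn` (= 0),
#'   `tolerance_ms`, and `matched_marker` (per-beat marker row or NA).
#' @export
score_detection <- function(true_r, mk, fs = 360, tolerance_ms = 150) {
  true_r <- sort(as.integer(true_r))
  tol <- round(tolerance_ms / 1000 * fs)
  n_mk <- nrow(mk)
  used <- logical(n_mk)
  matched <- rep(NA_integer_, length(true_r))
  j <- 1L
  for (i in seq_along(true_r)) {
    r <- true_r[i]
    while (j <= n_mk && mk$end[j] + tol < r) j <- j + 1L
    k <- j
    while (k <= n_mk && mk$start[k] - tol <= r) {
      if (!used[k]) { matched[i] <- k; used[k] <- TRUE; break }
      k <- k + 1L
    }
  }
  tp <- sum(!is.na(matched))
  structure(list(tp = tp, fn = length(true_r) - tp,
                 fp = n_mk - sum(used), tn = 0L,
                 tolerance_ms = tolerance_ms, matched_marker = matched),
            class = "detection_score")
}

#' @export
print.detection_score <- function(x, ...) {
  r <- fn_fp_ratios(x)
  cat(sprintf("<detection_score> TP=%d FN=%d FP=%d (FN %.2f%%, FP %.2f%%)\n",
              x$tp, x$fn, x$fp, r["fn_ratio"], r["fp_ratio"]))
  invisible(x)
}

#' Missing- and mistaken-marker ratios
#'
#' `fn_ratio = 100 * FN / (TP + FN)` and `fp_ratio = 100 * FP / (TP + FN)`:
#' both are referred to the number of true beats.
#'
#' @param score A `detection_score`, or a list/row with `tp`, `fn`, `fp`.
#' @return Named numeric vector `c(fn_ratio, fp_ratio)` in percent.
#' @export
fn_fp_ratios <- function(score) {
  denom <- score$tp + score$fn
  if (denom <= 0) stop("fn_fp_ratios: no true beats (tp + fn == 0)")
  c(fn_ratio = 100 * score$fn / denom, fp_ratio = 100 * score$fp / denom)
}

#' One-vs-rest confusion counts
#'
#' @param truth,predicted Equal-length label vectors.
#' @param positive_class The class scored as positive.
#' @return A list of class `confusion_table`: `class`, `tp`, `fn`, `fp`,
#'   `tn`.
#' @export
confusion_one_vs_rest <- function(truth, predicted, positive_class) {
  if (length(truth) != length(predicted))
    stop("confusion_one_vs_rest: label vectors differ in length")
  t_pos <- truth == positive_class
  p_pos <- predicted == positive_class
  structure(list(class = positive_class,
                 tp = sum(t_pos & p_pos), fn = sum(t_pos & !p_pos),
                 fp = sum(!t_pos & p_pos), tn = sum(!t_pos & !p_pos)),
            class = "confusion_table")
}

#' Sensitivity, specificity and accuracy of a confusion table
#'
#' `sensitivity = 100 * TP / (TP + FN)`, `specificity = 100 * TN /
#' (TN + FP)`, `accuracy = 100 * (TP + TN) / (TP + FN + FP + TN)`. A zero
#' denominator yields `NaN` for that statistic.
#'
#' @param table A `confusion_table` (or any list with `tp`, `fn`, `fp`,
#'   `tn`).
#' @return Named numeric vector (percent).
#' @export
sens_spec_acc <- function(table) {
  with(table, c(
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NaN,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NaN,
    accuracy = if (tp + fn + fp + tn > 0)
      100 * (tp + tn) / (tp + fn + fp + tn) else NaN))
}

#' Round half away from zero
#'
#' The shipped reference tables quote percentages at one decimal
#' with halves rounded away from zero; base `round()` rounds halves to even.
#'
#' @param x Numeric.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-class classification report
#'
#' One-vs-rest confusion counts and statistics for every class present in
#' `truth` (plus any in `classes`).
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Classes to report (default: sorted union of `truth`).
#' @return A `data.frame` with one row per class: counts, sensitivity,
#'   specificity, accuracy (percent, full precision), plus attributes
#'   `pooled_accuracy` (fraction of exactly correct labels, percent) and
#'   `mean_accuracy` (mean of the per-class one-vs-rest accuracies).
#' @export
classification_report <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(truth)))
  rows <- lapply(classes, function(cl) {
    ct <- confusion_one_vs_rest(truth, predicted, cl)
    st <- sens_spec_acc(ct)
    data.frame(class = cl, tp = ct$tp, fn = ct$fn, fp = ct$fp, tn = ct$tn,
               sensitivity = st["sensitivity"],
               specificity = st["specificity"], accuracy = st["accuracy"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pooled_accuracy") <- 100 * mean(truth == predicted)
  attr(out, "mean_accuracy") <- mean(out$accuracy)
  out
}

#' Packaged reference evaluation counts
#'
#' Beat-by-beat evaluation count tables for the 33-record two-lead arrhythmia
#' test set (five-minute segments, Lead II + V1), shipped as plain-CSV
#' fixtures so the metric arithmetic can be verified without any download:
#'
#' * `"beats"` — per-record counts of annotated N/V/R/L/A beats.
#' * `"detection"` — per-record marker TP/FN/FP of the SVM detector.
#' * `"confusion_matched"` — one-vs-rest confusion counts of the classifier
#'   when detection errors are ignored.
#' * `"confusion_screened"` — the same with all markers classified and the
#'   output-threshold noise rejection active (includes the `noise` row).
#'
#' @param which One of `"beats"`, `"detection"`, `"confusion_matched"`,
#'   `"confusion_screened"`.
#' @return A `data.frame`.
#' @export
reference_counts <- function(which = c("beats", "detection",
                                       "confusion_matched",
                                       "confusion_screened")) {
  which <- match.arg(which)
  fname <- switch(which,
                  beats = "mitdb_beat_counts.csv",
                  detection = "mitdb_svm_detection.csv",
                  confusion_matched = "sonfin_confusion_matched.csv",
                  confusion_screened = "sonfin_confusion_screened.csv")
  path <- system.file("extdata", fname, package = "ecgsonfin")
  if (path == "") stop("fixture not found: ", fname)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
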