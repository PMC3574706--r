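#' Decide a beat label from the network outputs
#'
#' A marker whose segment is not a real heartbeat drives the TSK consequents
#' off their training manifold and the extrapolated outputs blow past the
#' target coding of +/-1; a magnitude threshold therefore separates noise
#' from true beats. If the rejection statistic exceeds `noise_threshold` the
#' beat is labeled `"noise"`, otherwise the class of the maximum output.
#'
#' @param outputs Numeric vector of raw network outputs (one per class).
#' @param noise_threshold Rejection threshold (default 2.5).
#' @param class_labels Class labels in output order.
#' @param statistic `"max_abs"` (default): reject on `max |o_i|`;
#'   `"max_raw"`: reject on `max o_i`.
#' @return A single label: one of `class_labels` or `"noise"`.
#' @export
decide_beat <- function(outputs, noise_threshold = 2.5,
                        class_labels = c("N", "V", "L", "R"),
                        statistic = c("max_abs", "max_raw")) {
  statistic <- match.arg(statistic)
  stopifnot(length(outputs) == length(class_labels))
  stat <- if (statistic == "max_abs") max(abs(outputs)) else max(outputs)
  if (is.finite(noise_threshold) && stat > noise_threshold) return("noise")
  class_labels[which.max(outputs)]
}

#' Flag premature atrial beats by RR prematurity
#'
#' PAC beats have normal (NSR) morphology — only their timing is premature —
#' so the network cannot separate them from NSR on waveform shape. A beat
#' labeled `N` whose preceding RR interval is shorter than
#' `prematurity_ratio` times the mean of the previous `history` RR intervals
#' is relabeled `A`.
#'
#' @param decisions `data.frame` ordered by `r_index` with columns `r_index`
#'   and `label` (as produced by [classify_record()]).
#' @param prematurity_ratio Prematurity threshold (default 0.85).
#' @param history Number of trailing RR intervals averaged (default 8).
#' @return The `data.frame` with premature `N` beats relabeled `A` and a
#'   `rr_prev` column (NA for the first beat).
#' @export
flag_pac <- function(decisions, prematurity_ratio = 0.85, history = 8L) {
  n <- nrow(decisions)
  decisions$rr_prev <- c(NA_integer_, diff(decisions$r_index))
  if (n < 3L) return(decisions)
  rr <- decisions$rr_prev
  for (i in 3:n) {
    if (decisions$label[i] != "N" || is.na(rr[i])) next
    hist_rr <- rr[max(2L, i - history):(i - 1L)]
    hist_rr <- hist_rr[!is.na(hist_rr)]
    if (!length(hist_rr)) next
    if (rr[i] < prematurity_ratio * mean(hist_rr))
      decisions$label[i] <- "A"
  }
  decisions
}

#' Classify every beat of a record
#'
#' The full pipeline: preprocess both leads, mark QRS samples with the SVM
#' detector, merge/delete markers, locate the R wave of each marker, extract
#' the 200-dimensional two-lead segments, run the SoNFIN forward pass,
#' threshold-reject noise markers, and flag premature atrial beats.
#'
#' @param record An [ecg_record()].
#' @param detector A `qrs_detector` from [train_detector()].
#' @param sonfin_model A trained `sonfin`.
#' @param noise_threshold Output-magnitude rejection threshold (default 2.5;
#'   `Inf` disables rejection).
#' @param prematurity_ratio,history PAC rule parameters (see [flag_pac()]).
#' @param spec A [filter_spec()].
#' @param statistic Rejection statistic (see [decide_beat()]).
#' @return A list of class `beat_decisions`: `decisions` (`data.frame` with
#'   `r_index`, `label`, outputs `o_N..o_R`, `rr_prev`), and `counts` (raw /
#'   post-processed / rejected marker tallies and skipped boundary beats).
#' @export
classify_record <- function(record, detector, sonfin_model,
                            noise_threshold = 2.5, prematurity_ratio = 0.85,
                            history = 8L, spec = filter_spec(),
                            statistic = "max_abs") {
  det <- detect_markers(detector, record, spec)
  beats <- extract_beats(det$preprocessed, det$markers)
  counts <- list(markers_raw = nrow(det$raw_markers),
                 markers_post = nrow(det$markers),
                 markers_removed = nrow(det$raw_markers) - nrow(det$markers),
                 beats_skipped = beats$n_skipped,
                 beats_rejected = 0L)
  if (!length(beats$segments)) {
    dec <- data.frame(r_index = integer(0), label = character(0),
                      rr_prev = integer(0))
    return(structure(list(decisions = dec, counts = counts,
                          markers = det$markers), class = "beat_decisions"))
  }
  feats <- beat_feature_matrix(beats)
  outs <- predict(sonfin_model, feats)
  labels <- vapply(seq_len(nrow(outs)), function(i)
    decide_beat(outs[i, ], noise_threshold, sonfin_model$class_labels,
                statistic), character(1))
  counts$beats_rejected <- sum(labels == "noise")
  dec <- data.frame(r_index = beats$r_indices, label = labels)
  colnames(outs) <- paste0("o_", sonfin_model$class_labels)
  dec <- cbind(dec, as.data.frame(outs))
  dec <- dec[order(dec$r_index), , drop = FALSE]
  accepted <- dec$label != "noise"
  dec$rr_prev <- NA_integer_
  dec[accepted, ] <- flag_pac(dec[accepted, , drop = FALSE],
                              prematurity_ratio, history)
  rownames(dec) <- NULL
  structure(list(decisions = dec, counts = counts, markers = det$markers),
            class = "beat_decisions")
}

#' @export
print.beat_decisions <- function(x, ...) {
  tab <- table(x$decisions$label)
  cat(sprintf("<beat_decisions> %d beats (%s); markers %d -> %d, rejected %d\n",
              nrow(x$decisions),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
              x$counts$markers_raw, x$counts$markers_post,
              x$counts$beats_rejected))
  invisible(x)
}

#' Write per-beat decisions to CSV
#'
#' @param result A `beat_decisions` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_decisions_csv <- function(result, path) {
  atomic_write(result$decisions, path)
  invisible(path)
}
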