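#' Build the sample-wise SVM training set
#'
#' For each selected annotated beat, one full cycle waveform (one RR interval
#' centered on the R wave, truncated at record edges) is taken from the
#' preprocessed record, and every sample in the cycle contributes one
#' two-dimensional feature `(raw, diff)` — the normalized filtered Lead II
#' value and its normalized first difference. Samples within
#' `qrs_halfwidth_ms` of the annotated R index are labeled `+1` (QRS region),
#' the rest `-1`.
#'
#' @param records List of annotated [ecg_record()] objects (or a single one).
#' @param per_type_beats Named integer vector: how many beats of each label to
#'   select (first occurrences across the records). Default
#'   `c(N = 27, V = 18, R = 4, L = 4)`, a small mixed set of 53 beats.
#' @param qrs_halfwidth_ms Half-width of the positive-label window around the
#'   R wave, in ms (default 40: an 80 ms window covers a QRS of at least
#'   60 ms symmetrically).
#' @param spec A [filter_spec()].
#' @return A `data.frame` with columns `raw`, `diff` (both in `[-1, 1]`) and
#'   `label` (`+1`/`-1`), one row per cycle sample, plus attribute `n_cycles`.
#' @export
build_training_set <- function(records,
                               per_type_beats = c(N = 27, V = 18, R = 4, L = 4),
                               qrs_halfwidth_ms = 40,
                               spec = filter_spec()) {
  if (inherits(records, "ecg_record")) records <- list(records)
  if (!length(records)) {
    out <- data.frame(raw = numeric(0), diff = numeric(0), label = numeric(0))
    attr(out, "n_cycles") <- 0L
    return(out)
  }
  quota <- per_type_beats
  rows <- list(); n_cycles <- 0L
  for (rec in records) {
    if (is.null(rec$annotations))
      stop("build_training_set: record '", rec$record_id,
           "' has no annotations")
    pp <- preprocess_record(rec, spec)
    half_w <- round(qrs_halfwidth_ms / 1000 * rec$fs)
    ann <- rec$annotations
    n <- length(rec$lead_ii)
    for (b in seq_len(nrow(ann))) {
      lab <- ann$label[b]
      if (is.na(quota[lab]) || quota[lab] <= 0L) next
      r <- ann$r_index[b]
      # one cycle: half the neighboring RR interval on each side
      left_rr <- if (b > 1) r - ann$r_index[b - 1] else NA
      right_rr <- if (b < nrow(ann)) ann$r_index[b + 1] - r else NA
      rr <- round(mean(c(left_rr, right_rr), na.rm = TRUE))
      if (!is.finite(rr)) rr <- round(rec$fs * 0.8)
      lo <- max(1L, r - rr %/% 2L)
      hi <- min(n, r + rr %/% 2L)
      idx <- lo:hi
      rows[[length(rows) + 1L]] <- data.frame(
        raw = pp$lead_ii[idx],
        diff = pp$diff_ii[idx],
        label = ifelse(abs(idx - r) <= half_w, 1, -1))
      quota[lab] <- quota[lab] - 1L
      n_cycles <- n_cycles + 1L
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(raw = numeric(0), diff = numeric(0), label = numeric(0))
  attr(out, "n_cycles") <- n_cycles
  out
}

#' Train the QRS-marking SVM
#'
#' Fits a soft-margin SVM with Gaussian radial-basis kernel
#' `K(x, xi) = exp(-gamma * ||x - xi||^2)` on the labeled `(raw, diff)`
#' samples. The decision function is the usual support-vector expansion
#' `f(x) = sum_i D_i alpha_i K(x, x_i) + b`; the returned model stores the
#' support vectors, signed coefficients `D_i alpha_i`, bias, `gamma` and
#' `cost` explicitly so it can be evaluated and serialized independently of
#' the solver.
#'
#' @param features A labeled `data.frame` from [build_training_set()] (columns
#'   `raw`, `diff`, `label` in `{+1, -1}`).
#' @param gamma Kernel radial size (default 2.5).
#' @param cost Box constraint C (default 200).
#' @return A list of class `qrs_detector` with elements `sv` (matrix, one
#'   support vector per row), `coefs` (`D_i alpha_i`), `b`, `gamma`, `cost`.
#' @export
train_detector <- function(features, gamma = 2.5, cost = 200) {
  lab <- features$label
  if (length(unique(lab)) < 2L)
    stop("train_detector: need both +1 and -1 labels")
  x <- as.matrix(features[, c("raw", "diff")])
  y <- factor(lab, levels = c(1, -1))
  fit <- e1071::svm(x, y, kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE)
  model <- structure(
    list(sv = unname(as.matrix(fit$SV)),
         coefs = as.numeric(fit$coefs),
         b = -fit$rho, gamma = gamma, cost = cost),
    class = "qrs_detector")
  # libsvm orients the decision value toward the class listed first in
  # fit$labels; flip so that positive always means QRS (+1)
  pos_first <- fit$levels[fit$labels[1]] == "1"
  if (!pos_first) {
    model$coefs <- -model$coefs
    model$b <- -model$b
  }
  model
}

#' Evaluate the SVM decision function
#'
#' `f(x) = sum_i D_i alpha_i exp(-gamma ||x - x_i||^2) + b`, computed in
#' chunks from the stored support vectors.
#'
#' @param model A `qrs_detector`.
#' @param raw,diff Equal-length numeric vectors of normalized features.
#' @return Numeric decision values (positive = QRS region).
#' @export
decision_values <- function(model, raw, diff) {
  stopifnot(inherits(model, "qrs_detector"), length(raw) == length(diff))
  x <- cbind(raw, diff)
  sv <- model$sv
  sv_norm2 <- rowSums(sv^2)
  n <- nrow(x)
  out <- numeric(n)
  chunk <- 20000L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    xi <- x[idx, , drop = FALSE]
    d2 <- outer(rowSums(xi^2), sv_norm2, `+`) - 2 * xi %*% t(sv)
    out[idx] <- exp(-model$gamma * pmax(d2, 0)) %*% model$coefs + model$b
  }
  out
}

#' Mark samples as QRS / non-QRS
#'
#' Applies the detector sample-by-sample to the normalized Lead II signal and
#' its normalized difference.
#'
#' @param model A `qrs_detector` from [train_detector()].
#' @param lead_ii_norm,diff_norm Equal-length normalized sequences.
#' @return Integer vector of decisions in `{+1, -1}`.
#' @export
mark_samples <- function(model, lead_ii_norm, diff_norm) {
  if (length(lead_ii_norm) != length(diff_norm))
    stop("mark_samples: sequences must have equal length")
  ifelse(decision_values(model, lead_ii_norm, diff_norm) > 0, 1L, -1L)
}

#' Run-length encode positive decisions into markers
#'
#' @param decisions Integer vector in `{+1, -1}`.
#' @return A `data.frame` with columns `start`, `end` (1-based inclusive
#'   sample indices) and `width`, one row per maximal run of `+1`.
#' @export
markers_from_decisions <- function(decisions) {
  if (length(decisions) && !all(decisions %in% c(-1L, 1L)))
    stop("decisions must be +1/-1")
  r <- rle(as.integer(decisions))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  markers(starts[keep], ends[keep])
}

markers <- function(start, end) {
  df <- data.frame(start = as.integer(start), end = as.integer(end))
  df$width <- df$end - df$start + 1L
  df
}

#' Merge and delete redundant QRS markers
#'
#' Neighboring markers separated by a gap of fewer than `min_gap` samples are
#' merged (repeatedly, until stable) — this recovers, e.g., the two narrow
#' runs an LBBB double peak produces. Then markers narrower than `min_width`
#' samples are deleted: a QRS complex spans at least 60 ms, i.e. over 20
#' samples at 360 Hz, so sub-10-sample markers are noise.
#'
#' @param mk Marker `data.frame` (`start`, `end`), sorted, non-overlapping.
#' @param min_width Minimum surviving marker width in samples (default 10).
#' @param min_gap Minimum allowed gap between neighbors in samples
#'   (default 5); smaller gaps trigger a merge.
#' @return Post-processed marker `data.frame`.
#' @export
postprocess_markers <- function(mk, min_width = 10L, min_gap = 5L) {
  if (!nrow(mk)) return(markers(integer(0), integer(0)))
  mk <- mk[order(mk$start), , drop = FALSE]
  # merge neighbors with gap < min_gap
  start <- mk$start; end <- mk$end
  out_s <- start[1]; out_e <- end[1]
  for (i in seq_len(nrow(mk))[-1]) {
    gap <- start[i] - out_e[length(out_e)] - 1L
    if (gap < min_gap) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], end[i])
    } else {
      out_s <- c(out_s, start[i]); out_e <- c(out_e, end[i])
    }
  }
  mk <- markers(out_s, out_e)
  mk <- mk[mk$width >= min_width, , drop = FALSE]
  rownames(mk) <- NULL
  mk
}

#' Detect QRS markers in a record
#'
#' Convenience wrapper: preprocess, mark samples, run-length encode, and
#' post-process.
#'
#' @param model A `qrs_detector`.
#' @param record An [ecg_record()] (or an `ecg_preprocessed` object).
#' @param spec A [filter_spec()].
#' @return A list with `markers` (post-processed), `raw_markers`, and
#'   `preprocessed`.
#' @export
detect_markers <- function(model, record, spec = filter_spec()) {
  pp <- if (inherits(record, "ecg_preprocessed")) record else
    preprocess_record(record, spec)
  dec <- mark_samples(model, pp$lead_ii, pp$diff_ii)
  raw_mk <- markers_from_decisions(dec)
  list(markers = postprocess_markers(raw_mk), raw_markers = raw_mk,
       preprocessed = pp)
}

#' Serialize / restore a QRS detector
#'
#' @param model A `qrs_detector`.
#' @param path JSON file path.
#' @return `write_detector` invisibly returns `path`; `read_detector` returns
#'   the restored `qrs_detector`.
#' @export
write_detector <- function(model, path) {
  stopifnot(inherits(model, "qrs_detector"))
  obj <- list(type = "qrs_detector",
              gamma = model$gamma, cost = model$cost, b = model$b,
              coefs = model$coefs,
              support_vectors = as.data.frame(model$sv))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_detector
#' @export
read_detector <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "qrs_detector"))
    stop("not a serialized qrs_detector: ", path)
  structure(list(sv = unname(as.matrix(obj$support_vectors)),
                 coefs = as.numeric(obj$coefs), b = obj$b,
                 gamma = obj$gamma, cost = obj$cost),
            class = "qrs_detector")
}

#' @export
print.qrs_detector <- function(x, ...) {
  cat(sprintf("<qrs_detector> %d support vectors, gamma=%g, C=%g\n",
              nrow(x$sv), x$gamma, x$cost))
  invisible(x)
}
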