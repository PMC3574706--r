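#' Pipeline configuration
#'
#' Collects every stage's tunables with their standard defaults: the FIR /
#' notch front end, the SVM kernel radial size gamma = 2.5 and box constraint
#' C = 200, the SoNFIN training settings (H = 0.1, sigma0 = 0.6, 1000
#' iterations, consequent/fuzzy rates 0.01/0.05), the noise-rejection output
#' threshold 2.5, the PAC prematurity rule, and the detection-scoring
#' tolerance.
#'
#' @param fs Sampling rate in Hz.
#' @param filter A [filter_spec()].
#' @param svm_gamma,svm_cost SVM kernel radial size and box constraint.
#' @param per_type_beats Detector training-beat quota (see
#'   [build_training_set()]).
#' @param qrs_halfwidth_ms Positive-label half window (ms).
#' @param sonfin A [sonfin_config()].
#' @param noise_threshold Output-magnitude rejection threshold.
#' @param prematurity_ratio,pac_history PAC rule parameters.
#' @param tolerance_ms Detection-scoring match tolerance (ms).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 360, filter = filter_spec(),
                            svm_gamma = 2.5, svm_cost = 200,
                            per_type_beats = c(N = 27, V = 18, R = 4, L = 4),
                            qrs_halfwidth_ms = 40,
                            sonfin = sonfin_config(),
                            noise_threshold = 2.5,
                            prematurity_ratio = 0.85, pac_history = 8L,
                            tolerance_ms = 150) {
  structure(list(fs = as.numeric(fs), filter = filter,
                 svm_gamma = as.numeric(svm_gamma),
                 svm_cost = as.numeric(svm_cost),
                 per_type_beats = stats::setNames(as.numeric(per_type_beats),
                                                  names(per_type_beats)),
                 qrs_halfwidth_ms = as.numeric(qrs_halfwidth_ms),
                 sonfin = sonfin,
                 noise_threshold = as.numeric(noise_threshold),
                 prematurity_ratio = as.numeric(prematurity_ratio),
                 pac_history = as.integer(pac_history),
                 tolerance_ms = as.numeric(tolerance_ms)),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' Round-trips losslessly through JSON.
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config` invisibly returns `path`;
#'   `read_pipeline_config` the restored config.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- unclass(config)
  obj$filter <- unclass(obj$filter)
  obj$sonfin <- unclass(obj$sonfin)
  obj$per_type_beats <- as.list(obj$per_type_beats)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    fs = obj$fs,
    filter = do.call(filter_spec, obj$filter),
    svm_gamma = obj$svm_gamma, svm_cost = obj$svm_cost,
    per_type_beats = unlist(obj$per_type_beats),
    qrs_halfwidth_ms = obj$qrs_halfwidth_ms,
    sonfin = do.call(sonfin_config, obj$sonfin),
    noise_threshold = obj$noise_threshold,
    prematurity_ratio = obj$prematurity_ratio,
    pac_history = obj$pac_history,
    tolerance_ms = obj$tolerance_ms)
}

#' Train both models from annotated records
#'
#' Trains the QRS-marking SVM on `detector_records` (per the config's
#' training-beat quota) and the SoNFIN on beat segments extracted at the
#' annotated R indices of `classifier_records` (labels `A` are trained as
#' `N`: PAC morphology is normal, only its timing differs).
#'
#' @param detector_records,classifier_records Lists of annotated
#'   [ecg_record()]s (a single record is accepted).
#' @param config A [pipeline_config()].
#' @param beats_per_class Number of training beats per class for the
#'   classifier (default 26).
#' @return A list with `detector` (a `qrs_detector`) and `classifier`
#'   (a trained `sonfin`).
#' @export
train_pipeline <- function(detector_records, classifier_records = NULL,
                           config = pipeline_config(),
                           beats_per_class = 26L) {
  if (inherits(detector_records, "ecg_record"))
    detector_records <- list(detector_records)
  if (is.null(classifier_records)) classifier_records <- detector_records
  if (inherits(classifier_records, "ecg_record"))
    classifier_records <- list(classifier_records)

  ts <- build_training_set(detector_records, config$per_type_beats,
                           config$qrs_halfwidth_ms, config$filter)
  detector <- train_detector(ts, config$svm_gamma, config$svm_cost)

  feats <- list(); labs <- character(0)
  quota <- stats::setNames(rep(beats_per_class, 4), c("N", "V", "L", "R"))
  for (rec in classifier_records) {
    if (is.null(rec$annotations))
      stop("train_pipeline: classifier record '", rec$record_id,
           "' has no annotations")
    pp <- preprocess_record(rec, config$filter)
    ann <- rec$annotations
    for (b in seq_len(nrow(ann))) {
      lab <- ann$label[b]
      if (lab == "A") lab <- "N"
      if (is.na(quota[lab]) || quota[lab] <= 0L) next
      # snap to the local Lead II maximum so training segments align with
      # the marker-based R localization used at test time
      r <- snap_to_peak(pp$lead_ii, ann$r_index[b])
      seg <- extract_segment(pp, r)
      if (is.null(seg)) next
      feats[[length(feats) + 1L]] <- seg$feature
      labs <- c(labs, lab)
      quota[lab] <- quota[lab] - 1L
    }
  }
  if (!length(feats)) stop("train_pipeline: no classifier training beats")
  classifier <- sonfin_train(do.call(rbind, feats), labs, config$sonfin,
                             class_labels = c("N", "V", "L", "R"))
  list(detector = detector, classifier = classifier)
}

snap_to_peak <- function(x, r, halfwin = 5L) {
  lo <- max(1L, r - halfwin)
  hi <- min(length(x), r + halfwin)
  lo + which.max(x[lo:hi]) - 1L
}

#' Run the full pipeline on a record and score it
#'
#' Detects, classifies and (when the record is annotated) scores a record:
#' detection TP/FN/FP at the configured tolerance and a per-class
#' classification report over the matched beats.
#'
#' @param record An [ecg_record()].
#' @param models A list with `detector` and `classifier` (see
#'   [train_pipeline()]).
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report`: `decisions`
#'   (a `beat_decisions`), and when annotations exist `detection`
#'   (a `detection_score`) and `classification` (a report `data.frame` from
#'   [classification_report()] over matched, accepted beats).
#' @export
run_pipeline <- function(record, models, config = pipeline_config()) {
  res <- classify_record(record, models$detector, models$classifier,
                         noise_threshold = config$noise_threshold,
                         prematurity_ratio = config$prematurity_ratio,
                         history = config$pac_history, spec = config$filter)
  out <- list(decisions = res)
  if (!is.null(record$annotations)) {
    ann <- record$annotations
    out$detection <- score_detection(ann$r_index, res$markers,
                                     fs = record$fs,
                                     tolerance_ms = config$tolerance_ms)
    # match decisions to annotated beats by nearest R within tolerance
    tol <- round(config$tolerance_ms / 1000 * record$fs)
    dec <- res$decisions
    truth <- character(0); pred <- character(0)
    for (i in seq_len(nrow(ann))) {
      if (!nrow(dec)) break
      d <- abs(dec$r_index - ann$r_index[i])
      j <- which.min(d)
      if (d[j] <= tol) {
        truth <- c(truth, ann$label[i])
        pred <- c(pred, dec$label[j])
      }
    }
    keep <- pred != "noise"
    out$matched <- data.frame(truth = truth, pred = pred)
    if (any(keep))
      out$classification <- classification_report(truth[keep], pred[keep])
  }
  structure(out, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  print(x$decisions)
  if (!is.null(x$detection)) print(x$detection)
  if (!is.null(x$classification)) {
    cat(sprintf("  pooled accuracy: %.1f%%\n",
                attr(x$classification, "pooled_accuracy")))
  }
  invisible(x)
}
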