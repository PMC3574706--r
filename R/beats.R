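#' Locate the R wave from a QRS marker
#'
#' Starting from the marker's positive edge (its start index), searches
#' forward for the minimum of Lead II within 100 samples, then backward from
#' that minimum for the maximum within 50 samples. The maximum is taken as
#' the R wave. This two-step search is robust to inverted (PVC) complexes,
#' where the marker sits on the positive deflection preceding the deep
#' negative wave.
#'
#' @param lead_ii Numeric Lead II sequence (normalized or raw).
#' @param marker_start 1-based start index of the marker.
#' @param forward Forward search span in samples (default 100).
#' @param backward Backward search span in samples (default 50).
#' @return 1-based R-wave sample index.
#' @export
locate_r_wave <- function(lead_ii, marker_start, forward = 100L,
                          backward = 50L) {
  n <- length(lead_ii)
  if (marker_start < 1L || marker_start > n)
    stop("marker start outside record")
  fwd_hi <- min(n, marker_start + forward - 1L)
  min_idx <- marker_start + which.min(lead_ii[marker_start:fwd_hi]) - 1L
  bwd_lo <- max(1L, min_idx - backward)
  bwd_lo + which.max(lead_ii[bwd_lo:min_idx]) - 1L
}

#' Extract a 200-dimensional two-lead beat segment
#'
#' Takes 100 samples of normalized Lead II centered on the R wave (window
#' `[r - 50, r + 49]`, R at position 51) and the same index range on V1; the
#' feature vector is their concatenation (length 200). Beats whose window
#' would cross a record boundary are skipped (`NULL`), since the classifier
#' input dimension is fixed.
#'
#' @param pp An `ecg_preprocessed` object from [preprocess_record()].
#' @param r_index 1-based R-wave sample index.
#' @param half Half window in samples (default 50; window length `2 * half`).
#' @return A list of class `beat_segment` with `r_index`, `lead_ii_window`,
#'   `v1_window` (each length `2 * half`) and `feature` (their concatenation,
#'   length `4 * half` = 200 at the default) — or `NULL` if the window
#'   exceeds the record bounds.
#' @export
extract_segment <- function(pp, r_index, half = 50L) {
  n <- length(pp$lead_ii)
  if (r_index - half < 1L || r_index + half - 1L > n) return(NULL)
  idx <- (r_index - half):(r_index + half - 1L)
  ii <- pp$lead_ii[idx]
  v1 <- pp$lead_v1[idx]
  structure(list(r_index = as.integer(r_index),
                 lead_ii_window = ii, v1_window = v1,
                 feature = c(ii, v1)),
            class = "beat_segment")
}

#' Extract all beat segments for a marker set
#'
#' Runs [locate_r_wave()] on each marker's positive edge, removes duplicate R
#' locations, and extracts the 200-dimensional segments. Boundary beats are
#' skipped and counted.
#'
#' @param pp An `ecg_preprocessed` object.
#' @param mk Post-processed marker `data.frame` (`start`, `end`).
#' @inheritParams extract_segment
#' @return A list with `segments` (list of `beat_segment`), `r_indices`,
#'   `marker_index` (which marker produced each segment), and `n_skipped`.
#' @export
extract_beats <- function(pp, mk, half = 50L) {
  segs <- list(); r_out <- integer(0); m_out <- integer(0); skipped <- 0L
  seen <- integer(0)
  for (i in seq_len(nrow(mk))) {
    r <- locate_r_wave(pp$lead_ii, mk$start[i])
    if (r %in% seen) next
    seen <- c(seen, r)
    seg <- extract_segment(pp, r, half)
    if (is.null(seg)) { skipped <- skipped + 1L; next }
    seg$source_marker <- c(start = mk$start[i], end = mk$end[i])
    segs[[length(segs) + 1L]] <- seg
    r_out <- c(r_out, r); m_out <- c(m_out, i)
  }
  list(segments = segs, r_indices = r_out, marker_index = m_out,
       n_skipped = skipped)
}

#' Beat segments as a feature matrix
#'
#' @param beats Result of [extract_beats()], or a list of `beat_segment`s.
#' @return Numeric matrix, one row per beat, `2 * window` columns.
#' @export
beat_feature_matrix <- function(beats) {
  segs <- if (!is.null(beats$segments)) beats$segments else beats
  if (!length(segs)) return(matrix(numeric(0), nrow = 0))
  do.call(rbind, lapply(segs, function(s) s$feature))
}
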