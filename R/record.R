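#' Two-lead ECG record
#'
#' Container for a synchronized pair of ECG leads (Lead II and V1) sampled at a
#' common rate, with optional beat annotations. Lead II carries the rhythm
#' information used for QRS marking; V1 is a precordial lead whose morphology
#' separates the bundle-branch-block patterns.
#'
#' @param lead_ii Numeric vector, Lead II amplitudes in mV.
#' @param lead_v1 Numeric vector, V1 amplitudes in mV; same length as `lead_ii`.
#' @param fs Sampling rate in Hz (default 360).
#' @param record_id Character identifier.
#' @param annotations Optional `data.frame` with columns `r_index` (1-based
#'   sample index of the R wave) and `label` (one of `"N"`, `"V"`, `"L"`,
#'   `"R"`, `"A"`, `"noise"`).
#'
#' @return An object of class `ecg_record`: a list with elements `record_id`,
#'   `fs`, `lead_ii`, `lead_v1`, `annotations`.
#' @export
ecg_record <- function(lead_ii, lead_v1, fs = 360, record_id = "record",
                       annotations = NULL) {
  lead_ii <- as.numeric(lead_ii)
  lead_v1 <- as.numeric(lead_v1)
  if (length(lead_ii) < 1L)
    stop("ecg_record: leads must contain at least one sample")
  if (length(lead_ii) != length(lead_v1))
    stop("ecg_record: lead_ii and lead_v1 must have equal length")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("ecg_record: fs must be a positive scalar")
  if (!is.null(annotations)) {
    annotations <- validate_annotations(annotations, length(lead_ii))
  }
  structure(
    list(record_id = as.character(record_id), fs = fs,
         lead_ii = lead_ii, lead_v1 = lead_v1, annotations = annotations),
    class = "ecg_record"
  )
}

beat_labels <- function() c("N", "V", "L", "R", "A", "noise")

validate_annotations <- function(annotations, n_samples) {
  annotations <- as.data.frame(annotations)
  if (!all(c("r_index", "label") %in% names(annotations)))
    stop("annotations must have columns r_index and label")
  annotations$r_index <- as.integer(annotations$r_index)
  annotations$label <- as.character(annotations$label)
  if (any(annotations$r_index < 1L | annotations$r_index > n_samples))
    stop("annotation r_index outside record (1..", n_samples, ")")
  bad <- setdiff(unique(annotations$label), beat_labels())
  if (length(bad))
    stop("unknown beat label(s): ", paste(bad, collapse = ", "))
  annotations[order(annotations$r_index), c("r_index", "label"), drop = FALSE]
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> %d samples @ %g Hz (%.1f s)\n",
              x$record_id, length(x$lead_ii), x$fs, length(x$lead_ii) / x$fs))
  if (!is.null(x$annotations)) {
    tab <- table(x$annotations$label)
    cat("  annotations:", paste(sprintf("%s=%d", names(tab), tab),
                                collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$lead_ii)

#' Read a two-lead ECG record from CSV
#'
#' Reads a two-column CSV (`lead_ii`, `lead_v1`, with header) as written by
#' [write_ecg_csv()]. If an annotation file `<path base>.ann.csv` exists (or
#' one is supplied), it is read as columns `r_index,label`. Records lacking a
#' V1 column are rejected: the pipeline requires the Lead II / V1 pair.
#'
#' @param path Path to the signal CSV.
#' @param fs Sampling rate in Hz.
#' @param annotations_path Optional annotation CSV path; defaults to
#'   `<path without .csv>.ann.csv` when that file exists.
#' @param record_id Identifier; defaults to the file base name.
#' @return An [ecg_record()].
#' @export
read_ecg_csv <- function(path, fs = 360, annotations_path = NULL,
                         record_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- tryCatch(
    utils::read.csv(path, colClasses = "numeric"),
    error = function(e) stop("parse error in '", path, "' near byte ",
                             file.size(path), ": ", conditionMessage(e))
  )
  if (!"lead_ii" %in% names(dat))
    stop("record '", path, "' has no lead_ii column")
  if (!"lead_v1" %in% names(dat))
    stop("unsupported record '", path,
         "': missing V1 lead (the pipeline requires the Lead II / V1 pair)")
  if (is.null(annotations_path)) {
    cand <- paste0(sub("\\.csv$", "", path), ".ann.csv")
    if (file.exists(cand)) annotations_path <- cand
  }
  ann <- NULL
  if (!is.null(annotations_path)) {
    ann <- utils::read.csv(annotations_path,
                           colClasses = c("integer", "character"))
  }
  if (is.null(record_id))
    record_id <- sub("\\.csv$", "", basename(path))
  ecg_record(dat$lead_ii, dat$lead_v1, fs = fs, record_id = record_id,
             annotations = ann)
}

#' Write a two-lead ECG record to CSV
#'
#' Writes the signal as a two-column CSV and, when annotations are present,
#' a companion `<base>.ann.csv` with columns `r_index,label`. Writes are
#' atomic (write to a temporary file in the same directory, then rename).
#'
#' @param record An [ecg_record()].
#' @param path Output CSV path.
#' @return Invisibly, the signal path.
#' @export
write_ecg_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  df <- data.frame(lead_ii = record$lead_ii, lead_v1 = record$lead_v1)
  atomic_write(df, path)
  if (!is.null(record$annotations)) {
    atomic_write(record$annotations, paste0(sub("\\.csv$", "", path), ".ann.csv"))
  }
  invisible(path)
}

atomic_write <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
}
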