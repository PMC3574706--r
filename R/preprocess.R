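#' Filtering specification
#'
#' Parameters of the noise-reduction front end: an order-10 linear-phase FIR
#' low-pass at 40 Hz against muscle/powerline noise, and a DC-notch baseline
#' canceller whose stop band spans 0 to `notch_bandwidth_hz`.
#'
#' @param lowpass_order FIR order (default 10; the filter has order + 1 taps).
#' @param lowpass_cutoff_hz Low-pass cutoff in Hz (default 40).
#' @param notch_bandwidth_hz Baseline notch -3 dB edge in Hz (default 0.5).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(lowpass_order = 10, lowpass_cutoff_hz = 40,
                        notch_bandwidth_hz = 0.5) {
  stopifnot(lowpass_order >= 2, lowpass_cutoff_hz > 0, notch_bandwidth_hz > 0)
  structure(list(lowpass_order = as.integer(lowpass_order),
                 lowpass_cutoff_hz = as.numeric(lowpass_cutoff_hz),
                 notch_bandwidth_hz = as.numeric(notch_bandwidth_hz)),
            class = "filter_spec")
}

#' FIR taps of the low-pass stage
#'
#' Hamming-windowed linear-phase design with unity DC gain. Exposed so the
#' frequency response can be evaluated directly.
#'
#' @inheritParams lowpass_filter
#' @return Numeric vector of `lowpass_order + 1` taps.
#' @export
lowpass_taps <- function(fs, spec = filter_spec()) {
  if (spec$lowpass_cutoff_hz >= fs / 2)
    stop("lowpass cutoff must be below the Nyquist frequency fs/2")
  b <- as.numeric(signal::fir1(spec$lowpass_order,
                               spec$lowpass_cutoff_hz / (fs / 2),
                               type = "low"))
  b / sum(b)  # unity DC gain
}

#' Low-pass filter an ECG lead
#'
#' Applies the windowed-sinc FIR low-pass with group-delay compensation
#' (`order/2` samples), so the output stays index-aligned with the input.
#' Edges are handled by replicating the first/last sample.
#'
#' @param x Numeric signal (mV).
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_filter <- function(x, fs, spec = filter_spec()) {
  x <- as.numeric(x)
  ord <- spec$lowpass_order
  if (length(x) <= ord)
    stop("signal shorter than the FIR filter order (", ord, ")")
  b <- lowpass_taps(fs, spec)
  delay <- ord %/% 2
  xp <- c(rep(x[1], ord), x, rep(x[length(x)], ord))
  y <- as.numeric(signal::filter(b, 1, xp))
  y[(ord + delay + 1):(ord + delay + length(x))]
}

#' Remove baseline wander
#'
#' A single-weight adaptive canceller with constant reference input: the
#' weight tracks a running DC/baseline estimate of the signal and the error
#' output is the baseline-free signal, equivalent to a first-order DC-notch.
#' The canceller runs forward and then backward over the signal (zero phase,
#' so no group delay), with the per-pass step size set so the cascade's
#' -3 dB stop-band edge sits at `spec$notch_bandwidth_hz`.
#'
#' @inheritParams lowpass_filter
#' @return Signal with DC and sub-`notch_bandwidth_hz` drift removed.
#' @export
remove_baseline <- function(x, fs, spec = filter_spec()) {
  x <- as.numeric(x)
  if (length(x) < 1L) stop("empty signal")
  if (length(x) == 1L) return(0)
  # per-pass edge f1 such that |H1(f1)|^4 = 1/2 for the two-pass cascade
  f1 <- spec$notch_bandwidth_hz / sqrt(sqrt(2) - 1)
  mu <- 2 * pi * f1 / fs
  y <- lms_dc_cancel(x, mu)
  rev(lms_dc_cancel(rev(y), mu))
}

# One pass of the constant-reference LMS canceller:
#   w[t] = (1-mu) w[t-1] + mu x[t-1],  e[t] = x[t] - w[t],  w[1] = x[1]
lms_dc_cancel <- function(x, mu) {
  n <- length(x)
  w <- c(x[1], as.numeric(
    stats::filter(mu * x[1:(n - 1)], 1 - mu, method = "recursive",
                  init = x[1])))
  x - w
}

#' Min-max normalize to [-1, 1]
#'
#' Affine map `2 * (x - min) / (max - min) - 1`; the minimum maps exactly to
#' -1 and the maximum exactly to +1.
#'
#' @param x Numeric signal.
#' @return Normalized signal in `[-1, 1]`.
#' @export
normalize_minmax <- function(x) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!is.finite(rng[1]) || !is.finite(rng[2]))
    stop("normalize_minmax: non-finite values in input")
  if (rng[1] == rng[2])
    stop("normalize_minmax: degenerate constant input (max == min)")
  2 * (x - rng[1]) / (rng[2] - rng[1]) - 1
}

#' First-difference of a signal
#'
#' `y[n] = x[n] - x[n-1]` with `y[1] = 0`, preserving length and index
#' alignment. The difference signal is large over the steep QRS complex and
#' small elsewhere, which is what makes it a useful marking feature.
#'
#' @param x Numeric signal, length >= 2.
#' @return Difference signal, same length as `x`.
#' @export
differentiate <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("differentiate: need at least two samples")
  c(0, diff(x))
}

#' Preprocess a two-lead record for detection and classification
#'
#' Runs the full front end on both leads: low-pass, baseline removal, min-max
#' normalization; and on Lead II additionally the normalized first difference
#' used by the QRS-marking SVM.
#'
#' @param record An [ecg_record()].
#' @param spec A [filter_spec()].
#' @return A list of class `ecg_preprocessed` with elements `record`
#'   (the input), `lead_ii` and `lead_v1` (filtered, baseline-free,
#'   normalized), and `diff_ii` (normalized first difference of the filtered
#'   Lead II).
#' @export
preprocess_record <- function(record, spec = filter_spec()) {
  stopifnot(inherits(record, "ecg_record"))
  clean <- function(x) remove_baseline(lowpass_filter(x, record$fs, spec),
                                       record$fs, spec)
  ii <- clean(record$lead_ii)
  v1 <- clean(record$lead_v1)
  structure(
    list(record = record,
         lead_ii = normalize_minmax(ii),
         lead_v1 = normalize_minmax(v1),
         diff_ii = normalize_minmax(differentiate(ii))),
    class = "ecg_preprocessed"
  )
}
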