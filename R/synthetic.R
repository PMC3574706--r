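#' Beat morphology templates
#'
#' Each template is a pair of sampled waveforms (Lead II, V1) built as sums of
#' Gaussian bumps for the P, Q, R, S and T deflections, with the R wave at the
#' template midpoint. Morphologies follow the textbook two-lead signatures:
#'
#' * `N` (and `A`): upright narrow R in Lead II with P and T waves; rS in V1.
#'   PAC shares the NSR shape — only its premature timing differs.
#' * `V`: wide, dominantly inverted QRS in Lead II, no P wave, discordant T.
#' * `L`: widened R with two neighboring positive peaks in Lead II, lost
#'   Q wave; deep wide QS in V1.
#' * `R`: widened S in Lead II; rsR' pattern in V1.
#'
#' @param fs Sampling rate in Hz (default 360).
#' @return Named list of templates (`N`, `V`, `L`, `R`, `A`), each a list with
#'   `label`, `lead_ii`, `v1` (numeric waveforms, mV), `r_offset` (index of
#'   the R wave within the waveform), and `qrs_support` (integer vector
#'   `c(first, last)` of the QRS extent, relative to the same indexing).
#' @export
beat_templates <- function(fs = 360) {
  half_s <- 0.32                       # template spans R +/- 320 ms
  t <- seq(-half_s, half_s, by = 1 / fs)
  r_offset <- which.min(abs(t))        # t == 0
  bump <- function(amp, center, width) amp * exp(-((t - center)^2) / (2 * width^2))

  mk <- function(label, qrs_ii, other_ii, v1) {
    qrs_wave <- Reduce(`+`, lapply(qrs_ii, function(p) bump(p[1], p[2], p[3])))
    ii <- qrs_wave +
      if (length(other_ii)) Reduce(`+`, lapply(other_ii, function(p)
        bump(p[1], p[2], p[3]))) else 0
    v1w <- Reduce(`+`, lapply(v1, function(p) bump(p[1], p[2], p[3])))
    sup <- range(which(abs(qrs_wave) > 0.05 * max(abs(qrs_wave))))
    # the annotated R wave is the Lead II maximum within the QRS support —
    # the same point the marker-based R search converges to at test time
    r_off <- (sup[1]:sup[2])[which.max(ii[sup[1]:sup[2]])]
    list(label = label, lead_ii = ii, v1 = v1w, r_offset = r_off,
         qrs_support = sup)
  }

  n <- mk("N",
          qrs_ii = list(c(-0.10, -0.028, 0.008), c(1.00, 0, 0.010),
                        c(-0.20, 0.030, 0.009)),
          other_ii = list(c(0.12, -0.18, 0.025), c(0.30, 0.20, 0.045)),
          v1 = list(c(0.15, -0.012, 0.009), c(-0.60, 0.012, 0.013),
                    c(0.10, 0.20, 0.045)))
  v <- mk("V",
          qrs_ii = list(c(0.30, -0.022, 0.009), c(-1.05, 0.012, 0.020)),
          other_ii = list(c(0.40, 0.16, 0.050)),
          v1 = list(c(0.90, 0.005, 0.028), c(-0.30, 0.17, 0.050)))
  l <- mk("L",
          qrs_ii = list(c(0.85, -0.020, 0.012), c(0.90, 0.020, 0.012),
                        c(-0.30, 0.055, 0.012)),
          other_ii = list(c(0.10, -0.18, 0.025), c(-0.12, 0.20, 0.045)),
          v1 = list(c(-0.85, 0.005, 0.028), c(0.20, 0.19, 0.045)))
  r <- mk("R",
          qrs_ii = list(c(0.80, 0, 0.010), c(-0.50, 0.042, 0.022)),
          other_ii = list(c(0.10, -0.18, 0.025), c(0.25, 0.21, 0.045)),
          v1 = list(c(0.30, -0.032, 0.009), c(-0.35, -0.002, 0.009),
                    c(0.90, 0.030, 0.014), c(-0.15, 0.21, 0.045)))
  a <- n; a$label <- "A"
  list(N = n, V = v, L = l, R = r, A = a)
}

#' Simulation configuration
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Record length in seconds.
#' @param mean_hr_bpm Mean heart rate (beats per minute).
#' @param rr_jitter_fraction Gaussian RR jitter as a fraction of the nominal
#'   RR interval (0 = metronomic).
#' @param beat_mix Named proportions over `c(N, V, L, R, A)`; must be
#'   non-negative and sum to 1.
#' @param pac_prematurity PAC beats are placed at this fraction of the
#'   nominal RR interval (default 0.7, comfortably below the classifier's
#'   0.85 prematurity threshold).
#' @param powerline_hz,powerline_amp Powerline interference frequency (Hz)
#'   and amplitude (mV).
#' @param baseline_hz,baseline_amp Sinusoidal baseline-wander frequency (Hz,
#'   below 0.5) and amplitude (mV).
#' @param white_sd Broadband Gaussian noise standard deviation (mV).
#' @param spike_artifact_rate Expected spike artifacts per minute (applied by
#'   [inject_artifacts()] when `> 0`).
#' @param seed Integer seed; a fixed seed makes [simulate_ecg()] output
#'   byte-identical.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(fs = 360, duration_s = 120, mean_hr_bpm = 72,
                       rr_jitter_fraction = 0.04,
                       beat_mix = c(N = 1, V = 0, L = 0, R = 0, A = 0),
                       pac_prematurity = 0.7,
                       powerline_hz = 60, powerline_amp = 0,
                       baseline_hz = 0.25, baseline_amp = 0,
                       white_sd = 0, spike_artifact_rate = 0, seed = 1L) {
  beat_mix <- beat_mix[c("N", "V", "L", "R", "A")]
  beat_mix[is.na(beat_mix)] <- 0
  names(beat_mix) <- c("N", "V", "L", "R", "A")
  if (any(beat_mix < 0) || abs(sum(beat_mix) - 1) > 1e-9)
    stop("beat_mix proportions must be >= 0 and sum to 1")
  stopifnot(fs > 0, duration_s > 0, mean_hr_bpm > 0,
            rr_jitter_fraction >= 0, spike_artifact_rate >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an annotated two-lead ECG record
#'
#' Places beats at jittered RR intervals (PAC beats prematurely at
#' `pac_prematurity` times the nominal RR), sums the morphology templates of
#' [beat_templates()] onto the two leads, then adds powerline, baseline-wander
#' and broadband noise. Every beat carries an exact R-index annotation.
#'
#' @param config A [sim_config()].
#' @return An [ecg_record()] with a full annotation table.
#' @export
simulate_ecg <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration_s * fs)
  tpl <- beat_templates(fs)
  rr_nom <- 60 / config$mean_hr_bpm * fs          # samples
  margin <- length(tpl$N$lead_ii)                  # keep templates in bounds

  # draw labels and RR gaps
  r_idx <- integer(0); labels <- character(0)
  pos <- margin %/% 2 + 1
  repeat {
    lab <- sample(names(config$beat_mix), 1, prob = config$beat_mix)
    gap <- rr_nom * (if (lab == "A") config$pac_prematurity else 1)
    if (config$rr_jitter_fraction > 0 && lab != "A")
      gap <- gap + stats::rnorm(1, 0, config$rr_jitter_fraction * rr_nom)
    pos <- if (length(r_idx)) r_idx[length(r_idx)] + round(gap) else pos
    if (pos + margin %/% 2 > n - 1) break
    r_idx <- c(r_idx, pos); labels <- c(labels, lab)
  }
  if (!length(r_idx)) stop("record too short for a single beat at this HR")

  ii <- numeric(n); v1 <- numeric(n)
  for (b in seq_along(r_idx)) {
    tp <- tpl[[labels[b]]]
    idx <- r_idx[b] + seq_along(tp$lead_ii) - tp$r_offset
    keep <- idx >= 1 & idx <= n
    ii[idx[keep]] <- ii[idx[keep]] + tp$lead_ii[keep]
    v1[idx[keep]] <- v1[idx[keep]] + tp$v1[keep]
  }

  tt <- (seq_len(n) - 1) / fs
  if (config$powerline_amp > 0) {
    pl <- config$powerline_amp * sin(2 * pi * config$powerline_hz * tt)
    ii <- ii + pl; v1 <- v1 + pl
  }
  if (config$baseline_amp > 0) {
    bw <- config$baseline_amp * sin(2 * pi * config$baseline_hz * tt)
    ii <- ii + bw; v1 <- v1 + 0.6 * bw
  }
  if (config$white_sd > 0) {
    ii <- ii + stats::rnorm(n, 0, config$white_sd)
    v1 <- v1 + stats::rnorm(n, 0, config$white_sd)
  }

  ecg_record(ii, v1, fs = fs,
             record_id = sprintf("sim-seed%d", config$seed),
             annotations = data.frame(r_index = r_idx, label = labels))
}

#' Inject non-physiological spike artifacts
#'
#' Adds sharp biphasic spikes (total width < 10 samples) at random positions
#' kept away from true QRS supports, emulating electrode pops and motion
#' transients that produce false QRS markers.
#'
#' @param record An annotated [ecg_record()].
#' @param rate Expected artifacts per minute.
#' @param seed Integer seed.
#' @param amplitude Spike amplitude in mV.
#' @return A list with `record` (spiked copy) and `spike_indices` (centers).
#' @export
inject_artifacts <- function(record, rate, seed = 1L, amplitude = 1.2) {
  stopifnot(inherits(record, "ecg_record"), rate >= 0)
  if (rate == 0)
    return(list(record = record, spike_indices = integer(0)))
  set.seed(seed)
  n <- length(record$lead_ii)
  n_spikes <- max(0L, stats::rpois(1, rate * n / record$fs / 60))
  if (n_spikes == 0L)
    return(list(record = record, spike_indices = integer(0)))
  guard <- round(0.15 * record$fs)
  ok <- rep(TRUE, n)
  ok[seq_len(min(n, 20L))] <- FALSE
  ok[seq.int(max(1L, n - 20L), n)] <- FALSE
  if (!is.null(record$annotations)) {
    for (r in record$annotations$r_index)
      ok[max(1, r - guard):min(n, r + guard)] <- FALSE
  }
  centers <- sort(sample(which(ok), min(n_spikes, sum(ok))))
  # biphasic: +amp at c-1..c, -amp at c+1..c+2  (width 4 < 10 samples)
  shape <- c(0.5, 1, -1, -0.5) * amplitude
  ii <- record$lead_ii; v1 <- record$lead_v1
  for (cc in centers) {
    idx <- cc + (-1:2)
    ii[idx] <- ii[idx] + shape
    v1[idx] <- v1[idx] + 0.7 * shape
  }
  rec <- ecg_record(ii, v1, fs = record$fs,
                    record_id = paste0(record$record_id, "+spikes"),
                    annotations = record$annotations)
  list(record = rec, spike_indices = centers)
}
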