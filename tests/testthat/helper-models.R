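# Shared synthetic records and trained models, built once per test run.
# Training sizes are kept small (a 150 s mixed-rhythm record, 24 detector
# beats, 20 classifier beats per class, 20 SoNFIN epochs): the synthetic
# morphologies are clean enough that the pipeline saturates quickly.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

mixed_beat_mix <- c(N = 0.55, V = 0.2, L = 0.15, R = 0.1, A = 0)

noisy_sim_config <- function(duration_s, seed, mix = mixed_beat_mix,
                             mean_hr_bpm = 75) {
  sim_config(duration_s = duration_s, mean_hr_bpm = mean_hr_bpm,
             beat_mix = mix, powerline_amp = 0.05, baseline_amp = 0.15,
             white_sd = 0.02, seed = seed)
}

train_record <- function() memo("train_record",
  simulate_ecg(noisy_sim_config(150, seed = 7)))

clean_record <- function() memo("clean_record",
  simulate_ecg(sim_config(duration_s = 60, mean_hr_bpm = 72,
                          rr_jitter_fraction = 0.03,
                          beat_mix = mixed_beat_mix, seed = 11)))

test_pipeline_config <- function() {
  pipeline_config(per_type_beats = c(N = 10, V = 6, R = 4, L = 4),
                  sonfin = sonfin_config(iterations = 20))
}

trained_models <- function() memo("models", {
  train_pipeline(train_record(), train_record(), test_pipeline_config(),
                 beats_per_class = 20)
})

# small random helpers for property-style tests
random_sonfin <- function(p, n, K = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- sonfin(n, K, class_labels = paste0("c", seq_len(K)))
  for (j in seq_len(p)) {
    m <- maybe_add_rule(m, stats::runif(n, -1, 1), H = 0.999,
                        sigma0 = stats::runif(1, 0.3, 1.2))$model
  }
  p_got <- nrow(m$centers)   # a draw landing on an existing center adds none
  m$widths <- matrix(stats::runif(p_got * n, 0.2, 1.5), p_got, n)
  m$weights <- array(stats::rnorm((n + 1) * p_got * K), c(n + 1, p_got, K))
  m
}
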