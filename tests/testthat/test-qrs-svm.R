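pure_record <- function(label, duration_s = 40, seed = 21) {
  mix <- c(N = 0, V = 0, L = 0, R = 0, A = 0)
  mix[label] <- 1
  simulate_ecg(sim_config(duration_s = duration_s, mean_hr_bpm = 70,
                          rr_jitter_fraction = 0.02, beat_mix = mix,
                          seed = seed))
}

test_that("training-set construction yields one labeled cycle per selected beat", {
  recs <- list(pure_record("N", 40), pure_record("V", 30, seed = 22),
               pure_record("R", 15, seed = 23), pure_record("L", 15, seed = 24))
  ts <- build_training_set(recs, per_type_beats = c(N = 27, V = 18, R = 4, L = 4))
  expect_identical(attr(ts, "n_cycles"), 53L)
  expect_setequal(unique(ts$label), c(1, -1))
  expect_true(all(ts$raw >= -1 & ts$raw <= 1))
  expect_true(all(ts$diff >= -1 & ts$diff <= 1))

  empty <- build_training_set(list())
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "n_cycles"), 0L)

  # the +/-40 ms labeling window marks exactly 29 samples at 360 Hz
  one <- build_training_set(recs[[1]], per_type_beats = c(N = 1))
  expect_identical(sum(one$label == 1), 2L * 14L + 1L)

  no_ann <- ecg_record(rnorm(500), rnorm(500))
  expect_error(build_training_set(no_ann, c(N = 1)), "annotations")
})

test_that("the RBF SVM separates standard toy sets", {
  pair <- data.frame(raw = c(-1, 1), diff = c(-1, 1), label = c(-1, 1))
  m <- train_detector(pair)
  expect_identical(mark_samples(m, c(-1, 1), c(-1, 1)), c(-1L, 1L))
  # margin boundary between the two points: origin is near the boundary
  expect_lt(abs(decision_values(m, 0, 0)),
            abs(decision_values(m, 1, 1)))

  xor <- data.frame(raw = c(-1, -1, 1, 1), diff = c(-1, 1, -1, 1),
                    label = c(-1, 1, 1, -1))
  mx <- train_detector(xor, gamma = 2.5, cost = 200)
  expect_identical(mark_samples(mx, xor$raw, xor$diff), as.integer(xor$label))

  expect_error(train_detector(data.frame(raw = 1:3, diff = 1:3,
                                         label = c(1, 1, 1))), "labels")
})

test_that("SVM training error is no worse than the best axis-aligned threshold", {
  set.seed(31)
  n <- 150
  feats <- data.frame(
    raw = c(rnorm(n, 0.1, 0.3), rnorm(n, 0.5, 0.3)),
    diff = c(rnorm(n, -0.1, 0.15), rnorm(n, 0.45, 0.2)),
    label = rep(c(-1, 1), each = n))
  m <- train_detector(feats, gamma = 2.5, cost = 200)
  pred <- mark_samples(m, feats$raw, feats$diff)
  svm_err <- mean(pred != feats$label)
  # exhaustive threshold-scan oracle on the diff coordinate
  cuts <- sort(unique(feats$diff))
  thr_err <- min(vapply(cuts, function(cut) {
    min(mean((feats$diff > cut) != (feats$label == 1)),
        mean((feats$diff <= cut) != (feats$label == 1)))
  }, numeric(1)))
  expect_lte(svm_err, thr_err)
})

test_that("unbounded support vectors sit on the margin (KKT)", {
  set.seed(32)
  feats <- data.frame(raw = c(rnorm(40, -0.5, 0.2), rnorm(40, 0.5, 0.2)),
                      diff = c(rnorm(40, -0.5, 0.2), rnorm(40, 0.5, 0.2)),
                      label = rep(c(-1, 1), each = 40))
  m <- train_detector(feats, gamma = 2.5, cost = 200)
  f_sv <- decision_values(m, m$sv[, 1], m$sv[, 2])
  free <- abs(m$coefs) < m$cost - 1e-6
  expect_true(any(free))
  expect_lt(max(abs(abs(f_sv[free]) - 1)), 1e-3)
})

test_that("our decision function agrees with an independent RBF-SVM solver", {
  set.seed(33)
  feats <- data.frame(raw = c(rnorm(60, -0.4, 0.25), rnorm(60, 0.4, 0.25)),
                      diff = c(rnorm(60, -0.3, 0.25), rnorm(60, 0.3, 0.25)),
                      label = rep(c(-1, 1), each = 60))
  m <- train_detector(feats, gamma = 2.5, cost = 200)
  k <- kernlab::ksvm(as.matrix(feats[, 1:2]), factor(feats$label),
                     kernel = "rbfdot", kpar = list(sigma = 2.5), C = 200,
                     scaled = FALSE)
  grid <- expand.grid(raw = seq(-1, 1, 0.25), diff = seq(-1, 1, 0.25))
  ours <- sign(decision_values(m, grid$raw, grid$diff))
  theirs <- as.numeric(as.character(kernlab::predict(k, as.matrix(grid))))
  expect_gt(mean(ours == theirs), 0.97)
})

test_that("run-length encoding of decisions round-trips markers", {
  mk <- markers_from_decisions(c(-1, 1, 1, -1))
  expect_identical(mk$start, 2L)
  expect_identical(mk$end, 3L)
  expect_identical(mk$width, 2L)
  expect_identical(nrow(markers_from_decisions(rep(-1, 6))), 0L)
  mk2 <- markers_from_decisions(c(1, -1, 1))
  expect_identical(mk2$start, c(1L, 3L))
  expect_identical(mk2$end, c(1L, 3L))
  expect_error(markers_from_decisions(c(1, 0, -1)), "\\+1/-1")
})

test_that("marker post-processing merges near neighbors then deletes slivers", {
  # widths 6 and 12 with a 2-sample gap: merged into one 20-wide marker
  mk <- data.frame(start = c(101L, 109L), end = c(106L, 120L))
  out <- postprocess_markers(mk)
  expect_identical(out$start, 101L)
  expect_identical(out$end, 120L)

  # isolated width-8 marker deleted
  out2 <- postprocess_markers(data.frame(start = 51L, end = 58L))
  expect_identical(nrow(out2), 0L)

  empty <- data.frame(start = integer(0), end = integer(0))
  expect_identical(nrow(postprocess_markers(empty)), 0L)

  # idempotent, never grows the marker count, and enforces the invariants
  set.seed(41)
  for (i in 1:50) {
    starts <- sort(sample.int(400, 12))
    widths <- sample.int(20, 12, replace = TRUE)
    ends <- starts + widths - 1L
    keep <- c(TRUE, starts[-1] > ends[-12])   # drop overlaps
    mk <- data.frame(start = starts[keep], end = ends[keep])
    out <- postprocess_markers(mk)
    expect_lte(nrow(out), nrow(mk))
    expect_identical(postprocess_markers(out), out)
    if (nrow(out)) {
      expect_true(all(out$width >= 10))
      if (nrow(out) > 1)
        expect_true(all(out$start[-1] - out$end[-nrow(out)] - 1 >= 5))
    }
  }
})

test_that("detection marks every beat of a clean simulated record", {
  rec <- clean_record()   # >= 50 beats, no noise
  det <- detect_markers(trained_models()$detector, rec)
  sc <- score_detection(rec$annotations$r_index, det$markers, fs = rec$fs)
  expect_gte(nrow(rec$annotations), 50)
  expect_identical(sc$fn, 0L)            # sensitivity 100%
  expect_identical(sc$fp, 0L)            # FP ratio 0%
})

test_that("detector models serialize losslessly to JSON", {
  m <- trained_models()$detector
  path <- tempfile(fileext = ".json")
  write_detector(m, path)
  m2 <- read_detector(path)
  expect_equal(m2$sv, m$sv, tolerance = 1e-12)
  expect_equal(m2$coefs, m$coefs, tolerance = 1e-12)
  expect_equal(m2$b, m$b, tolerance = 1e-12)
  x <- seq(-1, 1, 0.1)
  expect_equal(decision_values(m2, x, rev(x)), decision_values(m, x, rev(x)),
               tolerance = 1e-9)
})
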