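test_that("detection scoring matches hand-built cases", {
  true_r <- c(100L, 400L, 700L, 1000L, 1300L)
  perfect <- data.frame(start = true_r - 10L, end = true_r + 10L)
  sc <- score_detection(true_r, perfect)
  expect_identical(c(sc$tp, sc$fn, sc$fp), c(5L, 0L, 0L))

  none <- data.frame(start = integer(0), end = integer(0))
  sc0 <- score_detection(rep(1:10) * 300L, none)
  expect_identical(c(sc0$tp, sc0$fn, sc0$fp), c(0L, 10L, 0L))

  # one spurious marker far from any beat, one beat with no marker
  mk <- data.frame(start = c(90L, 390L, 690L, 1290L, 2000L),
                   end = c(110L, 410L, 710L, 1310L, 2020L))
  sc1 <- score_detection(true_r, mk)
  expect_identical(c(sc1$tp, sc1$fn, sc1$fp), c(4L, 1L, 1L))
  expect_identical(sc1$tn, 0L)
})

test_that("FN/FP ratios reproduce the reference detection totals", {
  det <- reference_counts("detection")
  tot <- list(tp = sum(det$tp), fn = sum(det$fn), fp = sum(det$fp))
  expect_identical(c(tot$tp, tot$fn, tot$fp), c(12754L, 22L, 572L))
  r <- fn_fp_ratios(tot)
  expect_identical(round_half_up(unname(r), 2), c(0.17, 4.48))

  expect_identical(unname(fn_fp_ratios(list(tp = 50, fn = 0, fp = 0))),
                   c(0, 0))
  expect_equal(unname(fn_fp_ratios(list(tp = 99, fn = 1, fp = 10))),
               c(1, 10))
  expect_error(fn_fp_ratios(list(tp = 0, fn = 0, fp = 3)), "no true beats")
})

test_that("one-vs-rest confusion counts agree with direct enumeration", {
  t1 <- c("N", "V", "N", "L")
  expect_identical(
    unlist(confusion_one_vs_rest(t1, t1, "N")[c("fn", "fp")]),
    c(fn = 0L, fp = 0L))

  allN <- rep("N", 7); allV <- rep("V", 7)
  ct <- confusion_one_vs_rest(allN, allV, "N")
  expect_identical(c(ct$tp, ct$fn, ct$fp, ct$tn), c(0L, 7L, 0L, 0L))

  truth <- c("N", "N", "V", "L", "V", "N")
  pred  <- c("N", "V", "V", "V", "L", "N")
  ct2 <- confusion_one_vs_rest(truth, pred, "V")
  # enumeration oracle
  tp <- sum(truth == "V" & pred == "V"); fn <- sum(truth == "V" & pred != "V")
  fp <- sum(truth != "V" & pred == "V"); tn <- sum(truth != "V" & pred != "V")
  expect_identical(c(ct2$tp, ct2$fn, ct2$fp, ct2$tn), c(tp, fn, fp, tn))
  expect_error(confusion_one_vs_rest(truth, pred[-1], "V"), "length")
})

test_that("sensitivity/specificity/accuracy reproduce the reference per-class rows", {
  cm <- reference_counts("confusion_matched")
  stat_n <- sens_spec_acc(as.list(cm[cm$class == "N", ]))
  expect_identical(round_half_up(unname(stat_n["sensitivity"])), 98.8)
  stat_v <- sens_spec_acc(as.list(cm[cm$class == "V", ]))
  expect_identical(round_half_up(unname(stat_v["sensitivity"])), 95.1)
  expect_identical(round_half_up(unname(stat_v["specificity"])), 99.4)

  expect_equal(unname(sens_spec_acc(list(tp = 50, fn = 0, fp = 0, tn = 50))),
               c(100, 100, 100))
  expect_true(is.nan(sens_spec_acc(list(tp = 0, fn = 0, fp = 1,
                                        tn = 1))["sensitivity"]))
})

test_that("metric invariants hold on random label sets", {
  set.seed(81)
  classes <- c("N", "V", "L", "R")
  for (i in 1:20) {
    truth <- sample(classes, 60, replace = TRUE)
    pred <- sample(classes, 60, replace = TRUE)
    rep <- classification_report(truth, pred, classes)
    # sum of one-vs-rest TPs equals total correct decisions
    expect_identical(sum(rep$tp), sum(truth == pred))
    stats <- unlist(rep[c("sensitivity", "specificity", "accuracy")])
    stats <- stats[!is.nan(stats)]
    expect_true(all(stats >= 0 & stats <= 100))
  }
})

test_that("per-record detection fixture rows are internally consistent", {
  det <- reference_counts("detection")
  beats <- reference_counts("beats")
  expect_identical(nrow(det), 33L)
  expect_identical(nrow(beats), 33L)
  # tp + fn per record equals that record's annotated beat total
  totals <- rowSums(beats[, c("N", "V", "R", "L", "A")])
  expect_identical(as.integer(det$tp + det$fn), as.integer(totals))
  expect_identical(as.integer(sum(totals)), 12776L)
})
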