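test_that("Gaussian membership takes its textbook values", {
  expect_identical(membership(0.3, 0.3, 0.5), 1)
  expect_equal(membership(1.5, 1, 0.5), exp(-1))
  expect_equal(membership(2, 1, 0.5), exp(-4))
  expect_error(membership(0, 0, 0), "sigma")
})

test_that("firing strength is the product of per-input memberships", {
  m <- sonfin(2, 2, c("a", "b"))
  m <- maybe_add_rule(m, c(0.1, -0.2), sigma0 = 0.5)$model
  expect_equal(firing_strengths(m, c(0.1, -0.2)), 1)
  expect_equal(firing_strengths(m, c(0.6, 0.3)), exp(-2))  # both one width off

  m3 <- random_sonfin(3, 4, seed = 51)
  x <- runif(4, -1, 1)
  # scalar loop oracle
  oracle <- vapply(1:3, function(j) {
    prod(vapply(1:4, function(i)
      membership(x[i], m3$centers[j, i], m3$widths[j, i]), numeric(1)))
  }, numeric(1))
  expect_equal(firing_strengths(m3, x), oracle, tolerance = 1e-12)
  expect_error(firing_strengths(m3, c(1, 2)), "length")
})

test_that("the defuzzifier reduces to known closed forms", {
  # single rule: output equals the consequent, whatever the firing strength
  m <- sonfin(2, 3, c("a", "b", "c"))
  m <- maybe_add_rule(m, c(5, 5), sigma0 = 0.3)$model  # fires ~0 elsewhere
  m$weights[, 1, 1] <- c(1, 2, 3)    # w0 + 2 x1 + 3 x2
  m$weights[, 1, 2] <- c(-1, 0, 0)
  x <- c(0.4, -0.2)
  o <- sonfin_forward(m, x)
  expect_equal(unname(o), c(1 + 2 * 0.4 + 3 * -0.2, -1, 0), tolerance = 1e-12)

  # two rules with equal firing strengths: arithmetic mean of consequents
  m2 <- sonfin(1, 1, "y")
  m2 <- maybe_add_rule(m2, -1, sigma0 = 1)$model
  m2 <- maybe_add_rule(m2, 1, sigma0 = 1)$model
  m2$weights[1, , 1] <- c(4, 10)     # constant consequents 4 and 10
  expect_equal(unname(sonfin_forward(m2, 0)), 7, tolerance = 1e-12)

  # 3-rule, 2-input hand-set model vs a manual weighted average
  m3 <- random_sonfin(3, 2, K = 2, seed = 52)
  x <- c(0.3, -0.6)
  u <- firing_strengths(m3, x)
  z <- sapply(1:2, function(k) vapply(1:3, function(j)
    m3$weights[1, j, k] + sum(m3$weights[-1, j, k] * x), numeric(1)))
  expect_equal(unname(sonfin_forward(m3, x)),
               as.numeric(crossprod(z, u) / sum(u)), tolerance = 1e-9)
})

test_that("structure learning creates rules exactly when nothing fires above H", {
  m <- sonfin(2, 2, c("a", "b"))
  st <- maybe_add_rule(m, c(0.3, -0.3), H = 0.1, sigma0 = 0.6)
  expect_true(st$added)                      # empty model always grows
  expect_equal(st$model$centers[1, ], c(0.3, -0.3))
  expect_true(all(st$model$widths == 0.6))
  expect_true(all(st$model$weights == 0))
  # the triggering sample now fires at exactly 1
  expect_equal(max(firing_strengths(st$model, c(0.3, -0.3))), 1)

  # same point again: strength 1 >= H, no growth
  st2 <- maybe_add_rule(st$model, c(0.3, -0.3), H = 0.1, sigma0 = 0.6)
  expect_false(st2$added)

  # far point: all strengths below H (verified by the strength oracle)
  far <- c(3, 3)
  expect_lt(max(firing_strengths(st$model, far)), 0.1)
  expect_true(maybe_add_rule(st$model, far, H = 0.1, sigma0 = 0.6)$added)
})

test_that("RLS consequent updates recover a generating linear rule", {
  set.seed(53)
  m <- sonfin(3, 2, c("a", "b"))
  m <- maybe_add_rule(m, c(0, 0, 0), sigma0 = 2)$model
  rls <- rls_state(m, p0 = 1e8)
  xs <- matrix(runif(50 * 3, -1, 1), 50)
  truth <- list(c(0.5, -1, 2, 0.25), c(-2, 0, 1, 1))
  for (s in 1:50) {
    d <- vapply(truth, function(w) w[1] + sum(w[-1] * xs[s, ]), numeric(1))
    up <- update_consequent_rls(m, rls, xs[s, ], d)
    m <- up$model; rls <- up$rls
  }
  for (k in 1:2)
    expect_equal(as.numeric(m$weights[, 1, k]), truth[[k]], tolerance = 1e-6)
  # covariance stayed symmetric positive definite
  expect_equal(rls$P, t(rls$P), tolerance = 1e-10)
  expect_true(all(eigen(rls$P, only.values = TRUE)$values > 0))
})

test_that("repeated RLS updates on one pair shrink the residual monotonically", {
  m <- random_sonfin(2, 2, K = 2, seed = 54)
  rls <- rls_state(m)
  x <- c(0.2, 0.4); d <- c(1, -1)
  res <- numeric(10)
  for (i in 1:10) {
    res[i] <- sqrt(sum((d - sonfin_forward(m, x))^2))
    up <- update_consequent_rls(m, rls, x, d)
    m <- up$model; rls <- up$rls
  }
  expect_true(all(diff(res) <= 1e-10))
})

test_that("fuzzy-set gradients match central finite differences", {
  fd_check <- function(m, x, d, h = 1e-5) {
    g <- ecgsonfin:::fuzzy_gradients(m, x, d)
    err <- function(mm) ecgsonfin:::sonfin_error(mm, x, d)
    worst <- 0
    for (j in seq_len(nrow(m$centers))) for (i in seq_len(ncol(m$centers))) {
      for (field in c("centers", "widths")) {
        mp <- m; mp[[field]][j, i] <- mp[[field]][j, i] + h
        mm <- m; mm[[field]][j, i] <- mm[[field]][j, i] - h
        fd <- (err(mp) - err(mm)) / (2 * h)
        an <- if (field == "centers") g$dm[j, i] else g$dsigma[j, i]
        denom <- max(abs(fd), abs(an), 1e-8)
        worst <- max(worst, abs(fd - an) / denom)
      }
    }
    worst
  }
  m <- random_sonfin(2, 2, K = 2, seed = 55)
  expect_lt(fd_check(m, c(0.3, -0.1), c(1, -1)), 1e-4)

  # zero error implies zero gradient: single rule tuned to hit the target
  m1 <- sonfin(1, 1, "y")
  m1 <- maybe_add_rule(m1, 0.5, sigma0 = 0.6)$model
  m1$weights[, 1, 1] <- c(2, 0)
  g <- ecgsonfin:::fuzzy_gradients(m1, 0.5, 2)   # o == d == 2
  expect_true(all(abs(g$dm) < 1e-12) && all(abs(g$dsigma) < 1e-12))
  m1b <- update_fuzzy_gd(m1, 0.5, 2)
  expect_identical(m1b$centers, m1$centers)
})

test_that("gradient descent on the fuzzy sets is a descent direction", {
  m <- random_sonfin(3, 2, K = 2, seed = 56)
  x <- c(0.1, 0.7); d <- c(1, -1)
  errs <- numeric(100)
  for (i in 1:100) {
    errs[i] <- ecgsonfin:::sonfin_error(m, x, d)
    m <- update_fuzzy_gd(m, x, d, lr = 0.002)
  }
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("training solves a well-separated 4-class problem", {
  set.seed(57)
  centers <- matrix(c(-1, -1, 1, -1, -1, 1, 1, 1), 4, 2, byrow = TRUE)
  feats <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(80, 0, 0.15), 40, 2), 2, centers[k, ], `+`)))
  labels <- rep(1:4, each = 40)
  cfg <- sonfin_config(iterations = 30)
  m <- sonfin_train(feats, labels, cfg)
  pred <- apply(predict(m, feats), 1, which.max)
  expect_identical(mean(pred == labels), 1)       # 100% within 200 epochs

  # rule count grows with H on the same data
  m_lo <- sonfin_train(feats, labels, sonfin_config(H = 0.01, iterations = 2))
  m_hi <- sonfin_train(feats, labels, sonfin_config(H = 0.99, iterations = 2))
  expect_gte(nrow(m_hi$centers), nrow(m_lo$centers))

  # rule count non-decreasing over training and bounded by sample count
  rt <- attr(m, "rule_trace")
  expect_true(all(diff(rt) >= 0))
  expect_lte(max(rt), nrow(feats))
})

test_that("a single-sample dataset is memorized by one rule", {
  m <- sonfin_train(matrix(c(0.2, -0.4), 1), 2,
                    sonfin_config(iterations = 50),
                    class_labels = c("a", "b", "c", "d"))
  expect_identical(nrow(m$centers), 1L)
  o <- sonfin_forward(m, c(0.2, -0.4))
  expect_equal(unname(o), c(-1, 1, -1, -1), tolerance = 1e-3)
})

test_that("sonfin models serialize losslessly to JSON", {
  m <- random_sonfin(3, 4, K = 4, seed = 58)
  m$class_labels <- c("N", "V", "L", "R")
  path <- tempfile(fileext = ".json")
  write_sonfin(m, path)
  m2 <- read_sonfin(path)
  x <- runif(4, -1, 1)
  expect_equal(sonfin_forward(m2, x), sonfin_forward(m, x), tolerance = 1e-12)
  expect_identical(m2$class_labels, m$class_labels)
})
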