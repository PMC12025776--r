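test_that("confusion counts tally threshold predictions", {
  c1 <- confusion_counts(c(1, 1, 0, 0), c(0.9, 0.2, 0.8, 0.1), 0.5)
  expect_equal(c1$TP, 1)
  expect_equal(c1$FN, 1)
  expect_equal(c1$FP, 1)
  expect_equal(c1$TN, 1)

  # perfect separation leaves no errors
  c2 <- confusion_counts(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1), 0.5)
  expect_equal(c2$FP + c2$FN, 0)

  set.seed(1)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    cc <- confusion_counts(rbinom(n, 1, 0.5), runif(n), runif(1, 0.1, 0.9))
    expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, n)
  }
  expect_error(confusion_counts(numeric(), numeric()), "empty")
})

test_that("threshold metrics evaluate their defining formulas", {
  m <- compute_metrics(confusion_counts(
    c(rep(1, 5), rep(0, 5)),
    c(0.9, 0.8, 0.7, 0.2, 0.1, 0.6, 0.3, 0.2, 0.1, 0.05), 0.5))
  # TP=3 FP=1 FN=2 TN=4
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 0.666667, tolerance = 1e-6)

  perfect <- compute_metrics(confusion_counts(c(1, 0), c(0.9, 0.1)))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1,
                                  recall = 1, f1 = 1))

  # degenerate denominators return 0 with a warning
  expect_warning(z <- compute_metrics(confusion_counts(c(1, 0), c(0.1, 0.9))),
                 "undefined")
  expect_equal(z$precision, 0)
  expect_equal(z$f1, 0)
})

test_that("F1 lies between precision and recall when both are positive", {
  set.seed(2)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    m <- suppressWarnings(compute_metrics(confusion_counts(y, runif(n))))
    for (v in unlist(m)) {
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
    if (m$precision > 0 && m$recall > 0) {
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
    }
  }
})

test_that("trapezoidal AUC equals the pairwise-comparison oracle", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)

  set.seed(3)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    expect_equal(roc_auc(y, s), pairwise_auc(y, s), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(4)
  y <- rbinom(40, 1, 0.5)
  y[1:2] <- c(0, 1)
  s <- runif(40)
  base <- roc_auc(y, s)
  expect_equal(roc_auc(y, exp(3 * s)), base, tolerance = 1e-12)
  expect_equal(roc_auc(y, rank(s)), base, tolerance = 1e-12)
})

test_that("ROC points are monotone and anchored at the corners", {
  set.seed(5)
  y <- rbinom(50, 1, 0.4)
  y[1:2] <- c(0, 1)
  pts <- roc_points(y, runif(50))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  y <- rbinom(80, 1, 0.5)
  y[1:2] <- c(0, 1)
  s <- round(runif(80), 2)
  ref <- as.numeric(suppressMessages(
    pROC::auc(y, s, levels = c(0, 1), direction = "<")))
  expect_equal(roc_auc(y, s), ref, tolerance = 1e-12)
})
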