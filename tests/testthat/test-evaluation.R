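test_that("segmentation-scale confusion counts reproduce their printed metrics", {
  m <- compute_metrics(confusion_counts(tp = 35610, fp = 7527,
                                        tn = 12932412, fn = 579))
  pct <- metrics_percent(m, digits = 2)
  expect_equal(unname(pct["recall"]), 98.40)       # sensitivity / TPR
  expect_equal(unname(pct["specificity"]), 99.94)  # TNR
  expect_equal(unname(pct["accuracy"]), 99.94)
  expect_equal(unname(pct["precision"]), 82.55)
  expect_equal(unname(pct["f1"]), 89.78)
})

test_that("classification-scale confusion counts reproduce their printed metrics", {
  m <- compute_metrics(confusion_counts(tp = 54100, fp = 1509,
                                        tn = 547099, fn = 10640))
  expect_equal(unname(metrics_percent(m, 1)["recall"]), 83.6)
  expect_equal(unname(metrics_percent(m, 1)["precision"]), 97.3)
  expect_equal(unname(metrics_percent(m, 2)["specificity"]), 99.72)
  expect_equal(unname(metrics_percent(m, 1)["accuracy"]), 98.0)
  expect_equal(unname(metrics_percent(m, 2)["f1"]), 89.91)
})

test_that("metric formulas behave at the boundaries and under scaling", {
  m <- compute_metrics(confusion_counts(1, 0, 1, 0))
  expect_true(all(unlist(m[c("accuracy", "precision", "recall",
                             "specificity", "f1")]) == 1))
  # scale invariance
  set.seed(9)
  for (i in 1:5) {
    cc <- as.integer(sample(1:500, 4))
    m1 <- compute_metrics(do.call(confusion_counts, as.list(cc)))
    m2 <- compute_metrics(do.call(confusion_counts, as.list(cc * 7L)))
    expect_equal(unlist(m1[1:5]), unlist(m2[1:5]), tolerance = 1e-12)
    # F1 harmonic-mean identity
    expect_equal(m1$f1, 2 * m1$precision * m1$recall /
                   (m1$precision + m1$recall), tolerance = 1e-12)
  }
  # zero denominators are flagged undefined, not coerced to 0
  m0 <- compute_metrics(confusion_counts(0, 0, 5, 2))
  expect_true(is.na(m0$precision))
  expect_true("precision" %in% m0$undefined)
  expect_error(confusion_counts(-1, 0, 0, 1), ">= 0")
})

test_that("score thresholding tabulates the standard 2x2 table", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.2, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0)
  cc <- confusion_from_scores(scores, labels, 0.5)
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
               c(tp = 2, fp = 1, tn = 2, fn = 1), ignore_attr = TRUE)
  cc0 <- confusion_from_scores(scores, labels, 0)
  expect_equal(cc0$tn + cc0$fn, 0)  # threshold 0: everything positive
  ccp <- confusion_from_scores(labels, labels, 0.5)
  expect_equal(ccp$fp + ccp$fn, 0)  # perfect scores
  expect_error(confusion_from_scores(numeric(0), integer(0)), "empty")
})

test_that("ROC/AUC equals the Mann-Whitney pair-counting oracle", {
  # perfectly separated
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1.0)
  # 5-point hand case with a tie, against exhaustive pair counting
  scores <- c(0.1, 0.4, 0.4, 0.8, 0.9)
  labels <- c(0, 0, 1, 1, 0)
  mw <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(roc_auc(scores, labels)$auc, mw(scores, labels),
               tolerance = 1e-12)
  # random scores and labels: oracle match plus chance-level AUC
  set.seed(14)
  s <- runif(200); y <- rbinom(200, 1, 0.5)
  expect_equal(roc_auc(s, y)$auc, mw(s, y), tolerance = 1e-12)
  expect_lt(abs(roc_auc(s, y)$auc - 0.5), 0.1)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(qlogis(s), y)$auc, roc_auc(s, y)$auc,
               tolerance = 1e-12)
  expect_error(roc_auc(s, rep(1, 200)), "both classes")
})

test_that("ROC agrees with the pROC reference implementation", {
  set.seed(15)
  s <- rnorm(150) + rep(c(0, 1), 75)
  y <- rep(c(0, 1), 75)
  ours <- roc_auc(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("pearson_r matches the covariance-formula oracle", {
  expect_equal(pearson_r(2 * (1:5), 1:5), 1.0)
  expect_equal(pearson_r(-(1:5), 1:5), -1.0)
  x <- c(1, 3, 4, 8); y <- c(2, 3, 7, 9)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), oracle, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), 1:3), "variance")
  expect_error(pearson_r(1:2, 1:2), "3 pairs")
})
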