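test_that("kappa matches hand arithmetic and its limiting cases", {
  expect_equal(kappa_statistic(diag(c(10, 10, 10))), 1.0)
  expect_equal(kappa_statistic(matrix(c(25, 25, 25, 25), 2)), 0.0)

  # hand computation: p0 = 85/100, pe = (50*45 + 50*55)/100^2 = 0.5
  cm <- matrix(c(40, 5, 10, 45), 2)   # rows truth, cols pred
  expect_equal(kappa_statistic(cm), (0.85 - 0.5) / (1 - 0.5))

  expect_warning(k <- kappa_statistic(matrix(c(10, 0, 0, 0), 2)),
                 "undefined")
  expect_true(is.na(k))

  # invariance under simultaneous row/column permutation
  set.seed(42)
  for (i in 1:20) {
    m <- matrix(rpois(16, 8), 4)
    p <- sample(4)
    expect_equal(kappa_statistic(m), kappa_statistic(m[p, p]))
  }
})

test_that("binary rates follow the textbook formulas", {
  r <- binary_rates(tp = 29, tn = 107, fp = 0, fn = 0)
  expect_equal(r$accuracy, 1.0)
  expect_equal(r$sensitivity, 1.0)
  expect_equal(r$specificity, 1.0)
  expect_equal(r$f1, 1.0)

  r2 <- binary_rates(tp = 0, tn = 107, fp = 0, fn = 29)
  expect_equal(r2$sensitivity, 0.0)
  expect_equal(r2$specificity, 1.0)
  expect_true(is.na(r2$precision))

  r3 <- binary_rates(tp = 20, fp = 10, fn = 9, tn = 97)
  prec <- 20 / 30; sens <- 20 / 29
  expect_equal(r3$f1, 2 * prec * sens / (prec + sens))

  # accuracy decomposition identity over random matrices
  set.seed(7)
  for (i in 1:1000) {
    counts <- rpois(4, 20) + c(1, 1, 1, 1)
    tp <- counts[1]; tn <- counts[2]; fp <- counts[3]; fn <- counts[4]
    r <- binary_rates(tp = tp, tn = tn, fp = fp, fn = fn)
    P <- tp + fn; N <- tn + fp
    expect_equal(r$accuracy, (r$sensitivity * P + r$specificity * N) / (P + N))
  }
})

test_that("AUC equals the brute-force rank statistic and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.6, 0.4), c(1, 0, 1))$auc,
               brute_auc(c(0.9, 0.6, 0.4), c(1, 0, 1)))

  set.seed(11)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))[sample(n)]
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, labels))
  }
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- runif(60); labels <- rbinom(60, 1, 0.4)
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("bootstrap AUC interval is valid, deterministic and shrinks with n", {
  # perfect separation with well-populated classes: degenerate interval
  s <- c(rep(0.9, 30), rep(0.1, 30)); y <- rep(c(1, 0), each = 30)
  expect_equal(auc_ci(s, y, reps = 300, seed = 4), c(1, 1))

  set.seed(9)
  s2 <- c(rnorm(40, 1), rnorm(40)); y2 <- rep(c(1, 0), each = 40)
  ci <- auc_ci(s2, y2, reps = 2000, seed = 5)
  a <- roc_auc(s2, y2)$auc
  expect_true(ci[1] <= a && a <= ci[2])
  expect_equal(ci, auc_ci(s2, y2, reps = 2000, seed = 5))  # deterministic

  width <- sapply(c(50, 500), function(n) {
    set.seed(21)
    sc <- c(rnorm(n, 0.8), rnorm(n)); yy <- rep(c(1, 0), each = n)
    diff(auc_ci(sc, yy, reps = 500, seed = 6))
  })
  expect_lt(width[2], width[1])
})

test_that("specificity at full recall matches the exhaustive threshold oracle", {
  expect_equal(specificity_at_full_recall(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(specificity_at_full_recall(rep(0.3, 8), rep(c(1, 0), 4)), 0.0)
  s <- c(0.9, 0.8, 0.3, 0.2); y <- c(1, 0, 1, 0)
  expect_equal(specificity_at_full_recall(s, y), brute_spec_full_recall(s, y))

  set.seed(13)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    sc <- round(runif(n), 2)
    yy <- c(0, 1, rbinom(n - 2, 1, 0.5))[sample(n)]
    expect_equal(specificity_at_full_recall(sc, yy),
                 brute_spec_full_recall(sc, yy))
  }
})

test_that("confusion_matrix respects the fixed label order", {
  cm <- confusion_matrix(c(0, 1, 2, 2), c(0, 2, 2, 1), labels = 0:4)
  expect_equal(dim(cm), c(5, 5))
  expect_equal(cm["2", "2"], 1L)
  expect_equal(sum(cm), 4L)
  expect_error(confusion_matrix(c(0, 9), c(0, 0), labels = 0:4))
})
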