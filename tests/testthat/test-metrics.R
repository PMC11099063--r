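test_that("confusion metrics reproduce the breast-cancer row rates", {
  # row-normalized rates 0.87/0.13 and 0.61/0.39 realized as counts
  truth <- c(rep("MDA-MB-231", 100), rep("MCF-7", 100))
  pred <- c(rep("MDA-MB-231", 87), rep("MCF-7", 13),
            rep("MDA-MB-231", 61), rep("MCF-7", 39))
  rep_ <- evaluate(pred, truth)
  expect_equal(unname(rep_$recall["MDA-MB-231"]), 0.87)
  expect_equal(unname(rep_$recall["MCF-7"]), 0.39)
  rates <- confusion_rates(rep_$confusion)
  expect_equal(unname(rates["MDA-MB-231", ]), c(0.13, 0.87),
               tolerance = 1e-12)
  expect_equal(unname(rates["MCF-7", ]), c(0.39, 0.61), tolerance = 1e-12)
  expect_equal(rep_$accuracy, (87 + 39) / 200)
})

test_that("metric identities hold on random confusion inputs", {
  set.seed(71)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    classes <- letters[1:k]
    n <- 200
    truth <- sample(classes, n, TRUE)
    pred <- ifelse(runif(n) < 0.6, truth, sample(classes, n, TRUE))
    r <- evaluate(pred, truth, levels = classes)
    cm <- r$confusion
    # conservation: row sums are per-class test counts
    expect_equal(rowSums(cm), table(factor(truth, classes))[classes],
                 ignore_attr = TRUE)
    expect_equal(sum(cm), n)
    expect_equal(r$accuracy, sum(diag(cm)) / n)
    # hand-computed recall/precision per class
    for (cl in classes) {
      expect_equal(unname(r$recall[cl]), cm[cl, cl] / sum(cm[cl, ]))
      cs <- sum(cm[, cl])
      expect_equal(unname(r$precision[cl]),
                   if (cs > 0) cm[cl, cl] / cs else 0)
    }
    expect_equal(r$macro_recall, mean(r$recall))
  }
})

test_that("degenerate predictors give the expected corner metrics", {
  # perfect predictions
  y <- rep(c("x", "y", "z"), each = 5)
  p <- evaluate(y, y)
  expect_equal(p$accuracy, 1)
  expect_equal(unname(p$recall), rep(1, 3))
  expect_equal(p$confusion, diag(5L, 3),
               ignore_attr = TRUE)
  # all-one-class predictor on balanced two-class data
  truth <- rep(c("a", "b"), each = 10)
  pred <- rep("a", 20)
  r <- evaluate(pred, truth, levels = c("a", "b"))
  expect_equal(r$accuracy, 0.5)
  expect_equal(unname(r$recall), c(1, 0))
  expect_error(evaluate(character(0), character(0)), "empty")
})

test_that("false-negative distributions conserve per-class counts", {
  set.seed(72)
  truth <- rep(c("low", "high"), each = 50)
  ws <- c(runif(50, 100, 500), runif(50, 900, 1800))
  # misclassify the low-amplitude tail of "low"
  pred <- truth
  confused <- which(truth == "low" & ws < 250)
  pred[confused] <- "high"
  fn <- false_negative_distribution(pred, truth, ws,
                                    breaks = seq(0, 2000, by = 100))
  low <- fn$low
  expect_equal(sum(low$correct) + sum(unlist(low$false_negative)), 50)
  expect_equal(sum(unlist(low$false_negative)), length(confused))
  # false negatives concentrate in the low-WS bins (all below 300 pm)
  fn_counts <- low$false_negative$high
  expect_equal(sum(fn_counts[low$breaks[-1] > 300]), 0)
  expect_gt(sum(fn_counts[low$breaks[-1] <= 300]), 0)
  # perfect classifier: no false-negative mass anywhere
  fn2 <- false_negative_distribution(truth, truth, ws)
  expect_equal(sum(unlist(lapply(fn2, `[[`, "false_negative"))), 0)
})
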