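test_that("confusion matrices count true/predicted pairs", {
  cm <- confusion_matrix(c("A", "A", "N"), c("A", "N", "N"), c("A", "N"))
  expect_equal(unclass(cm)[, ], matrix(c(1L, 0L, 1L, 1L), 2,
               dimnames = list(true = c("A", "N"), predicted = c("A", "N"))))
  expect_equal(sum(cm), 3)

  perfect <- confusion_matrix(c("A", "N", "O"), c("A", "N", "O"),
                              c("A", "N", "O"))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_error(confusion_matrix("A", "X", c("A", "N")), "outside")
  expect_error(confusion_matrix(c("A", "A"), "A", c("A")), "equal length")
})

test_that("one-vs-rest reduction conserves totals", {
  cm <- confusion_matrix(c("A", "A", "N"), c("A", "N", "N"), c("A", "N"))
  a <- one_vs_rest_counts(cm, "A")
  expect_equal(a, list(Tp = 1, Fn = 1, Fp = 0, Tn = 1))
  for (k in 1:2) {
    cts <- one_vs_rest_counts(cm, k)
    expect_equal(cts$Tp + cts$Fn + cts$Fp + cts$Tn, sum(cm))
  }
  expect_error(one_vs_rest_counts(cm, 5), "out of range")
})

test_that("the six metrics match direct formula evaluation", {
  perfect <- class_metrics(list(Tp = 10, Fn = 0, Fp = 0, Tn = 90))
  expect_equal(unlist(perfect[c("acc", "se", "sp", "pre", "f1", "mcc")]),
               c(acc = 1, se = 1, sp = 1, pre = 1, f1 = 1, mcc = 1))

  m <- class_metrics(list(Tp = 45, Fn = 5, Fp = 10, Tn = 90))
  expect_equal(m$se, 0.9000, tolerance = 5e-4)
  expect_equal(m$sp, 0.9000, tolerance = 5e-4)
  expect_equal(m$pre, 0.8182, tolerance = 5e-4)
  expect_equal(m$f1, 0.8571, tolerance = 5e-4)
  expect_equal(m$acc, 0.9000, tolerance = 5e-4)
  expect_equal(m$mcc, 0.7826, tolerance = 5e-4)

  deg <- class_metrics(list(Tp = 0, Fn = 5, Fp = 0, Tn = 95))
  expect_equal(deg$se, 0)
  expect_equal(deg$pre, 0)
  expect_equal(deg$mcc, 0)
  expect_true(all(c("pre", "mcc") %in% deg$degenerate))
  expect_error(class_metrics(list(Tp = 0, Fn = 0, Fp = 0, Tn = 0)), "zero")
})

test_that("MCC is 1 exactly when there are no errors and both classes occur", {
  set.seed(14)
  for (i in 1:50) {
    tp <- sample(0:30, 1); fn <- sample(0:30, 1)
    fp <- sample(0:30, 1); tn <- sample(0:30, 1)
    if (tp + fn + fp + tn == 0) next
    m <- class_metrics(list(Tp = tp, Fn = fn, Fp = fp, Tn = tn))
    expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
    if (m$mcc == 1) {
      expect_true(fn == 0 && fp == 0 && tp > 0 && tn > 0)
    }
    if (fn == 0 && fp == 0 && tp > 0 && tn > 0) expect_equal(m$mcc, 1)
  }
})

test_that("macro averages are plain arithmetic means", {
  r1 <- class_metrics(list(Tp = 8, Fn = 2, Fp = 1, Tn = 9))
  r2 <- class_metrics(list(Tp = 5, Fn = 5, Fp = 3, Tn = 7))
  avg <- macro_average(list(r1, r2))
  expect_equal(avg$f1, (r1$f1 + r2$f1) / 2)
  same <- macro_average(list(r1, r1, r1))
  expect_equal(same$mcc, r1$mcc)

  set.seed(15)
  recs <- replicate(5, class_metrics(list(Tp = sample(1:20, 1),
                                          Fn = sample(1:20, 1),
                                          Fp = sample(1:20, 1),
                                          Tn = sample(1:20, 1))),
                    simplify = FALSE)
  avg5 <- macro_average(recs)
  expect_equal(avg5$se, mean(sapply(recs, `[[`, "se")))
})

test_that("ROC curves: perfect separation, symmetry, chance level", {
  truth <- c(rep(1, 5), rep(0, 5))
  perfect <- roc_points_and_auc(c(runif(5, 0.8, 1), runif(5, 0, 0.2)), truth)
  expect_equal(perfect$auc, 1)

  set.seed(16)
  scores <- runif(10)
  r1 <- roc_points_and_auc(scores, truth)
  r2 <- roc_points_and_auc(1 - scores, truth)
  expect_equal(r1$auc + r2$auc, 1)

  big_truth <- rbinom(4000, 1, 0.4)
  big_scores <- runif(4000)
  chance <- roc_points_and_auc(big_scores, big_truth)
  expect_equal(chance$auc, 0.5, tolerance = 0.05)

  expect_error(roc_points_and_auc(runif(5), rep(1, 5)), "both")
})

test_that("ROC AUC is invariant under monotone score transforms and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(17)
  truth <- rbinom(80, 1, 0.5)
  truth[1:2] <- c(0, 1)
  scores <- runif(80)
  auc1 <- roc_points_and_auc(scores, truth)$auc
  auc2 <- roc_points_and_auc(scores^3, truth)$auc
  expect_equal(auc1, auc2)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc1, ref, tolerance = 1e-10)
})

test_that("PR curves match exhaustive threshold enumeration", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  truth <- c(1, 1, 0, 1, 0, 0)
  pr <- pr_points_and_auc(scores, truth)
  # brute force: every distinct score as the decision threshold
  brute <- t(sapply(sort(unique(scores), decreasing = TRUE), function(th) {
    pred <- scores >= th
    c(precision = sum(pred & truth == 1) / sum(pred),
      recall = sum(pred & truth == 1) / sum(truth == 1))
  }))
  expect_equal(pr$points$precision, unname(brute[, "precision"]))
  expect_equal(pr$points$recall, unname(brute[, "recall"]))

  perfect <- pr_points_and_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$recall_at_precision(0.9), 1)

  # every threshold below the minimum score predicts all-positive:
  # precision equals prevalence
  all_pos <- pr_points_and_auc(rep(0.5, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(all_pos$points$precision, 0.3)
  expect_error(pr_points_and_auc(runif(4), rep(0, 4)), "no positives")
})

test_that("full reports assemble per-class rows, macro row, and AUCs", {
  set.seed(18)
  classes <- c("A", "N", "O", "~")
  true <- sample(classes, 200, replace = TRUE)
  scores <- matrix(runif(800), ncol = 4, dimnames = list(NULL, classes))
  scores[cbind(seq_len(200), match(true, classes))] <- runif(200, 0.5, 1.5)
  scores <- scores / rowSums(scores)
  pred <- classes[max.col(scores, ties.method = "first")]
  rep_ <- metrics_report(true, pred, scores, classes)
  df <- as.data.frame(rep_)
  expect_equal(nrow(df), 5)
  expect_equal(df$class, c(classes, "macro"))
  expect_equal(df$f1[5], mean(df$f1[1:4]))
  expect_true(all(df$auc_roc >= 0 & df$auc_roc <= 1))
  expect_equal(sum(rep_$confusion), 200)
})
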