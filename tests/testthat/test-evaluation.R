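test_that("confusion counting follows the threshold-ties-positive rule", {
  cm <- confusion(c(0.9, 0.4, 0.5, 0.2), c("COPD", "COPD", "non-COPD",
                                           "non-COPD"))
  expect_equal(unclass(cm)[c("tp", "fn", "fp", "tn")],
               list(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  all_pos <- confusion(rep(1, 596), rep(c("COPD", "non-COPD"), c(204, 392)))
  expect_equal(all_pos$tp, 204)
  expect_equal(all_pos$fp, 392)
  expect_error(confusion(numeric(0), character(0)), "no predictions")
  expect_error(confusion(0.5, "copd"), "labels")
})

test_that("metrics reproduce hand arithmetic and degenerate conventions", {
  m <- eval_metrics(confusion_counts(tp = 180, fn = 24, fp = 40, tn = 352))
  expect_equal(unname(m["accuracy"]), 532 / 596, tolerance = 1e-12)
  expect_equal(round(100 * unname(m["accuracy"]), 1), 89.3)
  expect_equal(unname(m["sensitivity"]), 180 / 204, tolerance = 1e-12)
  expect_equal(unname(m["specificity"]), 352 / 392, tolerance = 1e-12)
  expect_equal(unname(m["precision"]), 180 / 220, tolerance = 1e-12)
  expect_equal(unname(m["f1"]),
               2 * (180 / 220) * (180 / 204) / (180 / 220 + 180 / 204),
               tolerance = 1e-12)
  # scale invariance
  m10 <- eval_metrics(confusion_counts(1800, 240, 400, 3520))
  expect_equal(m, m10)
  # zero denominators report 0 with a warning
  expect_warning(expect_warning(
    m0 <- eval_metrics(confusion_counts(0, 10, 0, 10)), "precision"), "F1")
  expect_equal(unname(m0["sensitivity"]), 0)
  expect_equal(unname(m0["specificity"]), 1)
})

test_that("accuracy equals the prevalence-weighted identity", {
  set.seed(16)
  for (rep in 1:10) {
    lab <- sample(c("COPD", "non-COPD"), 40, TRUE)
    if (length(unique(lab)) < 2) next
    p <- runif(40)
    m <- eval_metrics(confusion(p, lab))
    prev <- mean(lab == "COPD")
    expect_equal(unname(m["accuracy"]),
                 prev * m[["sensitivity"]] + (1 - prev) * m[["specificity"]],
                 tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC equals brute-force pair counting", {
  p <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  lab <- c("COPD", "COPD", "non-COPD", "COPD", "non-COPD", "non-COPD")
  ra <- roc_auc(p, lab)
  expect_equal(ra$auc, 8 / 9, tolerance = 1e-12)
  expect_equal(ra$auc, auc_pairs(p, lab), tolerance = 1e-12)
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(4:20, 1)
    lab <- sample(c("COPD", "non-COPD"), n, TRUE)
    if (length(unique(lab)) < 2) next
    p <- sample(seq(0, 1, 0.1), n, TRUE)   # discrete scores force ties
    ra <- roc_auc(p, lab)
    expect_equal(ra$auc, auc_pairs(p, lab), tolerance = 1e-12)
    # ROC contract: starts (0,0), ends (1,1), monotone
    expect_equal(unlist(ra$roc[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(ra$roc[nrow(ra$roc), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(ra$roc$fpr) >= 0) && all(diff(ra$roc$tpr) >= 0))
  }
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(18)
  lab <- sample(c("COPD", "non-COPD"), 120, TRUE)
  p <- runif(120) + 0.3 * (lab == "COPD")
  ours <- roc_auc(p, lab)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(lab == "COPD", p)))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("edge cases: separation, null scores, single class", {
  lab <- rep(c("COPD", "non-COPD"), each = 10)
  expect_equal(roc_auc(c(runif(10, 0.8, 1), runif(10, 0, 0.2)), lab)$auc, 1)
  set.seed(19)
  expect_equal(roc_auc(runif(4000), sample(lab, 4000, TRUE))$auc, 0.5,
               tolerance = 0.05)
  expect_error(roc_auc(runif(5), rep("COPD", 5)), "both classes")
  # metrics are invariant to prediction order
  p <- runif(30); lab <- sample(c("COPD", "non-COPD"), 30, TRUE)
  o <- sample(30)
  expect_equal(eval_metrics(confusion(p, lab)),
               eval_metrics(confusion(p[o], lab[o])))
  expect_equal(roc_auc(p, lab)$auc, roc_auc(p[o], lab[o])$auc)
})
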