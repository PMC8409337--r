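test_that("confusion counts follow the definition and its symmetries", {
  c1 <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(c1[c("tp", "fn", "fp", "tn")]), c(tp = 1, fn = 1, fp = 1, tn = 1))
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0)
  # swapping arguments transposes FP and FN
  a <- confusion_counts(c(1, 1, 0), c(1, 0, 0))
  b <- confusion_counts(c(1, 0, 0), c(1, 1, 0))
  expect_equal(a$fp, b$fn)
  expect_equal(a$fn, b$fp)
  expect_error(confusion_counts(c(1, 0), c(1, 2)), class = "ssmfn_metric_error")
  expect_error(confusion_counts(c(1, 0), c(1)), class = "ssmfn_metric_error")
})

test_that("single-value metric examples match direct substitution", {
  c0 <- list(tp = 3, tn = 4, fp = 1, fn = 2)
  expect_equal(metric_accuracy(c0), 0.7)
  expect_equal(metric_sensitivity(c0), 0.6)
  expect_equal(metric_specificity(c0), 0.8)
  expect_equal(metric_mcc(c0), 10 / sqrt(600))  # ~0.4082
  expect_equal(metric_f1(list(tp = 1, tn = 0, fp = 1, fn = 1), "threat"), 1 / 3)
  expect_equal(metric_f1(list(tp = 1, tn = 0, fp = 1, fn = 1), "standard"), 0.5)
  expect_equal(metric_f1(list(tp = 5, tn = 2, fp = 0, fn = 0), "standard"), 1)
  expect_equal(metric_f1(list(tp = 5, tn = 2, fp = 0, fn = 0), "threat"), 1)
  expect_equal(metric_accuracy(list(tp = 25, tn = 25, fp = 25, fn = 25)), 0.5)
  expect_equal(metric_mcc(list(tp = 25, tn = 25, fp = 25, fn = 25)), 0)
  expect_equal(metric_mcc(list(tp = 50, tn = 50, fp = 0, fn = 0)), 1)
})

test_that("metrics match the per-sample brute-force oracle on 200 random tables", {
  withr::with_seed(99, {
    for (i in 1:200) {
      cts <- as.list(stats::setNames(sample(0:100, 4, replace = TRUE),
                                     c("tp", "tn", "fp", "fn")))
      if (cts$tp + cts$tn + cts$fp + cts$fn == 0) cts$tn <- 1
      o <- oracle_from_counts(cts$tp, cts$tn, cts$fp, cts$fn)
      expect_equal(metric_accuracy(cts), o$acc, tolerance = 1e-12)
      expect_equal(metric_mcc(cts), o$mcc, tolerance = 1e-12)
      if (cts$tp + cts$fn > 0)
        expect_equal(metric_sensitivity(cts), o$sens, tolerance = 1e-12)
      if (cts$tn + cts$fp > 0)
        expect_equal(metric_specificity(cts), o$spec, tolerance = 1e-12)
      if (cts$tp + cts$fp + cts$fn > 0) {
        expect_equal(metric_f1(cts, "standard"), o$f1_std, tolerance = 1e-12)
        expect_equal(metric_f1(cts, "threat"), o$f1_threat, tolerance = 1e-12)
      }
    }
  })
})

test_that("roc_auc equals exhaustive pair counting, exactly, up to n = 50", {
  expect_equal(roc_auc(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2)), 0.75)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)  # all ties
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- sample(4:50, 1)
      truth <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
      expect_identical(roc_auc(truth, scores), pair_count_auc(truth, scores))
    }
  })
})

test_that("roc_auc agrees with an established ROC implementation", {
  withr::with_seed(11, {
    truth <- sample(0:1, 300, replace = TRUE)
    truth[1:2] <- c(0, 1)
    scores <- stats::rnorm(300) + truth
    ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(truth, scores), ref, tolerance = 1e-12)
  })
})

test_that("class relabeling maps AUC to 1 - AUC and swaps sens and spec", {
  withr::with_seed(13, {
    truth <- c(1, 0, sample(0:1, 60, replace = TRUE))
    scores <- stats::rnorm(62) + truth
    auc <- roc_auc(truth, scores)
    expect_equal(roc_auc(1 - truth, scores), 1 - auc, tolerance = 1e-12)
    expect_equal(roc_auc(truth, -scores), 1 - auc, tolerance = 1e-12)
    # swapping labels and negating scores together restores the original
    expect_equal(roc_auc(1 - truth, -scores), auc, tolerance = 1e-12)
    pred <- as.integer(scores > 0.5)
    a <- confusion_counts(truth, pred)
    b <- confusion_counts(1 - truth, 1 - pred)
    expect_equal(metric_sensitivity(a), metric_specificity(b))
    expect_equal(metric_specificity(a), metric_sensitivity(b))
    # MCC invariant under the joint swap TP<->TN, FP<->FN
    expect_equal(metric_mcc(a), metric_mcc(b), tolerance = 1e-12)
  })
})

test_that("undefined metrics error individually and surface as NA in reports", {
  expect_error(metric_sensitivity(list(tp = 0, tn = 5, fp = 2, fn = 0)),
               class = "ssmfn_undefined_metric")
  expect_error(metric_specificity(list(tp = 3, tn = 0, fp = 0, fn = 1)),
               class = "ssmfn_undefined_metric")
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), class = "ssmfn_undefined_metric")
  # all-negative reference: sensitivity is not-applicable, never zero
  rep <- metric_report(c(0, 0, 0), c(0, 1, 0), c(0.1, 0.9, 0.2))
  expect_true(is.na(rep$sens))
  expect_true(is.na(rep$auc))
  expect_equal(rep$spec, 2 / 3)
})

test_that("a degenerate all-positive predictor on a balanced set behaves as expected", {
  truth <- rep(c(1, 0), each = 10)
  pred <- rep(1, 20)
  rep <- metric_report(truth, pred, scores = rep(0.9, 20))
  expect_equal(rep$acc, 0.5)
  expect_equal(rep$sens, 1)
  expect_equal(rep$spec, 0)
  expect_equal(rep$mcc, 0)   # zero-denominator convention
  expect_equal(rep$auc, 0.5) # all tied scores
})

test_that("metric_report records the F1 variant and confusion counts", {
  rep <- metric_report(c(1, 1, 0), c(1, 0, 1), c(0.9, 0.2, 0.8),
                       f1_variant = "threat")
  expect_identical(rep$f1_variant, "threat")
  expect_equal(rep$f1, 1 / 3)
  expect_equal(unlist(rep[c("tp", "tn", "fp", "fn")]),
               c(tp = 1, tn = 0, fp = 1, fn = 1))
  expect_equal(rep$n, 3)
})
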