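test_that("confusion counts follow the interacting-positive convention", {
  cm <- confusion(rep(c(1, 0), c(10, 10)), rep(c(1, 0), c(10, 10)))
  expect_equal(unclass(cm)[c("TP", "TN", "FP", "FN")],
               list(TP = 10L, TN = 10L, FP = 0L, FN = 0L))
  cm2 <- confusion(rep(1, 20), rep(c(1, 0), c(10, 10)))
  expect_equal(cm2$TP, 10L); expect_equal(cm2$FP, 10L)
  expect_equal(cm2$TN, 0L); expect_equal(cm2$FN, 0L)
  expect_error(confusion(integer(0), integer(0)), "empty")
  expect_error(confusion(c(1, 0), c(1)), "length")
})

test_that("confusion counts equal an exhaustive tally on random data", {
  set.seed(50)
  pred <- rbinom(50, 1, 0.5); lab <- rbinom(50, 1, 0.5)
  cm <- confusion(pred, lab)
  tp <- tn <- fp <- fn <- 0L
  for (i in 1:50) {
    if (pred[i] == 1 && lab[i] == 1) tp <- tp + 1L
    if (pred[i] == 0 && lab[i] == 0) tn <- tn + 1L
    if (pred[i] == 1 && lab[i] == 0) fp <- fp + 1L
    if (pred[i] == 0 && lab[i] == 1) fn <- fn + 1L
  }
  expect_equal(c(cm$TP, cm$TN, cm$FP, cm$FN), c(tp, tn, fp, fn))
  expect_equal(cm$TP + cm$TN + cm$FP + cm$FN, 50L)
})

make_counts <- function(TP, TN, FP, FN) {
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN),
            class = "ppi_confusion")
}

test_that("the five metric formulas match hand-computed values", {
  perfect <- ppi_metrics(make_counts(50, 50, 0, 0))
  expect_equal(perfect$accuracy, 1); expect_equal(perfect$recall, 1)
  expect_equal(perfect$specificity, 1); expect_equal(perfect$precision, 1)
  expect_equal(perfect$mcc, 1)

  coin <- ppi_metrics(make_counts(25, 25, 25, 25))
  expect_equal(coin$accuracy, 0.5)
  expect_equal(coin$mcc, 0)                   # numerator 625 - 625

  m <- ppi_metrics(make_counts(90, 80, 20, 10))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$recall, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$precision, 90 / 110)
  expect_equal(m$mcc, 0.70352647, tolerance = 1e-7)  # 7000 / sqrt(9.9e7)
  expect_identical(m$sensitivity, m$recall)   # same formula, one field
})

test_that("degenerate denominators return the documented sentinels", {
  w <- capture_warnings(m <- ppi_metrics(make_counts(0, 10, 0, 0)))
  expect_match(w, "recall", all = FALSE)
  expect_match(w, "precision", all = FALSE)
  expect_equal(m$recall, 0)
  expect_equal(m$precision, 0)
  expect_equal(m$mcc, 0)                      # zero factor under the radical
  expect_equal(m$accuracy, 1)
})

test_that("label flips swap recall and specificity but preserve accuracy and MCC", {
  set.seed(51)
  pred <- rbinom(200, 1, 0.4); lab <- rbinom(200, 1, 0.5)
  m1 <- ppi_metrics(confusion(pred, lab))
  m2 <- ppi_metrics(confusion(1 - pred, 1 - lab))
  expect_equal(m2$accuracy, m1$accuracy)
  expect_equal(m2$recall, m1$specificity)
  expect_equal(m2$specificity, m1$recall)
  expect_equal(m2$mcc, m1$mcc, tolerance = 1e-12)
  # self-agreement is all-ones with MCC 1
  ms <- ppi_metrics(confusion(lab, lab))
  expect_equal(unlist(ms[c("accuracy", "recall", "specificity",
                           "precision", "mcc")]),
               c(accuracy = 1, recall = 1, specificity = 1,
                 precision = 1, mcc = 1))
})

test_that("rank-based AUC matches pairwise enumeration and handles ties", {
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_score(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  expect_error(auc_score(runif(5), rep(1, 5)), "both classes")
  # agreement with exhaustive pair enumeration on random scores
  set.seed(52)
  sc <- round(runif(60), 1)                  # coarse grid forces ties
  lab <- rbinom(60, 1, 0.5)
  pos <- which(lab == 1); neg <- which(lab == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
  expect_equal(auc_score(sc, lab), tot / (length(pos) * length(neg)))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(53)
  sc <- rnorm(80); lab <- rbinom(80, 1, 0.5)
  a <- auc_score(sc, lab)
  expect_equal(auc_score(exp(sc), lab), a)
  expect_equal(auc_score(5 * sc - 2, lab), a)
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(a, ref, tolerance = 1e-12)
  }
})

test_that("stratified folds are disjoint, exhaustive and label-balanced", {
  lab <- rep(c(1, 0), c(60, 40))
  folds <- kfold_split(lab, k = 5, seed = 9)
  test_idx <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(test_idx)), 1:100)
  for (f in folds) {
    expect_length(f$test, 20L)
    expect_identical(sort(c(f$train, f$test)), 1:100)
    expect_equal(sum(lab[f$test] == 1), 12)
    expect_equal(sum(lab[f$test] == 0), 8)
  }
  # determinism and n >= k guard
  expect_identical(kfold_split(lab, k = 5, seed = 9), folds)
  expect_error(kfold_split(rep(1, 3), k = 5), "at least")
  # n = 10, k = 5: five test folds of size 2
  f10 <- kfold_split(rep(c(1, 0), 5), k = 5, seed = 1)
  expect_true(all(vapply(f10, function(x) length(x$test), integer(1)) == 2L))
})

test_that("cross-validation returns per-fold reports and a reproducible best model", {
  tiny <- tiny_dataset()
  cfg <- desk_config(seed = 2, epochs = 15L)
  cv1 <- run_cv(tiny$sim$pairs, tiny$features, cfg, k = 3, seed = 4)
  expect_s3_class(cv1, "ppi_cv")
  expect_identical(nrow(cv1$summary), 3L)
  expect_identical(sum(cv1$summary$n_test), nrow(tiny$sim$pairs))
  for (f in seq_len(3)) {
    cm <- cv1$folds[[f]]$counts
    expect_identical(cm$TP + cm$TN + cm$FP + cm$FN, cv1$summary$n_test[f])
  }
  expect_identical(cv1$best_fold,
                   which.max(cv1$summary$accuracy))
  cv2 <- run_cv(tiny$sim$pairs, tiny$features, cfg, k = 3, seed = 4)
  expect_identical(cv1$summary, cv2$summary)   # seeded determinism
})
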