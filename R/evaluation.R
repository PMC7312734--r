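# Binary-classifier evaluation: confusion counts, the five derived
# metrics (accuracy, recall, specificity, precision, MCC), rank-based
# AUC, stratified k-fold cross-validation.

#' Confusion counts of predicted vs true classes
#'
#' "Positive" is the interacting class (label 1).
#'
#' @param predictions,labels vectors of 1/0 classes of equal length.
#' @return a `ppi_confusion`: list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(predictions, labels) {
  if (!length(predictions))
    stop("empty predictions")
  if (length(predictions) != length(labels))
    stop("`predictions` and `labels` differ in length (",
         length(predictions), " vs ", length(labels), ")")
  if (!all(predictions %in% c(0, 1)) || !all(labels %in% c(0, 1)))
    stop("classes must be 1 (interacting) or 0 (non-interacting)")
  structure(list(TP = sum(predictions == 1 & labels == 1),
                 TN = sum(predictions == 0 & labels == 0),
                 FP = sum(predictions == 1 & labels == 0),
                 FN = sum(predictions == 0 & labels == 1)),
            class = "ppi_confusion")
}

#' @export
print.ppi_confusion <- function(x, ...) {
  cat(sprintf("Confusion counts: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

#' Confusion-based classification metrics
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, recall `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and the Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Degenerate denominators: recall/specificity/precision return 0 with a
#' warning; MCC returns 0 whenever any factor under the radical is zero
#' (the standard convention). `sensitivity` is an alias of recall — they
#' are the same formula.
#'
#' @param cm a `ppi_confusion` from [confusion()].
#' @return a `ppi_metrics`: list with `accuracy`, `recall`,
#'   `sensitivity`, `specificity`, `precision`, `mcc` and the counts.
#' @export
ppi_metrics <- function(cm) {
  stopifnot(inherits(cm, "ppi_confusion"))
  TP <- cm$TP; TN <- cm$TN; FP <- cm$FP; FN <- cm$FN
  n <- TP + TN + FP + FN
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); returning 0")
      return(0)
    }
    num / den
  }
  acc <- safe_div(TP + TN, n, "accuracy")
  rec <- safe_div(TP, TP + FN, "recall")
  spec <- safe_div(TN, TN + FP, "specificity")
  prec <- safe_div(TP, TP + FP, "precision")
  rad <- prod(c(TP + FP, TP + FN, TN + FP, TN + FN))
  mcc <- if (rad == 0) 0 else (TP * TN - FP * FN) / sqrt(rad)
  structure(list(accuracy = acc, recall = rec, sensitivity = rec,
                 specificity = spec, precision = prec, mcc = mcc,
                 counts = cm),
            class = "ppi_metrics")
}

#' @export
print.ppi_metrics <- function(x, ...) {
  cat(sprintf(paste0("  accuracy %.4f | recall %.4f | specificity %.4f | ",
                     "precision %.4f | MCC %.4f\n"),
              x$accuracy, x$recall, x$specificity, x$precision, x$mcc))
  invisible(x)
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney normalization: the fraction of (positive, negative) score
#' pairs ranked correctly, ties counting 0.5. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric scores, larger = more interacting.
#' @param labels 1/0 classes.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("`scores` and `labels` differ in length")
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)                     # average ranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold partition
#'
#' Disjoint, exhaustive folds whose sizes differ by at most one. With
#' `stratify = TRUE` (default) the label mix of every fold matches the
#' full set to within one pair per class (round-robin assignment within
#' each class, the counter continuing across classes so overall fold
#' sizes stay balanced). Deterministic for a given seed.
#'
#' @param labels 1/0 vector (used for stratification and length).
#' @param k number of folds.
#' @param seed integer seed.
#' @param stratify balance labels across folds.
#' @return list of k elements, each `list(train = ..., test = ...)` index
#'   vectors.
#' @export
kfold_split <- function(labels, k = 5L, seed = 1L, stratify = TRUE) {
  n <- length(labels)
  if (n < k) stop("need at least k = ", k, " records, got ", n)
  set.seed(as.integer(seed))
  fold <- integer(n)
  if (stratify) {
    counter <- 0L
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((counter + seq_along(idx) - 1L) %% k) + 1L
      counter <- counter + length(idx)
    }
  } else {
    fold <- ((sample.int(n) - 1L) %% k) + 1L
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}

#' Fivefold cross-validation of the Y-type classifier
#'
#' For each fold: the training portion is assembled, order-augmented and
#' fitted; the fold's test portion is scored untouched. The best model is
#' the one with the highest fold accuracy (ties: lowest fold index). An
#' optional hold-out pair list, never seen by any fold, is scored by the
#' best model.
#'
#' @param pairs data frame with `id_a`, `id_b`, `label`.
#' @param features matrix from [featurize_proteins()].
#' @param config a [model_config()]; fold f trains with seed
#'   `config$seed + f - 1`.
#' @param k number of folds.
#' @param seed seed of the fold partition.
#' @param holdout optional data frame of hold-out pairs.
#' @param verbose print per-fold progress.
#' @return a `ppi_cv`: per-fold `ppi_metrics` + AUC, a summary data
#'   frame, `best_fold`, the best `ppi_fit`, and hold-out metrics when a
#'   hold-out set was given.
#' @export
run_cv <- function(pairs, features, config = model_config(), k = 5L,
                   seed = 1L, holdout = NULL, verbose = FALSE) {
  folds <- kfold_split(pairs$label, k = k, seed = seed)
  fold_metrics <- vector("list", k)
  fold_auc <- numeric(k)
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    cfg <- config
    cfg$seed <- config$seed + f - 1L
    tr_pairs <- pairs[folds[[f]]$train, , drop = FALSE]
    te_pairs <- pairs[folds[[f]]$test, , drop = FALSE]
    fit <- ppi_fit(build_pair_features(features, tr_pairs, role = "training"),
                   config = cfg)
    te <- build_pair_features(features, te_pairs, role = "test")
    score <- predict(fit, te, type = "prob")
    m <- ppi_metrics(confusion(as.integer(score > 0.5), te_pairs$label))
    fold_metrics[[f]] <- m
    fold_auc[f] <- auc_score(score, te_pairs$label)
    fits[[f]] <- fit
    if (verbose)
      message(sprintf("fold %d/%d: accuracy %.3f, AUC %.3f",
                      f, k, m$accuracy, fold_auc[f]))
  }
  acc <- vapply(fold_metrics, `[[`, numeric(1), "accuracy")
  best <- which.max(acc)                # ties: lowest index
  summary_df <- data.frame(
    fold = seq_len(k),
    n_test = vapply(folds, function(x) length(x$test), integer(1)),
    accuracy = acc,
    recall = vapply(fold_metrics, `[[`, numeric(1), "recall"),
    specificity = vapply(fold_metrics, `[[`, numeric(1), "specificity"),
    precision = vapply(fold_metrics, `[[`, numeric(1), "precision"),
    mcc = vapply(fold_metrics, `[[`, numeric(1), "mcc"),
    auc = fold_auc)
  out <- list(folds = fold_metrics, auc = fold_auc, summary = summary_df,
              best_fold = best, best_fit = fits[[best]], splits = folds)
  if (!is.null(holdout)) {
    ho <- build_pair_features(features, holdout, role = "test")
    sc <- predict(fits[[best]], ho, type = "prob")
    out$holdout <- ppi_metrics(confusion(as.integer(sc > 0.5), holdout$label))
    out$holdout_auc <- auc_score(sc, holdout$label)
  }
  class(out) <- "ppi_cv"
  out
}

#' @export
print.ppi_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", nrow(x$summary)))
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("best fold: %d (accuracy %.4f)\n", x$best_fold,
              x$summary$accuracy[x$best_fold]))
  if (!is.null(x$holdout)) {
    cat("hold-out set:\n")
    print(x$holdout)
    cat(sprintf("  hold-out AUC: %.4f\n", x$holdout_auc))
  }
  invisible(x)
}
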