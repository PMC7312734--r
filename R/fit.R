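# User-facing fitting interface: ppi_fit() returns a classed model object
# with the usual methods (print, summary, coef, predict, plot, residuals,
# simulate).

#' Fit the Y-type PPI classifier to a training pair set
#'
#' Standardizes the 600 descriptor columns over the training proteins
#' (both halves of every pair pooled, so the scaling is order-symmetric),
#' applies forward/backward pair-order augmentation, builds the
#' weight-shared bidirectional LSTM and trains it by mini-batch SGD on
#' softmax cross-entropy.
#'
#' @param pairset a training `ppi_pairset` from [build_pair_features()].
#' @param config a [model_config()].
#' @param augment apply [augment_forward_backward()] before training
#'   (default TRUE; set FALSE if the set is already augmented).
#' @param verbose print per-epoch training loss.
#' @return a `ppi_fit` object: trained parameters, feature scaling,
#'   training history and fitted scores for the original (un-augmented)
#'   training records.
#' @export
ppi_fit <- function(pairset, config = model_config(), augment = TRUE,
                    verbose = FALSE) {
  if (!inherits(pairset, "ppi_pairset"))
    stop("`pairset` must be a ppi_pairset (see build_pair_features)")
  if (!identical(pairset$role, "training"))
    stop("`pairset` must be a training split")
  orig <- pairset
  scaling <- NULL
  if (config$scale_features) {
    prot <- rbind(pairset$x[, 1:600, drop = FALSE],
                  pairset$x[, 601:1200, drop = FALSE])
    mu <- colMeans(prot)
    sdev <- apply(prot, 2L, stats::sd)
    sdev[sdev == 0 | !is.finite(sdev)] <- 1
    scaling <- list(mu = mu, sd = sdev)
    pairset$x <- .apply_scaling(pairset$x, scaling)
    orig$x <- pairset$x
  }
  if (augment) pairset <- augment_forward_backward(pairset)
  params <- build_model(config, seed = config$seed)
  tr <- ytype_train(params, pairset$x, pairset$y, verbose = verbose)
  fitted <- ytype_predict(tr$params, orig$x)
  structure(list(call = match.call(), config = config, params = tr$params,
                 scaling = scaling, history = tr$history,
                 pairs = orig$pairs, fitted = fitted$score,
                 y = orig$y),
            class = "ppi_fit")
}

# scale both 600-halves of a pair-feature matrix with one protein-level
# scaling, so (A,B) and (B,A) stay exact mirrors
.apply_scaling <- function(x, scaling) {
  if (is.null(scaling)) return(x)
  mu2 <- c(scaling$mu, scaling$mu)
  sd2 <- c(scaling$sd, scaling$sd)
  sweep(sweep(x, 2L, mu2), 2L, sd2, "/")
}

#' @export
print.ppi_fit <- function(x, ...) {
  cat("Y-type PPI classifier fit\n")
  cat(sprintf("  training pairs: %d (x2 after order augmentation)\n",
              nrow(x$pairs)))
  cat(sprintf("  epochs run: %d; final loss %.4f, training accuracy %.3f\n",
              nrow(x$history), utils::tail(x$history$loss, 1),
              utils::tail(x$history$accuracy, 1)))
  print(x$params)
  invisible(x)
}

#' @export
summary.ppi_fit <- function(object, ...) {
  pred <- as.integer(object$fitted > 0.5)
  cm <- confusion(pred, object$y[, 1L])
  out <- list(audit = model_audit(object$params),
              history = object$history,
              training_metrics = ppi_metrics(cm),
              training_auc = auc_score(object$fitted, object$y[, 1L]))
  class(out) <- "summary.ppi_fit"
  out
}

#' @export
print.summary.ppi_fit <- function(x, ...) {
  cat("Y-type PPI classifier — training summary\n")
  cat(sprintf("  parameters: %s | recurrent units: %d | buffer: %d\n",
              format(x$audit$parameters, big.mark = ","),
              x$audit$rnn_units_total, x$audit$buffer_units))
  cat(sprintf("  epochs: %d, final loss %.4f\n", nrow(x$history),
              utils::tail(x$history$loss, 1)))
  print(x$training_metrics)
  cat(sprintf("  training AUC: %.4f\n", x$training_auc))
  invisible(x)
}

#' @export
coef.ppi_fit <- function(object, ...) {
  object$params[c("branch_a", if (!object$config$shared) "branch_b",
                  "buffer", "dense")]
}

#' Predict interaction scores for protein pairs
#'
#' @param object a `ppi_fit`.
#' @param newdata a `ppi_pairset` or an n x 1200 pair-feature matrix.
#' @param type `"prob"` for the interacting-class probability, `"class"`
#'   for the 1/0 call (ties at exactly 0.5 resolve to non-interacting).
#' @param symmetric average the (A,B) and (B,A) orders (default from the
#'   fit's config).
#' @param ... unused.
#' @return numeric (prob) or integer (class) vector.
#' @export
predict.ppi_fit <- function(object, newdata, type = c("prob", "class"),
                            symmetric = object$config$symmetric_inference,
                            ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "ppi_pairset")) newdata$x else as.matrix(newdata)
  if (ncol(x) != 1200L) stop("`newdata` must have 1200 feature columns")
  x <- .apply_scaling(x, object$scaling)
  pr <- ytype_predict(object$params, x, symmetric = symmetric)
  if (type == "prob") pr$score else pr$class
}

#' @export
residuals.ppi_fit <- function(object, ...) {
  object$y[, 1L] - object$fitted
}

#' @export
plot.ppi_fit <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "training cross-entropy",
                 main = "Y-type PPI classifier training", ...)
  invisible(x)
}

#' Simulate labels from fitted interaction probabilities
#'
#' Draws Bernoulli labels for the training pairs from their fitted
#' interacting-class probabilities.
#'
#' @param object a `ppi_fit`.
#' @param nsim number of label sets.
#' @param seed optional seed.
#' @param ... unused.
#' @return n x `nsim` integer matrix.
#' @export
simulate.ppi_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted)
  matrix(stats::rbinom(n * nsim, 1L, rep(object$fitted, nsim)), nrow = n)
}

#' Save / load a trained model checkpoint
#'
#' Versioned single-file checkpoint (RDS container with a format tag);
#' readers reject unknown versions.
#'
#' @param object a `ppi_fit` or `ytype_params`.
#' @param path file path.
#' @return `load_model` returns the saved object.
#' @export
save_model <- function(object, path) {
  saveRDS(list(format = "ppiwave-model", version = 1L, object = object), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "ppiwave-model"))
    stop("not a ppiwave model checkpoint: ", path)
  if (!identical(x$version, 1L))
    stop("unsupported model checkpoint version: ", x$version)
  x$object
}
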