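# The "Y-type" two-branch bidirectional LSTM with local weight sharing.
#
# Input: one 1200-vector per pair (two 600-dim protein descriptors).
# Each 600-half is unstacked to a 75-step x 8-channel sequence (one
# channel per physicochemical property) and fed through a bidirectional
# LSTM stack; the two branches use ONE shared parameter storage, so the
# transform applied to protein A is identical to that applied to B. The
# terminal states of each branch pass through a shared affine+ReLU
# projection; the two projections concatenate into the buffer layer,
# followed by a dense 32 -> 8 -> 2 stack with softmax output:
# (1,0) = interacting, (0,1) = non-interacting.
#
# Training is plain mini-batch SGD on softmax cross-entropy, with all
# gradients derived analytically (full backpropagation through time).

#' Rectified linear activation
#'
#' `ReLU(x) = x` for `x > 0`, else 0. Applied on the buffer and hidden
#' dense layers; the recurrent gates keep their sigmoid/tanh forms.
#'
#' @param x numeric vector, matrix or array.
#' @return object of the same shape.
#' @export
relu <- function(x) pmax(x, 0)

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Model configuration
#'
#' Defaults follow the published architecture and training protocol:
#' 2 bidirectional LSTM layers per branch with 512 units per layer
#' (256 per direction; total recurrent units 512 x 2 branches x
#' 2 layers = 2048), a 256-unit buffer layer, dense layers 32, 8, 2,
#' batch size 128, learning rate 0.05, 200 training epochs.
#'
#' @param rnn_units recurrent units per bidirectional layer (both
#'   directions combined; must be even).
#' @param rnn_layers bidirectional LSTM layers per branch.
#' @param buffer_units width of the buffer layer (both branches combined).
#' @param dense_units dense stack widths; must end in 2 (the one-hot
#'   output).
#' @param batch_size,learning_rate,epochs SGD protocol.
#' @param momentum SGD momentum; 0 (default) is plain SGD.
#' @param seed integer seed driving initialization and shuffling.
#' @param steps_per_protein,channels_per_step how each 600-vector is
#'   consumed as a sequence; their product must be 600.
#' @param shared if `TRUE` (default) the two branches share one parameter
#'   storage; `FALSE` builds the non-shared control with independent
#'   branch weights.
#' @param buffer_mode `"per_branch"` (default): a shared affine+ReLU maps
#'   each branch terminal to `buffer_units / 2` units and the two halves
#'   concatenate; `"joint"`: one affine+ReLU maps the concatenated
#'   terminals to `buffer_units`.
#' @param symmetric_inference if `TRUE` (default) predictions average the
#'   scores of the (A,B) and (B,A) orders, making inference exactly
#'   order-invariant.
#' @param scale_features if `TRUE` (default) [ppi_fit()] standardizes the
#'   600 descriptor columns on the training proteins and applies the same
#'   scaling at prediction time.
#' @param early_stop_acc optional training-accuracy threshold at which
#'   training stops early (e.g. 1.0); `NULL` disables.
#' @return a `ppi_model_config` list.
#' @export
model_config <- function(rnn_units = 512L, rnn_layers = 2L,
                         buffer_units = 256L, dense_units = c(32L, 8L, 2L),
                         batch_size = 128L, learning_rate = 0.05,
                         epochs = 200L, momentum = 0, seed = 1L,
                         steps_per_protein = 75L, channels_per_step = 8L,
                         shared = TRUE,
                         buffer_mode = c("per_branch", "joint"),
                         symmetric_inference = TRUE, scale_features = TRUE,
                         early_stop_acc = NULL) {
  buffer_mode <- match.arg(buffer_mode)
  stopifnot(rnn_units >= 2, rnn_units %% 2 == 0, rnn_layers >= 1,
            buffer_units >= 2, length(dense_units) >= 1,
            batch_size >= 1, learning_rate >= 0, epochs >= 0,
            momentum >= 0, momentum < 1,
            steps_per_protein >= 1, channels_per_step >= 1)
  if (utils::tail(dense_units, 1) != 2L)
    stop("`dense_units` must end in 2 (the one-hot output layer)")
  if (steps_per_protein * channels_per_step != 600L)
    stop("steps_per_protein x channels_per_step must equal 600")
  if (buffer_mode == "per_branch" && buffer_units %% 2 != 0)
    stop("per-branch buffer needs an even `buffer_units`")
  structure(list(rnn_units = as.integer(rnn_units),
                 rnn_layers = as.integer(rnn_layers),
                 buffer_units = as.integer(buffer_units),
                 dense_units = as.integer(dense_units),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 momentum = momentum,
                 seed = as.integer(seed),
                 steps_per_protein = as.integer(steps_per_protein),
                 channels_per_step = as.integer(channels_per_step),
                 shared = isTRUE(shared),
                 buffer_mode = buffer_mode,
                 symmetric_inference = isTRUE(symmetric_inference),
                 scale_features = isTRUE(scale_features),
                 early_stop_acc = early_stop_acc),
            class = "ppi_model_config")
}

#' One LSTM cell step (equation form)
#'
#' Single-example LSTM update: forget, input and output gates are
#' sigmoids of affine maps over the concatenation `[h_prev, x_t]`, the
#' candidate state is a tanh, then
#' `c_t = f * c_prev + i * c_tilde` and `h_t = o * tanh(c_t)`.
#'
#' @param x_t input vector.
#' @param h_prev,c_prev previous hidden and cell state (length H).
#' @param params list with `W_f`, `W_i`, `W_C`, `W_o` (H x (H + D)
#'   matrices over `[h_prev, x_t]`) and `b_f`, `b_i`, `b_C`, `b_o`.
#' @return list with `h` and `c`.
#' @export
lstm_step <- function(x_t, h_prev, c_prev, params) {
  hx <- c(h_prev, x_t)
  H <- length(h_prev)
  for (w in c("W_f", "W_i", "W_C", "W_o")) {
    if (!identical(dim(params[[w]]), c(H, length(hx))))
      stop("`", w, "` must be ", H, " x ", length(hx))
  }
  if (length(c_prev) != H) stop("`c_prev` must have length ", H)
  f <- .sigmoid(drop(params$W_f %*% hx) + params$b_f)
  i <- .sigmoid(drop(params$W_i %*% hx) + params$b_i)
  ctilde <- tanh(drop(params$W_C %*% hx) + params$b_C)
  o <- .sigmoid(drop(params$W_o %*% hx) + params$b_o)
  c_t <- f * c_prev + i * ctilde
  list(h = o * tanh(c_t), c = c_t)
}

# Fused batched cell: W is (D + H) x 4H with gate column blocks
# [i | f | g | o], b length 4H; z = [h_prev, x] %*% W + b.
.init_cell <- function(input_size, hidden_size) {
  m <- input_size + hidden_size
  lim <- sqrt(6 / (m + hidden_size))
  W <- matrix(stats::runif(m * 4L * hidden_size, -lim, lim), m, 4L * hidden_size)
  b <- rep(0, 4L * hidden_size)
  b[(hidden_size + 1L):(2L * hidden_size)] <- 1   # forget-gate bias at 1
  list(W = W, b = b)
}

# fused cell -> per-gate equation-form parameters for lstm_step()
.split_cell <- function(cell, hidden_size) {
  H <- hidden_size
  g <- function(k) t(cell$W[, ((k - 1L) * H + 1L):(k * H), drop = FALSE])
  bg <- function(k) cell$b[((k - 1L) * H + 1L):(k * H)]
  list(W_i = g(1), W_f = g(2), W_C = g(3), W_o = g(4),
       b_i = bg(1), b_f = bg(2), b_C = bg(3), b_o = bg(4))
}

# One direction over a list of step inputs (each n x D). `ord` is the
# traversal order (1:T forward, T:1 backward). Returns per-step hidden
# states, the terminal state, and caches for backpropagation.
.lstm_dir_forward <- function(xs, cell, ord, hidden_size) {
  n <- nrow(xs[[1]]); H <- hidden_size
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  hs <- vector("list", length(xs))
  cache <- vector("list", length(xs))
  for (t in ord) {
    hx <- cbind(h, xs[[t]])
    z <- hx %*% cell$W
    z <- sweep(z, 2L, cell$b, "+")
    i <- .sigmoid(z[, 1:H, drop = FALSE])
    f <- .sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    hs[[t]] <- h
    cache[[t]] <- list(hx = hx, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, tc = tc)
  }
  list(hs = hs, h_last = h, cache = cache)
}

# Backpropagation through one direction. `dhs` is a list of per-step
# gradients w.r.t. the direction's hidden outputs (NULL entries = zero).
# Returns gradients for the cell and for the step inputs.
.lstm_dir_backward <- function(dhs, cell, cache, ord, hidden_size, input_size) {
  H <- hidden_size
  Tn <- length(cache)
  n <- nrow(cache[[ord[1]]]$hx)
  dW <- matrix(0, nrow(cell$W), ncol(cell$W))
  db <- rep(0, length(cell$b))
  dh_carry <- matrix(0, n, H)
  dc_carry <- matrix(0, n, H)
  dxs <- vector("list", Tn)
  for (t in rev(ord)) {
    cc <- cache[[t]]
    dh <- dh_carry + if (is.null(dhs[[t]])) 0 else dhs[[t]]
    do_ <- dh * cc$tc
    dc <- dc_carry + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_carry <- dc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cc$hx, dz)
    db <- db + colSums(dz)
    dhx <- dz %*% t(cell$W)
    dh_carry <- dhx[, 1:H, drop = FALSE]
    dxs[[t]] <- dhx[, (H + 1):(H + input_size), drop = FALSE]
  }
  list(dW = dW, db = db, dxs = dxs)
}

# Branch forward through the shared bidirectional stack.
# xs: list of T matrices n x channels. Returns terminal (n x 2H of the
# top layer) and caches per layer.
.branch_forward <- function(xs, layers, hidden_size) {
  Tn <- length(xs)
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    fw <- .lstm_dir_forward(xs, layers[[l]]$fwd, seq_len(Tn), hidden_size)
    bw <- .lstm_dir_forward(xs, layers[[l]]$bwd, rev(seq_len(Tn)), hidden_size)
    caches[[l]] <- list(fw = fw, bw = bw,
                        input_size = ncol(xs[[1]]))
    xs <- lapply(seq_len(Tn), function(t) cbind(fw$hs[[t]], bw$hs[[t]]))
  }
  list(terminal = cbind(caches[[length(layers)]]$fw$h_last,
                        caches[[length(layers)]]$bw$h_last),
       caches = caches)
}

# Branch backward: gradient arrives only at the top layer's terminal
# states; lower layers receive per-step gradients from above.
.branch_backward <- function(dterminal, layers, caches, hidden_size) {
  H <- hidden_size
  L <- length(layers)
  Tn <- length(caches[[1]]$fw$hs)
  grads <- vector("list", L)
  # per-step gradient lists w.r.t. each direction's hidden outputs
  dh_fw <- vector("list", Tn); dh_bw <- vector("list", Tn)
  dh_fw[[Tn]] <- dterminal[, 1:H, drop = FALSE]
  dh_bw[[1]] <- dterminal[, (H + 1):(2 * H), drop = FALSE]
  for (l in L:1) {
    ca <- caches[[l]]
    gf <- .lstm_dir_backward(dh_fw, layers[[l]]$fwd, ca$fw$cache,
                             seq_len(Tn), H, ca$input_size)
    gb <- .lstm_dir_backward(dh_bw, layers[[l]]$bwd, ca$bw$cache,
                             rev(seq_len(Tn)), H, ca$input_size)
    grads[[l]] <- list(fwd = list(W = gf$dW, b = gf$db),
                       bwd = list(W = gb$dW, b = gb$db))
    if (l > 1L) {
      dh_fw <- vector("list", Tn); dh_bw <- vector("list", Tn)
      for (t in seq_len(Tn)) {
        dx <- gf$dxs[[t]] + gb$dxs[[t]]
        dh_fw[[t]] <- dx[, 1:H, drop = FALSE]
        dh_bw[[t]] <- dx[, (H + 1):(2 * H), drop = FALSE]
      }
    }
  }
  grads
}

#' Unstack a 600-dim descriptor into the recurrent input sequence
#'
#' Step `t` of the sequence carries the `t`-th feature of each of the 8
#' property blocks (block-major unstacking): element `(t, j)` is
#' `values[75 (j - 1) + t]`. `flatten_from_rnn()` is the exact inverse.
#'
#' @param f a `protein_feature` or plain 600-vector.
#' @param config a [model_config()].
#' @return `steps_per_protein` x `channels_per_step` matrix.
#' @export
reshape_for_rnn <- function(f, config = model_config()) {
  if (inherits(f, "protein_feature")) f <- f$values
  S <- config$steps_per_protein; C <- config$channels_per_step
  if (length(f) != S * C)
    stop("descriptor length ", length(f), " (expected ", S * C,
         " = ", S, " x ", C, ")")
  matrix(unname(f), nrow = S, ncol = C)
}

#' @rdname reshape_for_rnn
#' @param m matrix from [reshape_for_rnn()].
#' @export
flatten_from_rnn <- function(m) as.vector(m)

# split an n x 1200 matrix into two step-lists of n x channels matrices
.pair_to_steps <- function(x, config) {
  S <- config$steps_per_protein; C <- config$channels_per_step
  half <- S * C
  if (ncol(x) != 2L * half)
    stop("pair feature width ", ncol(x), " != ", 2L * half)
  sel <- function(off, t) x[, off + t + S * (0:(C - 1L)), drop = FALSE]
  list(a = lapply(seq_len(S), function(t) sel(0L, t)),
       b = lapply(seq_len(S), function(t) sel(half, t)))
}

#' Build the Y-type model parameters
#'
#' Glorot-uniform initialization throughout (forget-gate biases start at
#' 1), driven by one seed. With `config$shared = TRUE` (default) both
#' branches resolve to the same parameter storage.
#'
#' @param config a [model_config()].
#' @param seed overrides `config$seed` when given.
#' @return a `ytype_params` object.
#' @export
build_model <- function(config = model_config(), seed = config$seed) {
  stopifnot(inherits(config, "ppi_model_config"))
  set.seed(seed)
  H <- config$rnn_units %/% 2L         # units per direction
  make_branch <- function() {
    lapply(seq_len(config$rnn_layers), function(l) {
      d <- if (l == 1L) config$channels_per_step else 2L * H
      list(fwd = .init_cell(d, H), bwd = .init_cell(d, H))
    })
  }
  branch_a <- make_branch()
  branch_b <- if (config$shared) NULL else make_branch()
  glorot <- function(m, n) {
    lim <- sqrt(6 / (m + n))
    matrix(stats::runif(m * n, -lim, lim), m, n)
  }
  if (config$buffer_mode == "per_branch") {
    buffer <- list(W = glorot(2L * H, config$buffer_units %/% 2L),
                   b = rep(0, config$buffer_units %/% 2L))
  } else {
    buffer <- list(W = glorot(4L * H, config$buffer_units),
                   b = rep(0, config$buffer_units))
  }
  widths <- c(config$buffer_units, config$dense_units)
  dense <- lapply(seq_len(length(widths) - 1L), function(k)
    list(W = glorot(widths[k], widths[k + 1L]), b = rep(0, widths[k + 1L])))
  structure(list(config = config, branch_a = branch_a, branch_b = branch_b,
                 buffer = buffer, dense = dense),
            class = "ytype_params")
}

#' @export
print.ytype_params <- function(x, ...) {
  a <- model_audit(x)
  cat("Y-type weight-shared bidirectional LSTM\n")
  cat(sprintf("  input units: %d (2 x 600)\n", a$input_units))
  cat(sprintf("  recurrent units: %d (%d per layer x 2 branches x %d layers)%s\n",
              a$rnn_units_total, x$config$rnn_units, x$config$rnn_layers,
              if (x$config$shared) ", branch weights shared" else ""))
  cat(sprintf("  buffer units: %d; dense: %s\n", a$buffer_units,
              paste(a$dense_units, collapse = " -> ")))
  cat(sprintf("  trainable parameters: %s\n", format(a$parameters, big.mark = ",")))
  invisible(x)
}

# number of scalars in a nested parameter tree
.tree_count <- function(p) {
  if (is.list(p)) sum(vapply(p, .tree_count, numeric(1))) else length(p)
}

#' Count trainable parameters
#' @param params a `ytype_params`.
#' @return integer scalar.
#' @export
count_parameters <- function(params) {
  .tree_count(params[c("branch_a", "branch_b", "buffer", "dense")])
}

#' Structural audit of a built model
#'
#' @param params a `ytype_params`.
#' @return list with `input_units`, `rnn_units_total` (units per layer x
#'   2 branches x layers), `buffer_units`, `dense_units`, `parameters`.
#' @export
model_audit <- function(params) {
  cfg <- params$config
  list(input_units = 2L * cfg$steps_per_protein * cfg$channels_per_step,
       rnn_units_total = cfg$rnn_units * 2L * cfg$rnn_layers,
       buffer_units = cfg$buffer_units,
       dense_units = cfg$dense_units,
       parameters = count_parameters(params))
}

# Full forward pass. Returns softmax probabilities and, when
# `keep_cache`, everything needed for the backward pass.
.ytype_forward <- function(params, x, keep_cache = FALSE) {
  cfg <- params$config
  H <- cfg$rnn_units %/% 2L
  st <- .pair_to_steps(x, cfg)
  layers_b <- if (cfg$shared) params$branch_a else params$branch_b
  fa <- .branch_forward(st$a, params$branch_a, H)
  fb <- .branch_forward(st$b, layers_b, H)
  if (cfg$buffer_mode == "per_branch") {
    za <- sweep(fa$terminal %*% params$buffer$W, 2L, params$buffer$b, "+")
    zb <- sweep(fb$terminal %*% params$buffer$W, 2L, params$buffer$b, "+")
    buf <- cbind(relu(za), relu(zb))
    bufcache <- list(za = za, zb = zb)
  } else {
    zj <- sweep(cbind(fa$terminal, fb$terminal) %*% params$buffer$W,
                2L, params$buffer$b, "+")
    buf <- relu(zj)
    bufcache <- list(zj = zj)
  }
  acts <- list(buf)
  zs <- list()
  a <- buf
  nd <- length(params$dense)
  for (k in seq_len(nd)) {
    z <- sweep(a %*% params$dense[[k]]$W, 2L, params$dense[[k]]$b, "+")
    zs[[k]] <- z
    a <- if (k < nd) relu(z) else z
    acts[[k + 1L]] <- a
  }
  logits <- a
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  if (!keep_cache) return(list(probs = probs))
  list(probs = probs, fa = fa, fb = fb, bufcache = bufcache,
       acts = acts, zs = zs)
}

# Full backward pass -> gradient tree matching the parameter tree.
.ytype_backward <- function(params, fwd, y) {
  cfg <- params$config
  H <- cfg$rnn_units %/% 2L
  n <- nrow(y)
  nd <- length(params$dense)
  dgrad_dense <- vector("list", nd)
  dz <- (fwd$probs - y) / n
  for (k in nd:1) {
    a_in <- fwd$acts[[k]]
    dgrad_dense[[k]] <- list(W = crossprod(a_in, dz), b = colSums(dz))
    da <- dz %*% t(params$dense[[k]]$W)
    if (k > 1L) dz <- da * (fwd$zs[[k - 1L]] > 0)
  }
  dbuf <- da                            # gradient w.r.t. buffer output
  if (cfg$buffer_mode == "per_branch") {
    hw <- cfg$buffer_units %/% 2L
    dza <- dbuf[, 1:hw, drop = FALSE] * (fwd$bufcache$za > 0)
    dzb <- dbuf[, (hw + 1):(2 * hw), drop = FALSE] * (fwd$bufcache$zb > 0)
    dbuffer <- list(W = crossprod(fwd$fa$terminal, dza) +
                        crossprod(fwd$fb$terminal, dzb),
                    b = colSums(dza) + colSums(dzb))
    dterm_a <- dza %*% t(params$buffer$W)
    dterm_b <- dzb %*% t(params$buffer$W)
  } else {
    dzj <- dbuf * (fwd$bufcache$zj > 0)
    dbuffer <- list(W = crossprod(cbind(fwd$fa$terminal, fwd$fb$terminal), dzj),
                    b = colSums(dzj))
    dterm <- dzj %*% t(params$buffer$W)
    k <- 2L * H
    dterm_a <- dterm[, 1:k, drop = FALSE]
    dterm_b <- dterm[, (k + 1):(2 * k), drop = FALSE]
  }
  layers_b <- if (cfg$shared) params$branch_a else params$branch_b
  ga <- .branch_backward(dterm_a, params$branch_a, fwd$fa$caches, H)
  gb <- .branch_backward(dterm_b, layers_b, fwd$fb$caches, H)
  if (cfg$shared) {
    branch_a <- .tree_map2(ga, gb, `+`)
    branch_b <- NULL
  } else {
    branch_a <- ga
    branch_b <- gb
  }
  list(branch_a = branch_a, branch_b = branch_b,
       buffer = dbuffer, dense = dgrad_dense)
}

# elementwise combination of two parameter trees of identical shape
.tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- Map(function(u, v) .tree_map2(u, v, f), a, b)
    attributes(out) <- attributes(a)
    out
  } else f(a, b)
}

.tree_scale <- function(a, s) {
  if (is.list(a)) lapply(a, .tree_scale, s = s) else a * s
}

.tree_zeros <- function(a) .tree_scale(a, 0)

# cross-entropy of softmax probabilities against one-hot targets
.xent <- function(probs, y) {
  -mean(log(rowSums(probs * y) + 1e-12))
}

#' Train the Y-type model by mini-batch gradient descent
#'
#' Minimizes softmax cross-entropy with plain SGD (optional momentum) at
#' the configured batch size and learning rate. Deterministic for a
#' given config seed. With shared branches, the gradients of the two
#' branches accumulate into the single shared storage.
#'
#' @param params a `ytype_params` from [build_model()].
#' @param x n x 1200 pair-feature matrix (training split, normally
#'   augmented with [augment_forward_backward()]).
#' @param y n x 2 one-hot label matrix.
#' @param epochs number of passes over the data (default from config).
#' @param verbose print per-epoch loss.
#' @return list with updated `params` and a `history` data frame
#'   (epoch, loss, accuracy).
#' @export
ytype_train <- function(params, x, y, epochs = params$config$epochs,
                        verbose = FALSE) {
  stopifnot(inherits(params, "ytype_params"))
  if (!is.matrix(x) || nrow(x) == 0L) stop("empty training data")
  if (!is.matrix(y) || nrow(y) != nrow(x) || ncol(y) != 2L)
    stop("`y` must be an n x 2 one-hot matrix matching `x`")
  cfg <- params$config
  n <- nrow(x)
  trainable <- c("branch_a", if (!cfg$shared) "branch_b", "buffer", "dense")
  vel <- if (cfg$momentum > 0) .tree_zeros(params[trainable]) else NULL
  hist_loss <- numeric(0); hist_acc <- numeric(0)
  set.seed(cfg$seed + 1L)
  ep <- 0L
  while (ep < epochs) {
    ep <- ep + 1L
    perm <- sample.int(n)
    starts <- seq.int(1L, n, by = cfg$batch_size)
    ep_loss <- 0; ep_hits <- 0
    for (s in starts) {
      idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]; yb <- y[idx, , drop = FALSE]
      fwd <- .ytype_forward(params, xb, keep_cache = TRUE)
      loss <- .xent(fwd$probs, yb)
      if (!is.finite(loss))
        stop("divergence: non-finite loss at epoch ", ep)
      ep_loss <- ep_loss + loss * length(idx)
      ep_hits <- ep_hits + sum(max.col(fwd$probs) == max.col(yb))
      if (cfg$learning_rate > 0) {
        g <- .ytype_backward(params, fwd, yb)
        g <- g[trainable]
        if (!is.null(vel)) {
          vel <- .tree_map2(.tree_scale(vel, cfg$momentum), g, `+`)
          g <- vel
        }
        params[trainable] <- .tree_map2(
          params[trainable], .tree_scale(g, cfg$learning_rate), `-`)
      }
    }
    hist_loss <- c(hist_loss, ep_loss / n)
    hist_acc <- c(hist_acc, ep_hits / n)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep,
                      ep_loss / n, ep_hits / n))
    if (!is.null(cfg$early_stop_acc) && ep_hits / n >= cfg$early_stop_acc)
      break
  }
  list(params = params,
       history = data.frame(epoch = seq_along(hist_loss),
                            loss = hist_loss, accuracy = hist_acc))
}

#' Score protein pairs with a Y-type model
#'
#' @param params a `ytype_params`.
#' @param x n x 1200 pair-feature matrix.
#' @param symmetric average the scores of the (A,B) and (B,A) input
#'   orders (defaults to the config), making the score exactly
#'   order-invariant.
#' @return list with `score` (probability of the interacting class),
#'   `class` (1 = interacting, 0 = not; ties at exactly 0.5 resolve to
#'   non-interacting) and the n x 2 `probs`.
#' @export
ytype_predict <- function(params, x,
                          symmetric = params$config$symmetric_inference) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  probs <- .ytype_forward(params, x)$probs
  if (symmetric) {
    xs <- x[, c(601:1200, 1:600), drop = FALSE]
    probs <- (probs + .ytype_forward(params, xs)$probs) / 2
  }
  score <- probs[, 1L]
  list(score = score, class = as.integer(score > 0.5), probs = probs)
}
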