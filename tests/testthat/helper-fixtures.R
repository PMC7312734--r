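# Shared fixtures and independent oracles.

# Desk-scale training configuration: small weight-shared net, SGD with
# momentum, early stop once the training set is fit. Used wherever a
# model actually has to learn within a test's time budget.
desk_config <- function(seed = 1L, epochs = 50L, ...) {
  model_config(rnn_units = 16L, rnn_layers = 1L, buffer_units = 32L,
               dense_units = c(32L, 8L, 2L), batch_size = 32L,
               learning_rate = 0.05, momentum = 0.9, epochs = epochs,
               seed = seed, early_stop_acc = 1.0, ...)
}

.fixture_env <- new.env(parent = emptyenv())

# Small synthetic dataset (16 proteins, short chains, 40 pairs),
# featurized once per test run.
tiny_dataset <- function() {
  if (is.null(.fixture_env$tiny)) {
    cfg <- synthetic_config(n_proteins = 16L, length_range = c(64L, 120L),
                            n_pairs = 40L, seed = 101L)
    sim <- simulate_ppi_data(cfg)
    .fixture_env$tiny <- list(sim = sim,
                              features = featurize_proteins(sim$sequences))
  }
  .fixture_env$tiny
}

# The planted-rule study set: 400 noise-free pairs over 60 proteins.
study_dataset <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- synthetic_config(n_proteins = 60L, n_pairs = 400L,
                            noise_rate = 0, seed = 11L)
    sim <- simulate_ppi_data(cfg)
    .fixture_env$study <- list(sim = sim,
                               features = featurize_proteins(sim$sequences))
  }
  .fixture_env$study
}

# --- independent oracles -------------------------------------------------

# Subsequence statistics by exhaustive scanning (no order()/rank()):
# repeatedly pick the largest |value| not yet taken, earlier index wins.
oracle_subseq_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  sdev <- sqrt(sum((x - mu)^2) / n)
  taken <- rep(FALSE, n)
  vals <- numeric(0); locs <- numeric(0)
  for (k in seq_len(min(4L, n))) {
    best <- 0L
    for (i in seq_len(n)) {
      if (taken[i]) next
      if (best == 0L || abs(x[i]) > abs(x[best])) best <- i
    }
    taken[best] <- TRUE
    vals <- c(vals, x[best]); locs <- c(locs, best / n)
  }
  if (n < 4L) { vals <- c(vals, rep(0, 4L - n)); locs <- c(locs, rep(0, 4L - n)) }
  list(mean = mu, sd = sdev, top_values = vals, top_locations = locs)
}

# CWT singular values by direct construction: explicit per-position
# correlation sums against the Ricker wavelet, then a base SVD.
oracle_cwt_sv <- function(x, scales = 1:25) {
  L <- length(x)
  m <- matrix(0, L, length(scales))
  for (k in seq_along(scales)) {
    a <- scales[k]
    M <- min(10L * a, L)
    t <- seq_len(M) - 1 - (M - 1) / 2
    psi <- 2 / (sqrt(3 * a) * pi^0.25) * (1 - (t / a)^2) * exp(-t^2 / (2 * a^2))
    off <- (M - 1L) %/% 2L
    for (p in seq_len(L)) {
      # full-convolution element at index p + off: sum_j psi[j] x[p + off - j + 1]
      q <- p + off - seq_len(M) + 1L
      ok <- q >= 1L & q <= L
      m[p, k] <- sum(psi[ok] * x[q[ok]])
    }
  }
  sv <- svd(m, nu = 0, nv = 0)$d
  if (length(sv) < length(scales)) sv <- c(sv, rep(0, length(scales) - length(sv)))
  sv
}

rel_err <- function(a, b) {
  abs(a - b) / pmax(abs(a) + abs(b), 1e-8)
}
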