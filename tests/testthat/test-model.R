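test_that("ReLU clamps at zero", {
  expect_identical(relu(-3), 0)
  expect_identical(relu(0), 0)
  expect_identical(relu(2.5), 2.5)
  m <- matrix(c(-1, 2, 0, -0.5), 2)
  expect_equal(relu(m), matrix(c(0, 2, 0, 0), 2))
})

zero_cell_params <- function(H, D) {
  W <- matrix(0, H, H + D)
  list(W_f = W, W_i = W, W_C = W, W_o = W,
       b_f = rep(0, H), b_i = rep(0, H), b_C = rep(0, H), b_o = rep(0, H))
}

test_that("all-zero LSTM parameters force half-open gates", {
  H <- 2L; D <- 3L
  p <- zero_cell_params(H, D)
  c_prev <- c(0.4, -1.2)
  out <- lstm_step(rnorm(D), rep(0, H), c_prev, p)
  # f = i = o = sigmoid(0) = 0.5, candidate tanh(0) = 0
  expect_equal(out$c, 0.5 * c_prev)
  expect_equal(out$h, 0.5 * tanh(0.5 * c_prev))
  out0 <- lstm_step(rnorm(D), rep(0, H), rep(0, H), p)
  expect_equal(out0$h, rep(0, H))
})

test_that("lstm_step matches a hand-coded scalar evaluation of the gate equations", {
  set.seed(99)
  H <- 3L; D <- 4L
  p <- list(W_f = matrix(rnorm(H * (H + D)), H), W_i = matrix(rnorm(H * (H + D)), H),
            W_C = matrix(rnorm(H * (H + D)), H), W_o = matrix(rnorm(H * (H + D)), H),
            b_f = rnorm(H), b_i = rnorm(H), b_C = rnorm(H), b_o = rnorm(H))
  x <- rnorm(D); h0 <- rnorm(H); c0 <- rnorm(H)
  got <- lstm_step(x, h0, c0, p)
  # independent elementwise evaluation
  hx <- c(h0, x)
  sig <- function(z) 1 / (1 + exp(-z))
  h_ref <- numeric(H); c_ref <- numeric(H)
  for (k in seq_len(H)) {
    f_k <- sig(sum(p$W_f[k, ] * hx) + p$b_f[k])
    i_k <- sig(sum(p$W_i[k, ] * hx) + p$b_i[k])
    g_k <- tanh(sum(p$W_C[k, ] * hx) + p$b_C[k])
    o_k <- sig(sum(p$W_o[k, ] * hx) + p$b_o[k])
    c_ref[k] <- f_k * c0[k] + i_k * g_k
    h_ref[k] <- o_k * tanh(c_ref[k])
  }
  expect_equal(got$h, h_ref, tolerance = 1e-12)
  expect_equal(got$c, c_ref, tolerance = 1e-12)
  expect_error(lstm_step(x, h0, c0[-1], p), "c_prev")
})

test_that("the fused batched cell agrees with the equation-form step", {
  set.seed(17)
  H <- 3L; D <- 5L
  cell <- ppiwave:::.init_cell(D, H)
  xs <- list(matrix(rnorm(2 * D), 2), matrix(rnorm(2 * D), 2))
  fw <- ppiwave:::.lstm_dir_forward(xs, cell, 1:2, H)
  gates <- ppiwave:::.split_cell(cell, H)
  for (b in 1:2) {
    s1 <- lstm_step(xs[[1]][b, ], rep(0, H), rep(0, H), gates)
    s2 <- lstm_step(xs[[2]][b, ], s1$h, s1$c, gates)
    expect_equal(fw$hs[[1]][b, ], s1$h, tolerance = 1e-12)
    expect_equal(fw$h_last[b, ], s2$h, tolerance = 1e-12)
  }
})

test_that("descriptors unstack to 75 steps x 8 channels and back", {
  cfg <- model_config()
  set.seed(4)
  v <- rnorm(600)
  m <- reshape_for_rnn(v, cfg)
  expect_identical(dim(m), c(75L, 8L))
  expect_equal(flatten_from_rnn(m), v)                 # exact round trip
  for (case in list(c(1, 1), c(75, 1), c(13, 5), c(75, 8)))
    expect_identical(m[case[1], case[2]], v[75 * (case[2] - 1) + case[1]])
  # constant property block -> constant channel
  v2 <- rep(seq_len(8), each = 75)
  expect_true(all(apply(reshape_for_rnn(v2, cfg), 2, function(col)
    length(unique(col)) == 1L)))
  expect_error(reshape_for_rnn(rnorm(599), cfg), "600")
})

test_that("the default architecture audits to the published constants", {
  m <- build_model(model_config(seed = 1))
  a <- model_audit(m)
  expect_identical(a$input_units, 1200L)
  expect_identical(a$rnn_units_total, 2048L)   # 512 x 2 branches x 2 layers
  expect_identical(a$buffer_units, 256L)
  expect_identical(a$dense_units, c(32L, 8L, 2L))
})

test_that("config invariants are enforced", {
  expect_error(model_config(dense_units = c(32, 8, 3)), "end in 2")
  expect_error(model_config(steps_per_protein = 60, channels_per_step = 8),
               "600")
  expect_error(model_config(rnn_units = 7), "rnn_units")
})

test_that("branches share one parameter storage: equal inputs, equal outputs", {
  cfg <- desk_config(seed = 2)
  m <- build_model(cfg)
  set.seed(6)
  f <- rnorm(600)
  x <- matrix(c(f, f), nrow = 1)               # same protein on both branches
  st <- ppiwave:::.pair_to_steps(x, cfg)
  H <- cfg$rnn_units %/% 2L
  ta <- ppiwave:::.branch_forward(st$a, m$branch_a, H)$terminal
  tb <- ppiwave:::.branch_forward(st$b, m$branch_a, H)$terminal
  expect_identical(ta, tb)                     # bit-for-bit

  # still identical after genuine training steps
  tiny <- tiny_dataset()
  ps <- augment_forward_backward(build_pair_features(tiny$features, tiny$sim$pairs))
  tr <- ytype_train(m, ps$x, ps$y, epochs = 2L)
  st2 <- ppiwave:::.pair_to_steps(x, cfg)
  ta2 <- ppiwave:::.branch_forward(st2$a, tr$params$branch_a, H)$terminal
  tb2 <- ppiwave:::.branch_forward(st2$b, tr$params$branch_a, H)$terminal
  expect_identical(ta2, tb2)
})

test_that("weight sharing halves the recurrent parameter budget", {
  shared <- build_model(desk_config(seed = 1))
  control <- build_model(model_config(rnn_units = 16L, rnn_layers = 1L,
                                      buffer_units = 32L, batch_size = 32L,
                                      shared = FALSE, seed = 1))
  n_shared <- count_parameters(shared)
  n_control <- count_parameters(control)
  expect_lt(n_shared, n_control)
  branch <- ppiwave:::.tree_count(shared$branch_a)
  expect_identical(n_control - n_shared, branch)
})

test_that("softmax outputs are proper probabilities; zeroed head scores 0.5", {
  cfg <- desk_config(seed = 3)
  m <- build_model(cfg)
  set.seed(10)
  x <- matrix(rnorm(5 * 1200), 5)
  probs <- ppiwave:::.ytype_forward(m, x)$probs
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-9)
  last <- length(m$dense)
  m$dense[[last]]$W[] <- 0
  m$dense[[last]]$b[] <- 0
  pr <- ytype_predict(m, x, symmetric = FALSE)
  expect_equal(pr$score, rep(0.5, 5))
  expect_equal(pr$class, rep(0L, 5))          # ties resolve to non-interacting
})

test_that("zero epochs and zero learning rate leave parameters untouched", {
  cfg <- desk_config(seed = 5)
  m <- build_model(cfg)
  set.seed(11)
  x <- matrix(rnorm(8 * 1200), 8)
  y <- cbind(rep(c(1, 0), 4), rep(c(0, 1), 4))
  same_tree <- function(a, b) expect_equal(a[c("branch_a", "buffer", "dense")],
                                           b[c("branch_a", "buffer", "dense")])
  tr0 <- ytype_train(m, x, y, epochs = 0L)
  same_tree(tr0$params, m)
  cfg0 <- cfg; cfg0$learning_rate <- 0; cfg0$early_stop_acc <- NULL
  m0 <- build_model(cfg0, seed = 5)
  tr1 <- ytype_train(m0, x, y, epochs = 1L)
  same_tree(tr1$params, m0)
  expect_error(ytype_train(m, x[0, , drop = FALSE], y[0, , drop = FALSE]),
               "empty")
})

test_that("symmetric inference makes scores exactly order-invariant", {
  cfg <- desk_config(seed = 8)
  m <- build_model(cfg)
  set.seed(12)
  x <- matrix(rnorm(3 * 1200), 3)
  xs <- x[, c(601:1200, 1:600)]
  p1 <- ytype_predict(m, x, symmetric = TRUE)$score
  p2 <- ytype_predict(m, xs, symmetric = TRUE)$score
  expect_identical(p1, p2)
  # and equals the mean of the two directed scores
  d1 <- ytype_predict(m, x, symmetric = FALSE)$score
  d2 <- ytype_predict(m, xs, symmetric = FALSE)$score
  expect_equal(p1, (d1 + d2) / 2, tolerance = 1e-12)
})

test_that("training separates a linearly separable planted set", {
  set.seed(20)
  n <- 500L
  y1 <- rep(c(1L, 0L), length.out = n)
  mu <- ifelse(y1 == 1, 0.8, -0.8)
  x <- matrix(rnorm(n * 1200, mean = rep(mu, 1200)), nrow = n)
  cfg <- desk_config(seed = 4)
  m <- build_model(cfg)
  tr <- ytype_train(m, x, cbind(y1, 1 - y1), epochs = 50L)
  expect_lte(nrow(tr$history), 50L)
  expect_gte(utils::tail(tr$history$accuracy, 1), 0.95)
  # loss trends down on a separable problem
  h <- tr$history$loss
  expect_lt(utils::tail(h, 1), h[1])
})

test_that("fits are reproducible and expose the standard methods", {
  tiny <- tiny_dataset()
  ps <- build_pair_features(tiny$features, tiny$sim$pairs)
  cfg <- desk_config(seed = 6, epochs = 5L)
  f1 <- ppi_fit(ps, cfg)
  f2 <- ppi_fit(ps, cfg)
  expect_identical(f1$fitted, f2$fitted)     # bit-stable given the seed
  expect_s3_class(f1, "ppi_fit")
  expect_length(residuals(f1), nrow(ps$x))
  expect_equal(residuals(f1), ps$y[, 1] - f1$fitted)
  cf <- coef(f1)
  expect_named(cf, c("branch_a", "buffer", "dense"))
  s <- summary(f1)
  expect_s3_class(s, "summary.ppi_fit")
  expect_true(s$training_metrics$accuracy >= 0 && s$training_metrics$accuracy <= 1)
  sims <- simulate(f1, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(length(f1$fitted), 3L))
  expect_true(all(sims %in% 0:1))
  # checkpoint round trip preserves predictions
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(f1, path)
  back <- load_model(path)
  te <- build_pair_features(tiny$features, tiny$sim$pairs, role = "test")
  expect_identical(predict(back, te), predict(f1, te))
})
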