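# Independent scalar-loop evaluation of the gate equations, used as the
# oracle for the vectorized cell.
scalar_cell_oracle <- function(x, h, c_prev, p) {
  H <- p$hidden_size
  hx <- c(h, x)
  hn <- cn <- numeric(H)
  gates <- matrix(0, H, 4)
  for (j in seq_len(H)) {
    zi <- p$b_i[j]; zf <- p$b_f[j]; zc <- p$b_c[j]; zo <- p$b_o[j]
    for (k in seq_along(hx)) {
      zi <- zi + p$W_i[j, k] * hx[k]
      zf <- zf + p$W_f[j, k] * hx[k]
      zc <- zc + p$W_c[j, k] * hx[k]
      zo <- zo + p$W_o[j, k] * hx[k]
    }
    i <- 1 / (1 + exp(-zi)); f <- 1 / (1 + exp(-zf))
    g <- tanh(zc); o <- 1 / (1 + exp(-zo))
    cn[j] <- f * c_prev[j] + i * g
    hn[j] <- o * tanh(cn[j])
    gates[j, ] <- c(i, f, g, o)
  }
  list(h = hn, c = cn, gates = gates)
}

test_that("all-zero parameters and state give half-open gates and zero output", {
  p <- lstm_params(3L, 4L, 5L, seed = 61L)
  for (nm in ecgwolf:::LSTM_PARAM_NAMES) p[[nm]] <- 0 * p[[nm]]
  st <- lstm_cell_step(c(1, -2, 3), list(h = numeric(4), c = numeric(4)), p)
  expect_identical(st$h, numeric(4))
  expect_identical(st$c, numeric(4))
  expect_identical(st$i, rep(0.5, 4))
  expect_identical(st$f, rep(0.5, 4))
  expect_identical(st$g, numeric(4))
})

test_that("the cell matches the scalar gate-equation oracle on 100 random draws", {
  set.seed(62)
  for (i in 1:100) {
    D <- sample(1:4, 1); H <- sample(1:5, 1)
    p <- lstm_params(D, H, 3L, seed = i)
    for (nm in c("b_i", "b_f", "b_c", "b_o")) p[[nm]] <- rnorm(H)
    x <- rnorm(D); h <- rnorm(H); cc <- rnorm(H)
    got <- lstm_cell_step(x, list(h = h, c = cc), p)
    want <- scalar_cell_oracle(x, h, cc, p)
    expect_lt(max(abs(got$h - want$h)), 1e-8)
    expect_lt(max(abs(got$c - want$c)), 1e-8)
    expect_true(all(got$i > 0 & got$i < 1))
    expect_true(all(got$f > 0 & got$f < 1))
    expect_true(all(got$o > 0 & got$o < 1))
    expect_true(all(abs(got$g) < 1))
  }
})

test_that("the vectorized training-path cell agrees with the reference cell", {
  set.seed(63)
  D <- 6L; H <- 7L; Tn <- 4L
  p <- lstm_params(D, H, 5L, seed = 63L)
  X <- array(rnorm(3 * Tn * D), dim = c(3, Tn, D))
  fwd <- ecgwolf:::lstm_forward(X, p)
  for (b in 1:3) {
    st <- list(h = numeric(H), c = numeric(H))
    for (t in seq_len(Tn)) st <- lstm_cell_step(X[b, t, ], st, p)
    expect_lt(max(abs(fwd$h[b, ] - st$h)), 1e-6)
  }
})

test_that("softmax is a stable, shift-invariant probability map", {
  expect_equal(softmax(rep(3, 5)), rep(0.2, 5))
  set.seed(64)
  for (i in 1:50) {
    z <- rnorm(sample(2:8, 1), sd = 10)
    pz <- softmax(z)
    expect_equal(sum(pz), 1, tolerance = 1e-12)
    expect_identical(which.max(pz), which.max(z))
    expect_equal(softmax(z + 123.4), pz, tolerance = 1e-12)
  }
  expect_equal(softmax(c(1000, 0)), c(1, 0))  # no overflow
})

test_that("sequence conversion subsets columns exactly", {
  fm <- make_cluster_fm(4, n_noise = 7, seed = 65)
  d <- ncol(fm$values)
  mask <- integer(d); mask[c(2, 5, 9)] <- 1L
  sq <- to_sequences(fm, mask)
  expect_identical(dim(sq$x), c(20L, 1L, 3L))
  expect_identical(matrix(sq$x[, 1, ], ncol = 3),
                   unname(fm$values[, c(2, 5, 9)]))
  idm <- rep(1L, d)
  expect_identical(matrix(to_sequences(fm, idm)$x[, 1, ], ncol = d),
                   unname(fm$values))
  expect_error(to_sequences(fm, integer(d)), class = "ecgwolf_argument_error")
})

test_that("training separates well-separated clusters and is seed-deterministic", {
  fm <- make_cluster_fm(100, n_classes = 5, amp = 5, seed = 66)
  sp <- split_70_15_15(nrow(fm$values), seed = 66)
  sub <- function(i) feature_matrix(fm$values[i, ], fm$feature_names, fm$labels[i])
  mask <- rep(1L, ncol(fm$values))
  tr <- to_sequences(sub(sp$train), mask)
  va <- to_sequences(sub(sp$validation), mask)
  cfg <- train_config(seed = 66L)
  m1 <- lstm_train(tr, fm$labels[sp$train], cfg, va, fm$labels[sp$validation])
  expect_gte(max(m1$history$train_acc), 0.95)
  expect_lt(m1$history$train_loss[nrow(m1$history)], m1$history$train_loss[1])
  m2 <- lstm_train(tr, fm$labels[sp$train], cfg, va, fm$labels[sp$validation])
  expect_identical(m1$history$train_loss[1], m2$history$train_loss[1])
  expect_identical(m1$params$W_i, m2$params$W_i)

  te <- to_sequences(sub(sp$test), mask)
  pr <- predict(m1, te)
  expect_gte(mean(pr$labels == fm$labels[sp$test]), 0.9)
  expect_equal(rowSums(pr$probs), rep(1, length(sp$test)), tolerance = 1e-9)
  expect_identical(predict(m1, te), pr)  # inference is deterministic
  expect_error(predict(m1, to_sequences(sub(sp$test), c(mask[-1], 0L))),
               class = "ecgwolf_argument_error")
})

test_that("validation history is complete and early stop fires after exactly patience checks", {
  fm <- make_cluster_fm(20, n_classes = 3, seed = 67)
  mask <- rep(1L, ncol(fm$values))
  sq <- to_sequences(fm, mask)
  # zero learning rate freezes the weights: the first check improves on Inf,
  # every later one is a non-improvement, so training must stop at 1 + patience
  cfg <- train_config(learning_rate = 0, dropout = 0, epochs = 30L,
                      early_stop_patience = 4L, seed = 67L)
  m <- lstm_train(sq, fm$labels, cfg, sq, fm$labels, n_classes = 3L)
  expect_identical(m$stopped_epoch, 5L)
  expect_identical(m$history$epoch, 1:5)
  expect_true(all(is.finite(m$history$val_loss)))
  expect_equal(stats::sd(m$history$val_loss), 0)
})

test_that("Adam with zero learning rate leaves weights unchanged; pure L2 decays them", {
  p <- lstm_params(2L, 2L, 3L, seed = 68L)
  zero_grads <- lapply(p[ecgwolf:::LSTM_PARAM_NAMES], function(w) 0 * w)
  st <- ecgwolf:::adam_init(p)
  frozen <- ecgwolf:::adam_step(p, zero_grads, st,
                                train_config(learning_rate = 0, l2 = 0.5))
  expect_identical(frozen$params$W_i, p$W_i)
  expect_identical(frozen$params$W_out, p$W_out)

  # pure-L2 objective: gradient is only the decay term; norms shrink monotonically
  cfg <- train_config(learning_rate = 0.01, l2 = 0.1)
  st <- ecgwolf:::adam_init(p)
  norms <- numeric(20)
  for (i in 1:20) {
    upd <- ecgwolf:::adam_step(p, lapply(p[ecgwolf:::LSTM_PARAM_NAMES],
                                         function(w) 0 * w), st, cfg)
    p <- upd$params; st <- upd$state
    norms[i] <- sqrt(sum(vapply(p[ecgwolf:::LSTM_WEIGHT_NAMES],
                                function(w) sum(w^2), numeric(1))))
  }
  expect_true(all(diff(norms) < 0))
})

test_that("raw segment windows can feed the sequence input directly", {
  set.seed(69)
  segs <- lapply(1:6, function(i) ecg_segment(rnorm(30), 360, label = (i %% 5) + 1L))
  sq <- raw_sequences(segs)
  expect_identical(dim(sq$x), c(6L, 30L, 1L))
  expect_identical(sq$x[3, , 1], segs[[3]]$samples)
})
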