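# LSTM classification head, written out from the gate equations:
#   i = sigma(W_i [h, x] + b_i)        input gate
#   f = sigma(W_f [h, x] + b_f)        forget gate
#   g = tanh (W_c [h, x] + b_c)        candidate cell state
#   C = f * C_prev + i * g             cell state update
#   o = sigma(W_o [h, x] + b_o)        output gate
#   h = o * tanh(C)                    hidden state
# followed by dropout, a dense layer over the last hidden state, and softmax.
# Trained with Adam + L2 weight decay, gradient-norm clipping, and
# validation-based early stopping. No external deep-learning framework is
# used: forward, backward (BPTT) and the optimizer live here.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' LSTM parameter set
#'
#' Allocates gate weight matrices `W_i, W_f, W_c, W_o` of shape
#' `hidden x (hidden + input)`, their bias vectors, and the dense output
#' layer, He-normal initialized (sd `sqrt(2 / fan_in)`), biases zero.
#'
#' @param input_size Feature dimension of each timestep.
#' @param hidden_size Number of LSTM units (default 50).
#' @param n_classes Output classes (default 5).
#' @param seed Seed for the initialization draw.
#' @export
lstm_params <- function(input_size, hidden_size = 50L, n_classes = 5L,
                        seed = 1L) {
  if (!is_count(input_size) || !is_count(hidden_size) || !is_count(n_classes)) {
    abort_arg("input_size, hidden_size and n_classes must be positive integers")
  }
  set.seed(seed)
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nc)), nr, nc)
  H <- hidden_size; D <- input_size
  structure(list(
    W_i = he(H, H + D), W_f = he(H, H + D), W_c = he(H, H + D), W_o = he(H, H + D),
    b_i = numeric(H), b_f = numeric(H), b_c = numeric(H), b_o = numeric(H),
    W_out = he(n_classes, H), b_out = numeric(n_classes),
    hidden_size = H, input_size = D, n_classes = as.integer(n_classes)
  ), class = "lstm_params")
}

#' One LSTM cell step
#'
#' Applies the gate equations to a single input vector and state. This is the
#' same cell the trainer uses; the tests hold it against an independent
#' scalar-loop evaluation of the equations.
#'
#' @param x Input vector of length `input_size`.
#' @param state List with `h` and `c`, each of length `hidden_size`.
#' @param p An [lstm_params()].
#' @return Updated state: list with `h`, `c`, and the gate activations
#'   (`i`, `f`, `g`, `o`).
#' @export
lstm_cell_step <- function(x, state, p) {
  if (length(x) != p$input_size) abort_arg("input dimension mismatch")
  if (length(state$h) != p$hidden_size || length(state$c) != p$hidden_size) {
    abort_arg("state dimension mismatch")
  }
  hx <- c(state$h, x)
  i <- sigmoid(as.numeric(p$W_i %*% hx) + p$b_i)
  f <- sigmoid(as.numeric(p$W_f %*% hx) + p$b_f)
  g <- tanh(as.numeric(p$W_c %*% hx) + p$b_c)
  cc <- f * state$c + i * g
  o <- sigmoid(as.numeric(p$W_o %*% hx) + p$b_o)
  h <- o * tanh(cc)
  list(h = h, c = cc, i = i, f = f, g = g, o = o)
}

#' Numerically stable softmax
#'
#' `P(k) = exp(z_k) / sum_n exp(z_n)` with max-shift; sums to 1 and is
#' invariant to adding a constant to all logits.
#'
#' @param logits Finite numeric vector.
#' @export
softmax <- function(logits) {
  check_finite(logits, "logits")
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam at learning rate 0.01,
#' batch size 100, 30 epochs, L2 factor 0.001, dropout 0.2, He-normal
#' initialization, early stopping after 6 validation checks without
#' improvement. Gradients are clipped to norm `clip_norm` as a stability
#' safeguard at this relatively high learning rate.
#'
#' @param learning_rate,batch_size,epochs,l2,dropout,early_stop_patience,seed
#'   Training hyperparameters.
#' @param hidden_size LSTM units (default 50).
#' @param clip_norm Global gradient-norm clip (default 1.0).
#' @export
train_config <- function(learning_rate = 0.01, batch_size = 100L, epochs = 30L,
                         l2 = 0.001, dropout = 0.2, hidden_size = 50L,
                         early_stop_patience = 6L, clip_norm = 1.0, seed = 1L) {
  if (dropout < 0 || dropout >= 1) abort_arg("dropout must be in [0, 1)")
  if (learning_rate < 0 || l2 < 0) abort_arg("learning_rate and l2 must be >= 0")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), l2 = l2, dropout = dropout,
                 hidden_size = as.integer(hidden_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 clip_norm = clip_norm, seed = as.integer(seed),
                 init = "he_normal", optimizer = "adam"),
            class = "train_config")
}

#' Convert a feature matrix to model-ready sequences
#'
#' Restricts columns to the selected mask and shapes each row as a length-1
#' sequence (`n x 1 x popcount` array), matching the construction where
#' selected feature vectors feed a sequence input layer.
#'
#' @param fm A [feature_matrix()].
#' @param bits 0/1 selection mask over its columns (at least one bit set).
#' @return List with `x` (3-D array), `labels`, `feature_names`.
#' @export
to_sequences <- function(fm, bits) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (sum(bits) < 1L) abort_arg("cannot build sequences from an empty mask")
  if (length(bits) != ncol(fm$values)) abort_arg("mask length must equal feature count")
  sel <- which(bits == 1L)
  X <- fm$values[, sel, drop = FALSE]
  arr <- array(X, dim = c(nrow(X), 1L, length(sel)))
  list(x = arr, labels = fm$labels, feature_names = fm$feature_names[sel])
}

#' Shape raw segments as temporal sequences
#'
#' The alternative sequence mode: each segment's sample window becomes a
#' `T x 1` sequence, so the LSTM sees the waveform itself rather than a
#' static feature vector.
#'
#' @param segments List of equal-length labeled [ecg_segment()]s.
#' @return List with `x` (`n x T x 1` array), `labels`, `feature_names`.
#' @export
raw_sequences <- function(segments) {
  if (!length(segments)) abort_arg("no segments")
  lens <- vapply(segments, function(s) length(s$samples), integer(1))
  if (length(unique(lens)) != 1L) abort_arg("segments must have equal lengths")
  X <- t(vapply(segments, `[[`, numeric(lens[1]), "samples"))
  list(x = array(X, dim = c(nrow(X), lens[1], 1L)),
       labels = vapply(segments, `[[`, integer(1), "label"),
       feature_names = "sample")
}

# Vectorized forward over a batch; X is B x T x D. Returns logits, probs and
# (when keep_cache) everything the backward pass needs.
lstm_forward <- function(X, p, drop_mask = NULL, keep_cache = FALSE) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- p$hidden_size
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    hx <- cbind(h, matrix(X[, t, ], nrow = B))
    i <- sigmoid(hx %*% t(p$W_i) + rep(p$b_i, each = B))
    f <- sigmoid(hx %*% t(p$W_f) + rep(p$b_f, each = B))
    g <- tanh(hx %*% t(p$W_c) + rep(p$b_c, each = B))
    o <- sigmoid(hx %*% t(p$W_o) + rep(p$b_o, each = B))
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    if (keep_cache) cache[[t]] <- list(hx = hx, i = i, f = f, g = g, o = o,
                                       c_prev = c_prev, c = cc, tc = tc)
  }
  h_drop <- if (is.null(drop_mask)) h else h * drop_mask
  logits <- h_drop %*% t(p$W_out) + rep(p$b_out, each = B)
  list(logits = logits, probs = row_softmax(logits), h = h, h_drop = h_drop,
       cache = cache)
}

# BPTT for the cross-entropy loss of the last-step output.
lstm_backward <- function(fwd, X, Y, p, drop_mask = NULL) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- p$hidden_size
  dlogits <- (fwd$probs - Y) / B
  grads <- list(W_out = t(dlogits) %*% fwd$h_drop, b_out = colSums(dlogits))
  dh <- dlogits %*% p$W_out
  if (!is.null(drop_mask)) dh <- dh * drop_mask
  for (nm in c("W_i", "W_f", "W_c", "W_o")) grads[[nm]] <- 0 * p[[nm]]
  for (nm in c("b_i", "b_f", "b_c", "b_o")) grads[[nm]] <- 0 * p[[nm]]
  dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    cc <- fwd$cache[[t]]
    do <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dzi <- di * cc$i * (1 - cc$i)
    dzf <- df * cc$f * (1 - cc$f)
    dzg <- dg * (1 - cc$g^2)
    dzo <- do * cc$o * (1 - cc$o)
    grads$W_i <- grads$W_i + t(dzi) %*% cc$hx
    grads$W_f <- grads$W_f + t(dzf) %*% cc$hx
    grads$W_c <- grads$W_c + t(dzg) %*% cc$hx
    grads$W_o <- grads$W_o + t(dzo) %*% cc$hx
    grads$b_i <- grads$b_i + colSums(dzi)
    grads$b_f <- grads$b_f + colSums(dzf)
    grads$b_c <- grads$b_c + colSums(dzg)
    grads$b_o <- grads$b_o + colSums(dzo)
    dh <- dzi %*% p$W_i[, 1:H, drop = FALSE] +
      dzf %*% p$W_f[, 1:H, drop = FALSE] +
      dzg %*% p$W_c[, 1:H, drop = FALSE] +
      dzo %*% p$W_o[, 1:H, drop = FALSE]
  }
  grads
}

LSTM_WEIGHT_NAMES <- c("W_i", "W_f", "W_c", "W_o", "W_out")
LSTM_PARAM_NAMES <- c(LSTM_WEIGHT_NAMES, "b_i", "b_f", "b_c", "b_o", "b_out")

adam_init <- function(p) {
  list(m = lapply(p[LSTM_PARAM_NAMES], function(w) 0 * w),
       v = lapply(p[LSTM_PARAM_NAMES], function(w) 0 * w), t = 0L)
}

# One Adam update (beta1 0.9, beta2 0.999, eps 1e-8) with L2 weight decay on
# the weight matrices and global gradient-norm clipping.
adam_step <- function(p, grads, state, cfg) {
  for (nm in LSTM_WEIGHT_NAMES) grads[[nm]] <- grads[[nm]] + cfg$l2 * p[[nm]]
  gn <- sqrt(sum(vapply(grads[LSTM_PARAM_NAMES],
                        function(g) sum(g^2), numeric(1))))
  if (is.finite(gn) && gn > cfg$clip_norm) {
    scale <- cfg$clip_norm / gn
    for (nm in LSTM_PARAM_NAMES) grads[[nm]] <- grads[[nm]] * scale
  }
  state$t <- state$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr_t <- cfg$learning_rate * sqrt(1 - b2^state$t) / (1 - b1^state$t)
  for (nm in LSTM_PARAM_NAMES) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    p[[nm]] <- p[[nm]] - lr_t * state$m[[nm]] / (sqrt(state$v[[nm]]) + eps)
  }
  list(params = p, state = state)
}

ce_loss <- function(probs, Y) {
  -mean(log(pmax(rowSums(probs * Y), 1e-12)))
}

one_hot <- function(labels, n_classes) {
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

#' Train the LSTM classifier
#'
#' Architecture: sequence input (selected-feature dimension) -> LSTM
#' (`hidden_size` units, last output) -> dropout -> dense(`n_classes`) ->
#' softmax, trained with mini-batch Adam under L2 weight decay and
#' cross-entropy loss. Validation loss is checked every epoch; training stops
#' after `early_stop_patience` checks without improvement and the
#' best-validation weights are restored. Fully seeded and reproducible.
#'
#' @param seqs Sequence set from [to_sequences()] or [raw_sequences()].
#' @param labels Integer class labels (1..n_classes) for the rows of `seqs`.
#' @param cfg A [train_config()].
#' @param val_seqs,val_labels Nonempty validation set in the same format.
#' @param n_classes Number of classes (default 5).
#' @return An object of class `lstm_classifier`: `params`, `feature_names`,
#'   `class_labels`, `history` (per-epoch data frame), `stopped_epoch`.
#' @export
lstm_train <- function(seqs, labels, cfg = train_config(),
                       val_seqs, val_labels, n_classes = 5L) {
  X <- seqs$x
  if (length(unique(labels)) < 2L) abort_arg("training labels must contain >= 2 classes")
  if (!length(val_labels)) abort_arg("validation set must be nonempty")
  # z-score per feature on the training set; heterogeneous feature scales
  # (energies vs texture measures) otherwise stall gradient training
  center <- apply(X, 3L, mean)
  scale <- apply(X, 3L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  standardize <- function(A) {
    for (j in seq_len(dim(A)[3])) A[, , j] <- (A[, , j] - center[j]) / scale[j]
    A
  }
  X <- standardize(X)
  set.seed(cfg$seed)
  p <- lstm_params(dim(X)[3], cfg$hidden_size, n_classes,
                   seed = stats::runif(1) * 1e6)
  opt <- adam_init(p)
  n <- dim(X)[1]
  Y <- one_hot(labels, n_classes)
  Xv <- standardize(val_seqs$x)
  Yv <- one_hot(val_labels, n_classes)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(),
                     val_acc = numeric())
  best_val <- Inf; best_p <- p; bad_checks <- 0L; stopped <- cfg$epochs
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    batch_losses <- numeric()
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[b0:min(b0 + cfg$batch_size - 1L, n)]
      Xb <- X[idx, , , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      dm <- if (cfg$dropout > 0) {
        matrix(stats::rbinom(length(idx) * p$hidden_size, 1L, 1 - cfg$dropout),
               length(idx), p$hidden_size) / (1 - cfg$dropout)
      } else NULL
      fwd <- lstm_forward(Xb, p, drop_mask = dm, keep_cache = TRUE)
      loss <- ce_loss(fwd$probs, Yb)
      if (!is.finite(loss)) {
        abort(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
              "ecgwolf_training_error")
      }
      batch_losses <- c(batch_losses, loss)
      grads <- lstm_backward(fwd, Xb, Yb, p, drop_mask = dm)
      upd <- adam_step(p, grads, opt, cfg)
      p <- upd$params; opt <- upd$state
    }
    tr <- lstm_forward(X, p)
    vl <- lstm_forward(Xv, p)
    val_loss <- ce_loss(vl$probs, Yv)
    hist <- rbind(hist, data.frame(
      epoch = epoch, train_loss = ce_loss(tr$probs, Y),
      train_acc = mean(max.col(tr$probs) == labels),
      val_loss = val_loss, val_acc = mean(max.col(vl$probs) == val_labels)))
    if (val_loss < best_val) {
      best_val <- val_loss; best_p <- p; bad_checks <- 0L
    } else {
      bad_checks <- bad_checks + 1L
      if (bad_checks >= cfg$early_stop_patience) { stopped <- epoch; break }
    }
    stopped <- epoch
  }
  structure(list(params = best_p, feature_names = seqs$feature_names,
                 class_labels = seq_len(n_classes), history = hist,
                 stopped_epoch = stopped, config = cfg,
                 center = center, scale = scale),
            class = "lstm_classifier")
}

#' Predict with a trained classifier
#'
#' Deterministic inference (dropout inactive): class probabilities from the
#' softmax layer and argmax labels.
#'
#' @param object An `lstm_classifier`.
#' @param seqs Sequence set with the model's feature dimension.
#' @param ... Unused.
#' @return List with `labels` (integer) and `probs` (n x classes matrix).
#' @export
predict.lstm_classifier <- function(object, seqs, ...) {
  X <- seqs$x
  if (dim(X)[3] != object$params$input_size) {
    abort_arg(sprintf("feature dimension %d does not match the model's %d",
                      dim(X)[3], object$params$input_size))
  }
  for (j in seq_len(dim(X)[3])) {
    X[, , j] <- (X[, , j] - object$center[j]) / object$scale[j]
  }
  fwd <- lstm_forward(X, object$params)
  list(labels = max.col(fwd$probs), probs = fwd$probs)
}

#' @export
print.lstm_classifier <- function(x, ...) {
  cat(sprintf("<lstm_classifier> %d features -> LSTM(%d) -> %d classes; trained %d epochs (val acc %.3f)\n",
              x$params$input_size, x$params$hidden_size, x$params$n_classes,
              x$stopped_epoch, utils::tail(x$history$val_acc, 1)))
  invisible(x)
}
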