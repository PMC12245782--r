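# Enhanced binary gray wolf optimization for wrapper feature selection.
# Each wolf is a bit vector over feature columns; fitness is the stratified
# 5-fold cross-validated accuracy of a K-nearest-neighbour classifier on the
# selected columns. Continuous wolf positions are retained between iterations
# and binarized through a sigmoid transfer for evaluation; the three
# best-ever distinct wolves lead the pack, and the exploration parameter `a`
# decays linearly across iterations. A binary PSO and a budget-matched random
# search with the identical fitness are provided as comparison baselines.

#' EGWO configuration
#'
#' @param num_wolves Pack size (>= 3; alpha/beta/delta must exist). Default 30.
#' @param max_iter Iteration budget. Default 100.
#' @param init_k Bits set per wolf at initialization (capped at the feature
#'   count d). Default 30.
#' @param knn_k Neighbours for the KNN fitness classifier. Default 5.
#' @param cv_folds Stratified CV folds for the fitness. Default 5.
#' @param a_start,a_end Linear schedule of the exploration parameter
#'   (2 -> 0 by default).
#' @param transfer_steepness Sigmoid transfer steepness lambda in
#'   `S(x) = 1/(1 + exp(-lambda (x - 0.5)))`. Default 10.
#' @param seed Integer seed; all randomness of a run flows from it.
#' @export
egwo_config <- function(num_wolves = 30L, max_iter = 100L, init_k = 30L,
                        knn_k = 5L, cv_folds = 5L,
                        a_start = 2, a_end = 0,
                        transfer_steepness = 10, seed = 1L) {
  if (!is_count(num_wolves) || num_wolves < 3L) abort_arg("num_wolves must be >= 3")
  if (!is.numeric(max_iter) || max_iter < 0) abort_arg("max_iter must be >= 0")
  if (!is_count(init_k)) abort_arg("init_k must be a positive integer")
  if (!is_count(cv_folds) || cv_folds < 2L) abort_arg("cv_folds must be >= 2")
  structure(list(num_wolves = as.integer(num_wolves),
                 max_iter = as.integer(max_iter),
                 init_k = as.integer(init_k), knn_k = as.integer(knn_k),
                 cv_folds = as.integer(cv_folds),
                 a_start = a_start, a_end = a_end,
                 transfer_steepness = transfer_steepness,
                 seed = as.integer(seed)),
            class = "egwo_config")
}

#' Linear schedule of the exploration parameter a
#'
#' `a` runs from `a_start` at the first iteration to `a_end` at the last,
#' in equal decrements.
#'
#' @param cfg An [egwo_config()].
#' @return Numeric vector of length `cfg$max_iter`.
#' @export
a_schedule <- function(cfg) {
  if (cfg$max_iter == 0L) return(numeric())
  if (cfg$max_iter == 1L) return(cfg$a_start)
  seq(cfg$a_start, cfg$a_end, length.out = cfg$max_iter)
}

transfer_sigmoid <- function(x, steepness) 1 / (1 + exp(-steepness * (x - 0.5)))

#' Initialize the wolf population
#'
#' `num_wolves` binary masks, each with exactly `min(init_k, d)` bits set,
#' chosen uniformly without replacement.
#'
#' @param d Number of features (>= 1).
#' @param cfg An [egwo_config()]; its seed makes the population reproducible.
#' @return List of 0/1 integer vectors of length `d`.
#' @export
init_population <- function(d, cfg) {
  if (!is_count(d)) abort_arg("d must be a positive integer")
  set.seed(cfg$seed)
  k <- min(cfg$init_k, d)
  lapply(seq_len(cfg$num_wolves), function(i) {
    bits <- integer(d)
    bits[sample.int(d, k)] <- 1L
    bits
  })
}

#' Repair a degenerate mask
#'
#' A wolf that selects no features is replaced by a uniformly random mask
#' whose popcount is drawn uniformly from `1..min(init_k, d)`; any nonzero
#' mask is returned unchanged.
#'
#' @param bits 0/1 integer vector.
#' @param cfg An [egwo_config()].
#' @export
repair_mask <- function(bits, cfg) {
  if (sum(bits) >= 1L) return(bits)
  d <- length(bits)
  k <- sample.int(min(cfg$init_k, d), 1L)
  out <- integer(d)
  out[sample.int(d, k)] <- 1L
  out
}

# Stratified fold assignment, fixed once per run for a deterministic fitness.
stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (k in unique(labels)) {
    idx <- which(labels == k)
    if (length(idx) < folds) {
      abort_arg(sprintf("class %s has %d rows, fewer than %d folds",
                        k, length(idx), folds))
    }
    assign[idx[sample.int(length(idx))]] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' KNN cross-validation fitness of a feature mask
#'
#' Mean stratified k-fold cross-validated accuracy of a K-nearest-neighbour
#' classifier restricted to the selected feature columns; in `[0, 1]`.
#'
#' @param bits 0/1 mask with at least one bit set (repair first if needed).
#' @param fm A [feature_matrix()].
#' @param cfg An [egwo_config()].
#' @param folds Optional precomputed fold assignment (1..cv_folds per row);
#'   computed from `cfg$seed` when missing.
#' @export
fitness_knn_cv <- function(bits, fm, cfg, folds = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (sum(bits) < 1L) abort_arg("fitness of an empty mask is undefined; repair first")
  if (length(bits) != ncol(fm$values)) abort_arg("mask length must equal feature count")
  if (is.null(folds)) {
    set.seed(cfg$seed)
    folds <- stratified_folds(fm$labels, cfg$cv_folds)
  }
  X <- fm$values[, bits == 1L, drop = FALSE]
  y <- factor(fm$labels)
  acc <- vapply(seq_len(cfg$cv_folds), function(f) {
    tr <- folds != f
    pred <- class::knn(X[tr, , drop = FALSE], X[!tr, , drop = FALSE],
                       y[tr], k = cfg$knn_k)
    mean(pred == y[!tr])
  }, numeric(1))
  mean(acc)
}

# Leader bookkeeping: keep the three best-ever distinct masks, ordered by
# fitness (desc), then popcount (asc, parsimony), then first-seen.
better_than <- function(fit_a, pop_a, fit_b, pop_b) {
  fit_a > fit_b || (fit_a == fit_b && pop_a < pop_b)
}

update_leaders <- function(leaders, bits, fit) {
  key <- paste(bits, collapse = "")
  for (i in seq_along(leaders)) {
    if (!is.null(leaders[[i]]) && leaders[[i]]$key == key) {
      return(leaders)  # already a leader; best-ever fitness already recorded
    }
  }
  cand <- list(bits = bits, fitness = fit, popcount = sum(bits), key = key)
  for (i in seq_along(leaders)) {
    L <- leaders[[i]]
    if (is.null(L) || better_than(fit, cand$popcount, L$fitness, L$popcount)) {
      leaders <- append(leaders[-length(leaders)], list(cand), after = i - 1L)
      return(leaders)
    }
  }
  leaders
}

#' One position update of the pack
#'
#' Canonical gray-wolf continuous update toward the three leaders
#' (`A = a (2 r1 - 1)`, `C = 2 r2`, `D = |C x_L - x|`, `X_L = x_L - A D`,
#' candidate = mean of the three pulls) followed by bitwise sigmoid-transfer
#' binarization (`bit = 1` iff `S(candidate_j) > r3`) and repair of empty
#' masks.
#'
#' @param positions List of continuous position vectors (one per wolf).
#' @param alpha,beta,delta Leader bit vectors.
#' @param a Exploration parameter in `[0, a_start]`.
#' @param cfg An [egwo_config()].
#' @return List with `positions` (continuous, retained for the next
#'   iteration) and `masks` (repaired 0/1 vectors).
#' @export
update_positions <- function(positions, alpha, beta, delta, a, cfg) {
  d <- length(alpha)
  leaders <- list(alpha, beta, delta)
  masks <- vector("list", length(positions))
  for (w in seq_along(positions)) {
    x <- positions[[w]]
    pulls <- vapply(leaders, function(xl) {
      A <- a * (2 * stats::runif(d) - 1)
      C <- 2 * stats::runif(d)
      D <- abs(C * xl - x)
      xl - A * D
    }, numeric(d))
    cand <- rowMeans(matrix(pulls, nrow = d))
    s <- transfer_sigmoid(cand, cfg$transfer_steepness)
    bits <- as.integer(s > stats::runif(d))
    masks[[w]] <- repair_mask(bits, cfg)
    positions[[w]] <- cand
  }
  list(positions = positions, masks = masks)
}

#' Run enhanced binary gray wolf feature selection
#'
#' Evaluates the initial pack, then iterates: update positions toward the
#' best-ever alpha/beta/delta wolves with `a` decaying linearly, binarize,
#' repair, re-evaluate, refresh leaders. Elitist: the alpha fitness never
#' decreases. Total fitness evaluations: `num_wolves * (max_iter + 1)`.
#'
#' @param fm A [feature_matrix()] with at least two classes.
#' @param cfg An [egwo_config()].
#' @return List of class `egwo_result`: `best_mask`, `best_fitness`,
#'   `convergence` (best-so-far per iteration), `n_evaluations`, `leaders`.
#' @export
run_egwo <- function(fm, cfg = egwo_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(unique(fm$labels)) < 2L) abort_arg("need at least two classes")
  d <- ncol(fm$values)
  masks <- init_population(d, cfg)  # seeds the RNG for the whole run
  folds <- stratified_folds(fm$labels, cfg$cv_folds)
  n_eval <- 0L
  leaders <- vector("list", 3L)
  evaluate_all <- function(mlist) {
    for (bits in mlist) {
      fit <- fitness_knn_cv(bits, fm, cfg, folds = folds)
      n_eval <<- n_eval + 1L
      leaders <<- update_leaders(leaders, bits, fit)
    }
  }
  evaluate_all(masks)
  # fewer than three distinct masks seen so far (e.g. a saturated init when
  # init_k >= d): unfilled leader slots fall back to the best mask
  leader_bits <- function(i) (leaders[[i]] %||% leaders[[1]])$bits
  positions <- lapply(masks, as.numeric)
  avals <- a_schedule(cfg)
  convergence <- numeric(cfg$max_iter)
  for (it in seq_len(cfg$max_iter)) {
    upd <- update_positions(positions, leader_bits(1L), leader_bits(2L),
                            leader_bits(3L), avals[it], cfg)
    positions <- upd$positions
    masks <- upd$masks
    evaluate_all(masks)
    convergence[it] <- leaders[[1]]$fitness
  }
  structure(list(best_mask = leaders[[1]]$bits,
                 best_fitness = leaders[[1]]$fitness,
                 convergence = convergence,
                 n_evaluations = n_eval,
                 leaders = leaders,
                 method = "egwo"),
            class = "egwo_result")
}

#' @export
print.egwo_result <- function(x, ...) {
  cat(sprintf("<%s_result> best fitness %.4f with %d/%d features, %d evaluations\n",
              x$method, x$best_fitness, sum(x$best_mask), length(x$best_mask),
              x$n_evaluations))
  invisible(x)
}

#' Binary particle swarm baseline
#'
#' Binary PSO with the same fitness, population size, iteration budget,
#' initialization and sigmoid transfer as [run_egwo()], for convergence-curve
#' comparison. Inertia decays linearly 0.9 -> 0.4; both acceleration
#' coefficients are 2.
#'
#' @inheritParams run_egwo
#' @return An `egwo_result` with `method = "bpso"`.
#' @export
run_bpso <- function(fm, cfg = egwo_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(unique(fm$labels)) < 2L) abort_arg("need at least two classes")
  d <- ncol(fm$values)
  masks <- init_population(d, cfg)
  folds <- stratified_folds(fm$labels, cfg$cv_folds)
  n_eval <- 0L
  fit_of <- function(bits) {
    n_eval <<- n_eval + 1L
    fitness_knn_cv(bits, fm, cfg, folds = folds)
  }
  fits <- vapply(masks, fit_of, numeric(1))
  pbest <- masks
  pbest_fit <- fits
  g <- which.max(fits)
  gbest <- masks[[g]]; gbest_fit <- fits[g]
  x <- lapply(masks, as.numeric)
  v <- lapply(masks, function(m) numeric(d))
  wts <- if (cfg$max_iter > 1) seq(0.9, 0.4, length.out = cfg$max_iter) else 0.9
  convergence <- numeric(cfg$max_iter)
  for (it in seq_len(cfg$max_iter)) {
    for (p in seq_along(x)) {
      r1 <- stats::runif(d); r2 <- stats::runif(d)
      v[[p]] <- wts[it] * v[[p]] + 2 * r1 * (pbest[[p]] - x[[p]]) +
        2 * r2 * (gbest - x[[p]])
      v[[p]] <- pmin(pmax(v[[p]], -4), 4)
      x[[p]] <- pmin(pmax(x[[p]] + v[[p]], 0), 1)
      s <- transfer_sigmoid(x[[p]], cfg$transfer_steepness)
      bits <- repair_mask(as.integer(s > stats::runif(d)), cfg)
      f <- fit_of(bits)
      if (f > pbest_fit[p]) { pbest[[p]] <- bits; pbest_fit[p] <- f }
      if (f > gbest_fit) { gbest <- bits; gbest_fit <- f }
    }
    convergence[it] <- gbest_fit
  }
  structure(list(best_mask = gbest, best_fitness = gbest_fit,
                 convergence = convergence, n_evaluations = n_eval,
                 leaders = NULL, method = "bpso"),
            class = "egwo_result")
}

#' Budget-matched random-search baseline
#'
#' Samples `num_wolves * (max_iter + 1)` masks from the repair distribution
#' (popcount uniform on `1..min(init_k, d)`) and keeps the best, using the
#' same fitness; the reference floor any guided search must beat.
#'
#' @inheritParams run_egwo
#' @return An `egwo_result` with `method = "random"`.
#' @export
run_random_search <- function(fm, cfg = egwo_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  d <- ncol(fm$values)
  set.seed(cfg$seed)
  folds <- stratified_folds(fm$labels, cfg$cv_folds)
  budget <- cfg$num_wolves * (cfg$max_iter + 1L)
  best <- NULL; best_fit <- -Inf
  convergence <- numeric(budget)
  for (i in seq_len(budget)) {
    bits <- repair_mask(integer(d), cfg)
    f <- fitness_knn_cv(bits, fm, cfg, folds = folds)
    if (f > best_fit || (f == best_fit && sum(bits) < sum(best))) {
      best <- bits; best_fit <- f
    }
    convergence[i] <- best_fit
  }
  structure(list(best_mask = best, best_fitness = best_fit,
                 convergence = convergence, n_evaluations = budget,
                 leaders = NULL, method = "random"),
            class = "egwo_result")
}
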