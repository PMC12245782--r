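test_that("initial wolves carry exactly min(init_k, d) bits and are seeded", {
  cfg <- egwo_config(num_wolves = 30L, init_k = 30L, seed = 41L)
  pop <- init_population(100L, cfg)
  expect_identical(length(pop), 30L)
  expect_true(all(vapply(pop, sum, integer(1)) == 30L))
  expect_identical(init_population(100L, cfg), pop)
  capped <- init_population(10L, cfg)
  expect_true(all(vapply(capped, sum, integer(1)) == 10L))
  expect_error(init_population(0L, cfg), class = "ecgwolf_argument_error")
})

test_that("repair replaces empty masks and leaves others alone", {
  cfg <- egwo_config(init_k = 10L, seed = 42L)
  set.seed(42)
  fixed <- repair_mask(integer(50), cfg)
  expect_gte(sum(fixed), 1L)
  expect_lte(sum(fixed), 10L)
  m <- c(1L, rep(0L, 49))
  expect_identical(repair_mask(m, cfg), m)
})

test_that("repaired popcounts are uniform on 1..init_k (chi-squared)", {
  cfg <- egwo_config(init_k = 8L, seed = 43L)
  set.seed(43)
  pops <- replicate(10000, sum(repair_mask(integer(40), cfg)))
  tab <- table(factor(pops, levels = 1:8))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("KNN CV fitness is 1 on separated clusters and equals a fold-loop oracle", {
  fm <- make_cluster_fm(20, n_classes = 2, n_noise = 3, amp = 10, seed = 44)
  cfg <- egwo_config(cv_folds = 5L, knn_k = 5L, seed = 44L)
  mask <- c(1L, rep(0L, ncol(fm$values) - 1L))
  expect_equal(fitness_knn_cv(mask, fm, cfg), 1.0)

  # full mask vs an explicit fold loop with the same folds
  set.seed(44)
  folds <- ecgwolf:::stratified_folds(fm$labels, 5L)
  full <- rep(1L, ncol(fm$values))
  got <- fitness_knn_cv(full, fm, cfg, folds = folds)
  accs <- numeric(5)
  for (f in 1:5) {
    tr <- folds != f
    pred <- class::knn(fm$values[tr, ], fm$values[!tr, ],
                       factor(fm$labels)[tr], k = 5)
    accs[f] <- mean(pred == factor(fm$labels)[!tr])
  }
  expect_equal(got, mean(accs), tolerance = 1e-12)
})

test_that("shuffled labels give chance-level fitness", {
  cfg <- egwo_config(seed = 45L)
  fits <- vapply(1:20, function(s) {
    set.seed(s)
    vals <- matrix(rnorm(100 * 3), 100, 3)
    labels <- sample(rep(1:5, each = 20))
    fm <- feature_matrix(vals, paste0("f", 1:3), labels)
    fitness_knn_cv(rep(1L, 3), fm, cfg)
  }, numeric(1))
  se <- stats::sd(fits) / sqrt(length(fits))
  expect_lte(abs(mean(fits) - 0.2), 3 * se + 1e-9)
})

test_that("fitness preconditions reject empty masks and thin classes", {
  fm <- make_cluster_fm(20, n_classes = 2)
  cfg <- egwo_config()
  expect_error(fitness_knn_cv(integer(ncol(fm$values)), fm, cfg),
               class = "ecgwolf_argument_error")
  thin <- feature_matrix(matrix(rnorm(12), 6, 2), c("a", "b"),
                         c(1L, 1L, 1L, 1L, 2L, 2L))
  expect_error(fitness_knn_cv(c(1L, 1L), thin, cfg),
               class = "ecgwolf_argument_error")
})

test_that("with a = 0 and unanimous leaders the continuous candidate is the leader", {
  cfg <- egwo_config(seed = 46L)
  set.seed(46)
  d <- 20L
  m <- as.integer(runif(d) < 0.5); m[1] <- 1L
  positions <- lapply(1:5, function(i) runif(d))
  upd <- update_positions(positions, m, m, m, a = 0, cfg)
  for (p in upd$positions) expect_equal(p, as.numeric(m), tolerance = 1e-15)
})

test_that("a steep transfer pins updated wolves to the leader (Monte Carlo)", {
  cfg <- egwo_config(transfer_steepness = 50, seed = 47L)
  set.seed(47)
  d <- 30L
  m <- as.integer(runif(d) < 0.5); m[1] <- 1L
  ham <- replicate(1000, {
    upd <- update_positions(list(runif(d)), m, m, m, a = 0, cfg)
    sum(upd$masks[[1]] != m)
  })
  expect_lte(mean(ham), 0.02 * d)
})

test_that("updated masks keep length d and popcount >= 1 under strong exploration", {
  cfg <- egwo_config(seed = 48L)
  set.seed(48)
  d <- 15L
  alpha <- c(1L, rep(0L, d - 1L))
  positions <- lapply(1:10, function(i) rnorm(d))
  upd <- update_positions(positions, alpha, alpha, alpha, a = 2, cfg)
  expect_true(all(vapply(upd$masks, length, integer(1)) == d))
  expect_true(all(vapply(upd$masks, sum, integer(1)) >= 1L))
})

test_that("a zero-iteration run returns the best initial wolf; budgets are exact", {
  fm <- make_cluster_fm(10, n_noise = 5, seed = 49)
  cfg <- egwo_config(num_wolves = 6L, max_iter = 0L, init_k = 4L, seed = 49L)
  res <- run_egwo(fm, cfg)
  expect_identical(res$convergence, numeric())
  expect_identical(res$n_evaluations, 6L)
  # replay the run's RNG stream: seeded init, then fold assignment
  pop <- init_population(ncol(fm$values), cfg)
  folds <- ecgwolf:::stratified_folds(fm$labels, cfg$cv_folds)
  fits <- vapply(pop, fitness_knn_cv, numeric(1), fm = fm, cfg = cfg, folds = folds)
  expect_equal(res$best_fitness, max(fits))
})

test_that("convergence is nondecreasing, elitist and budget-bounded", {
  fm <- make_cluster_fm(10, n_noise = 7, seed = 50)
  for (s in 1:3) {
    cfg <- egwo_config(num_wolves = 8L, max_iter = 10L, init_k = 5L, seed = s)
    res <- run_egwo(fm, cfg)
    expect_false(is.unsorted(res$convergence))
    expect_identical(length(res$convergence), 10L)
    expect_identical(res$n_evaluations, 8L * 11L)
    expect_equal(res$best_fitness, res$convergence[10])
    expect_gte(sum(res$best_mask), 1L)
  }
})

test_that("the exploration parameter decays linearly from a_start to a_end", {
  cfg <- egwo_config(max_iter = 5L)
  a <- a_schedule(cfg)
  expect_equal(a, c(2, 1.5, 1, 0.5, 0))
  expect_identical(a_schedule(egwo_config(max_iter = 0L)), numeric())
})

test_that("gray-wolf and PSO searches are reproducible under a fixed seed", {
  fm <- make_cluster_fm(10, n_noise = 5, seed = 51)
  cfg <- egwo_config(num_wolves = 6L, max_iter = 5L, init_k = 4L, seed = 51L)
  e1 <- run_egwo(fm, cfg); e2 <- run_egwo(fm, cfg)
  expect_identical(e1$convergence, e2$convergence)
  expect_identical(e1$best_mask, e2$best_mask)
  p1 <- run_bpso(fm, cfg); p2 <- run_bpso(fm, cfg)
  expect_identical(p1$convergence, p2$convergence)
  expect_false(is.unsorted(p1$convergence))
  expect_identical(p1$n_evaluations, 6L * 6L)
})
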