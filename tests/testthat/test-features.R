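test_that("segment energy matches the explicit sum of squares", {
  expect_identical(signal_energy(rep(0, 10)), 0)
  expect_identical(signal_energy(c(1, -1, 2)), 6)
  set.seed(31)
  for (i in 1:100) {
    x <- rnorm(sample(3:60, 1))
    acc <- 0
    for (v in x) acc <- acc + v^2
    expect_equal(signal_energy(x), acc, tolerance = 1e-12)
  }
  expect_error(signal_energy(numeric()), class = "ecgwolf_argument_error")
})

test_that("summary statistics use the population variance and agree with loop oracles", {
  s <- basic_stats(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$variance, 2 / 3)
  expect_equal(s$median, 2)
  expect_equal(s$rms, sqrt(14 / 3))
  expect_equal(s$max, 3); expect_equal(s$min, 1)
  cst <- basic_stats(rep(-4, 7))
  expect_equal(cst$variance, 0)
  expect_equal(cst$rms, 4)
  set.seed(32)
  for (i in 1:100) {
    x <- rnorm(sample(2:50, 1))
    n <- length(x)
    mu <- 0; for (v in x) mu <- mu + v / n
    va <- 0; for (v in x) va <- va + (v - mu)^2 / n
    rm2 <- 0; for (v in x) rm2 <- rm2 + v^2 / n
    st <- basic_stats(x)
    expect_equal(st$mean, mu, tolerance = 1e-12)
    expect_equal(st$variance, va, tolerance = 1e-12)
    expect_equal(st$rms, sqrt(rm2), tolerance = 1e-12)
    xs <- sort(x)
    med <- if (n %% 2) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
    expect_equal(st$median, med)
  }
})

test_that("orthogonal wavelet decomposition conserves energy (Parseval)", {
  set.seed(33)
  for (fam in c("haar", "db2", "db4")) {
    for (i in 1:10) {
      x <- rnorm(2^sample(5:9, 1))
      d <- dwt(x, fam, 4L)
      e <- sum(vapply(d$details, function(b) sum(b^2), numeric(1))) + sum(d$approx^2)
      expect_equal(e, sum(x^2), tolerance = 1e-8)
    }
  }
})

test_that("one DWT level equals direct filter-and-downsample circular convolution", {
  set.seed(34)
  x <- rnorm(8)
  f <- ecgwolf:::dwt_filters("db2")
  oracle_band <- function(h) {
    vapply(0:3, function(k) {
      acc <- 0
      for (m in seq_along(h)) acc <- acc + h[m] * x[(2 * k + m - 1) %% 8 + 1]
      acc
    }, numeric(1))
  }
  d <- dwt(x, "db2", 1L)
  expect_equal(d$approx, oracle_band(f$lo), tolerance = 1e-12)
  expect_equal(d$details[[1]], oracle_band(f$hi), tolerance = 1e-12)
})

test_that("wavelet features: zero in, zero sub-band energies out; short input errors", {
  wf <- wavelet_features(rep(0, 64), wavelet_spec("db4", 3L))
  expect_true(all(unlist(wf[grepl("energy", names(wf))]) == 0))
  expect_identical(length(wf), 2L * 4L)
  expect_error(dwt(rnorm(7), "db4", 3L), class = "ecgwolf_argument_error")
})

test_that("texture features of degenerate and alternating sequences match theory", {
  cst <- glcm_features(rep(2.5, 30))
  expect_equal(cst$glcm_contrast, 0)
  expect_equal(cst$glcm_energy, 1)
  expect_equal(cst$glcm_homogeneity, 1)
  expect_true(is.na(cst$glcm_correlation))
  alt <- glcm_features(rep(c(0, 1), 50), glcm_spec(levels = 2L, lag = 1L))
  expect_equal(alt$glcm_contrast, 1)
  expect_equal(alt$glcm_energy, 0.5)
  expect_equal(alt$glcm_homogeneity, 0.5)
  expect_equal(alt$glcm_correlation, -1)
})

test_that("texture features equal a nested-loop co-occurrence oracle", {
  set.seed(35)
  for (i in 1:100) {
    L <- sample(2:8, 1); lag <- sample(1:3, 1)
    x <- runif(sample((lag + 2):40, 1))
    spec <- glcm_spec(levels = L, lag = lag, symmetric = (i %% 2 == 0))
    got <- glcm_features(x, spec)
    q <- ecgwolf:::quantize_segment(x, L)
    C <- matrix(0, L, L)
    for (t in seq_len(length(q) - lag)) {
      C[q[t] + 1, q[t + lag] + 1] <- C[q[t] + 1, q[t + lag] + 1] + 1
      if (spec$symmetric) C[q[t + lag] + 1, q[t] + 1] <- C[q[t + lag] + 1, q[t] + 1] + 1
    }
    P <- C / sum(C)
    con <- en <- hom <- sij <- 0
    mi <- mj <- vi <- vj <- 0
    for (a in 0:(L - 1)) for (b in 0:(L - 1)) {
      p <- P[a + 1, b + 1]
      con <- con + p * (a - b)^2; en <- en + p^2
      hom <- hom + p / (1 + (a - b)^2); sij <- sij + a * b * p
      mi <- mi + a * p; mj <- mj + b * p
    }
    for (a in 0:(L - 1)) for (b in 0:(L - 1)) {
      p <- P[a + 1, b + 1]
      vi <- vi + (a - mi)^2 * p; vj <- vj + (b - mj)^2 * p
    }
    expect_equal(got$glcm_contrast, con, tolerance = 1e-12)
    expect_equal(got$glcm_energy, en, tolerance = 1e-12)
    expect_equal(got$glcm_homogeneity, hom, tolerance = 1e-12)
    if (vi > 0 && vj > 0) {
      expect_equal(got$glcm_correlation, (sij - mi * mj) / sqrt(vi * vj),
                   tolerance = 1e-12)
    }
    # distribution invariants
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_gte(got$glcm_contrast, 0)
    expect_true(got$glcm_energy > 0 && got$glcm_energy <= 1)
    expect_true(got$glcm_homogeneity > 0 && got$glcm_homogeneity <= 1)
    if (!is.na(got$glcm_correlation)) {
      expect_true(abs(got$glcm_correlation) <= 1 + 1e-12)
    }
  }
})

test_that("the full registry yields 1 + 6 + 2(levels+1) + 4 named columns", {
  set.seed(36)
  segs <- lapply(1:10, function(i) ecg_segment(rnorm(360), 360, label = (i %% 5) + 1L))
  fm <- extract_all(segs, wavelet_spec("db4", 4L), glcm_spec())
  expect_identical(ncol(fm$values), 1L + 6L + 2L * 5L + 4L)
  expect_false(anyDuplicated(fm$feature_names) > 0)
  fm2 <- extract_all(segs, wavelet_spec("db4", 4L), glcm_spec())
  expect_identical(fm$feature_names, fm2$feature_names)
  expect_identical(fm$values, fm2$values)
  # duplicate segments produce identical rows
  dup <- extract_all(list(segs[[1]], segs[[1]]), wavelet_spec("db4", 4L), glcm_spec())
  expect_identical(dup$values[1, ], dup$values[2, ])
})

test_that("features are pure functions of samples and spec, not provenance", {
  set.seed(37)
  x <- rnorm(128)
  a <- ecg_segment(x, 360, label = 1L, record_id = "a", start_index = 0L)
  b <- ecg_segment(x, 360, label = 1L, record_id = "b", start_index = 999L)
  fa <- extract_all(list(a), wavelet_spec("db4", 3L))
  fb <- extract_all(list(b), wavelet_spec("db4", 3L))
  expect_identical(fa$values, fb$values)
})

test_that("LDA projection separates two linearly separable classes in 1-D", {
  set.seed(38)
  labels <- rep(1:2, each = 30)
  vals <- cbind(sep = ifelse(labels == 1, 0, 10) + rnorm(60),
                n1 = rnorm(60), n2 = rnorm(60))
  fm <- feature_matrix(vals, colnames(vals), labels)
  red <- lda_reduce(fm, 1L)
  p1 <- red$values[labels == 1, 1]; p2 <- red$values[labels == 2, 1]
  expect_true(max(p1) < min(p2) || min(p1) > max(p2))
  expect_identical(red$feature_names, "LD1")
})

test_that("LDA enforces the C - 1 component bound and rejects one class", {
  fm <- make_cluster_fm(10)
  expect_error(lda_reduce(fm, 5L), class = "ecgwolf_argument_error")
  one <- feature_matrix(matrix(rnorm(20), 10, 2), c("a", "b"), rep(1L, 10))
  expect_error(lda_reduce(one, 1L), class = "ecgwolf_argument_error")
})

test_that("LDA directions match the generalized-eigenvector solution", {
  set.seed(39)
  fm <- make_cluster_fm(15, n_classes = 3, n_noise = 2, amp = 4)
  red <- lda_reduce(fm, 2L)
  # independent oracle: non-symmetric eigen decomposition of solve(Sw) Sb
  X <- fm$values; labels <- fm$labels
  mu <- colMeans(X); d <- ncol(X)
  Sw <- matrix(0, d, d); Sb <- matrix(0, d, d)
  for (k in unique(labels)) {
    Xk <- X[labels == k, , drop = FALSE]
    mk <- colMeans(Xk)
    Sw <- Sw + crossprod(sweep(Xk, 2, mk))
    Sb <- Sb + nrow(Xk) * tcrossprod(mk - mu)
  }
  Sw <- Sw + diag(1e-6 * mean(diag(Sw)), d)
  ev <- eigen(solve(Sw) %*% Sb)
  for (j in 1:2) {
    w_oracle <- Re(ev$vectors[, j])
    proj_oracle <- X %*% w_oracle
    r <- abs(stats::cor(red$values[, j], proj_oracle))
    expect_gt(r, 1 - 1e-6)
  }
})
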