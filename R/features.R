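# Formula-defined feature extraction. Per segment: signal energy, six summary
# statistics (population variance, divisor N), wavelet sub-band energy and
# variance, and four co-occurrence texture measures computed on the quantized
# amplitude sequence. Plus a supervised LDA projection as an optional
# alternative feature set.

#' Wavelet feature specification
#'
#' @param mother Wavelet family code (see [dwt()]); default `"db4"`.
#' @param levels Decomposition depth (>= 1); must satisfy
#'   `levels <= floor(log2(segment length)) - 1`.
#' @export
wavelet_spec <- function(mother = "db4", levels = 4L) {
  if (!is_count(levels)) abort_arg("levels must be a positive integer")
  structure(list(mother = mother, levels = as.integer(levels)),
            class = "wavelet_spec")
}

#' Co-occurrence texture specification
#'
#' Texture features on a 1-D signal: the min-max-normalized segment is
#' quantized to `levels` amplitude levels and pairs `(q[t], q[t + lag])` are
#' counted into a co-occurrence matrix (optionally symmetrized), from which
#' contrast, energy, homogeneity and correlation are computed.
#'
#' @param levels Quantization levels (2..256), default 8.
#' @param lag Co-occurrence offset in samples (>= 1), default 1.
#' @param symmetric Add transposed counts so the matrix is symmetric.
#' @export
glcm_spec <- function(levels = 8L, lag = 1L, symmetric = TRUE) {
  if (!is_count(levels) || levels < 2 || levels > 256) {
    abort_arg("glcm levels must be an integer in 2..256")
  }
  if (!is_count(lag)) abort_arg("lag must be a positive integer")
  structure(list(levels = as.integer(levels), lag = as.integer(lag),
                 symmetric = isTRUE(symmetric)),
            class = "glcm_spec")
}

#' Segment energy
#'
#' Sum of squared amplitudes over the segment; nonnegative, zero only for the
#' all-zero segment.
#'
#' @param x Nonempty numeric vector.
#' @export
signal_energy <- function(x) {
  if (!length(x)) abort_arg("energy of an empty segment is undefined")
  sum(abs(x)^2)
}

#' Summary statistics of a segment
#'
#' Mean, population variance (divisor N), median (mean of the two middle
#' order statistics for even N), maximum, minimum, and root-mean-square.
#'
#' @param x Nonempty numeric vector.
#' @return Named list: `mean`, `variance`, `median`, `max`, `min`, `rms`.
#' @export
basic_stats <- function(x) {
  if (!length(x)) abort_arg("statistics of an empty segment are undefined")
  n <- length(x)
  mu <- mean(x)
  list(mean = mu,
       variance = sum((x - mu)^2) / n,
       median = stats::median(x),
       max = max(x),
       min = min(x),
       rms = sqrt(sum(x^2) / n))
}

#' Wavelet sub-band features
#'
#' Decomposes the segment to `spec$levels` scales and reports the energy and
#' population variance of every detail band and of the final approximation.
#' Feature names encode band and statistic (`wv_d1_energy`, ...,
#' `wv_a4_variance`).
#'
#' @param x Numeric vector, `length(x) >= 2^levels`.
#' @param spec A [wavelet_spec()].
#' @return Named list of `2 * (levels + 1)` values.
#' @export
wavelet_features <- function(x, spec = wavelet_spec()) {
  stopifnot(inherits(spec, "wavelet_spec"))
  dec <- dwt(x, spec$mother, spec$levels)
  bands <- c(stats::setNames(dec$details, paste0("d", seq_len(spec$levels))),
             list(a = dec$approx))
  names(bands)[length(bands)] <- paste0("a", spec$levels)
  out <- list()
  for (bn in names(bands)) {
    b <- bands[[bn]]
    out[[paste0("wv_", bn, "_energy")]] <- signal_energy(b)
    out[[paste0("wv_", bn, "_variance")]] <- basic_stats(b)$variance
  }
  out
}

# Quantize a segment to 0..(levels-1); constant segments map to level 0.
quantize_segment <- function(x, levels) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(rep(0L, length(x)))
  q <- floor((x - lo) / (hi - lo) * levels)
  pmin(as.integer(q), levels - 1L)
}

#' Co-occurrence texture features of a segment
#'
#' Quantizes the segment, forms the normalized co-occurrence matrix
#' `P(i, j)` of amplitude-level pairs at the configured lag, and returns
#' `contrast = sum P(i,j) (i-j)^2`, `energy = sum P(i,j)^2`,
#' `homogeneity = sum P(i,j) / (1 + (i-j)^2)`, and
#' `correlation = (sum i j P(i,j) - mu_i mu_j) / (sigma_i sigma_j)`.
#' For a constant segment the co-occurrence mass sits in a single cell:
#' contrast 0, energy 1, homogeneity 1, and correlation is undefined
#' (returned as `NA`; such rows are dropped upstream).
#'
#' @param x Nonempty numeric vector with `length(x) > lag`.
#' @param spec A [glcm_spec()].
#' @return Named list: `glcm_contrast`, `glcm_energy`, `glcm_homogeneity`,
#'   `glcm_correlation`.
#' @export
glcm_features <- function(x, spec = glcm_spec()) {
  stopifnot(inherits(spec, "glcm_spec"))
  if (!length(x)) abort_arg("co-occurrence of an empty segment is undefined")
  if (length(x) <= spec$lag) abort_arg("lag must be smaller than the segment length")
  q <- quantize_segment(x, spec$levels)
  n <- length(q)
  i <- q[1:(n - spec$lag)]
  j <- q[(1 + spec$lag):n]
  L <- spec$levels
  counts <- matrix(0, L, L)
  tab <- table(factor(i, levels = 0:(L - 1)), factor(j, levels = 0:(L - 1)))
  counts <- counts + as.matrix(tab)
  if (spec$symmetric) counts <- counts + t(counts)
  P <- counts / sum(counts)
  lev <- 0:(L - 1)
  diffs2 <- outer(lev, lev, function(a, b) (a - b)^2)
  mu_i <- sum(rowSums(P) * lev)
  mu_j <- sum(colSums(P) * lev)
  sd_i <- sqrt(sum(rowSums(P) * (lev - mu_i)^2))
  sd_j <- sqrt(sum(colSums(P) * (lev - mu_j)^2))
  corr <- if (sd_i > 0 && sd_j > 0) {
    (sum(outer(lev, lev) * P) - mu_i * mu_j) / (sd_i * sd_j)
  } else {
    NA_real_
  }
  list(glcm_contrast = sum(P * diffs2),
       glcm_energy = sum(P^2),
       glcm_homogeneity = sum(P / (1 + diffs2)),
       glcm_correlation = corr)
}

#' Extract the full feature matrix from labeled segments
#'
#' One row per segment in a deterministic column order: segment energy, the
#' six summary statistics, the wavelet sub-band features, and the four
#' texture features (`1 + 6 + 2*(levels+1) + 4` columns). Rows with any
#' undefined feature (e.g. the degenerate texture correlation of a constant
#' segment) are dropped, with a message reporting the count.
#'
#' @param segments Nonempty list of labeled [ecg_segment()]s.
#' @param wspec,gspec Feature specifications.
#' @return A `feature_matrix`: list with `values` (numeric matrix),
#'   `feature_names`, and `labels`.
#' @export
extract_all <- function(segments, wspec = wavelet_spec(), gspec = glcm_spec()) {
  if (!length(segments)) abort_arg("extract_all needs at least one segment")
  rows <- lapply(segments, function(s) {
    bs <- basic_stats(s$samples)
    unlist(c(list(energy = signal_energy(s$samples)),
             bs[c("mean", "variance", "median", "max", "min", "rms")],
             wavelet_features(s$samples, wspec),
             glcm_features(s$samples, gspec)))
  })
  values <- do.call(rbind, rows)
  labels <- vapply(segments, `[[`, integer(1), "label")
  ok <- apply(values, 1L, function(r) all(is.finite(r))) & !is.na(labels)
  if (!all(ok)) {
    message(sprintf("extract_all: dropped %d of %d segments with undefined features or labels",
                    sum(!ok), length(ok)))
  }
  if (!any(ok)) abort_degenerate("all segments dropped: no finite labeled feature rows")
  feature_matrix(values[ok, , drop = FALSE], colnames(values), labels[ok])
}

#' Feature matrix container
#'
#' @param values Numeric matrix, rows = segments, columns = features; finite.
#' @param feature_names Unique column names.
#' @param labels Integer class labels (1-5), one per row.
#' @export
feature_matrix <- function(values, feature_names, labels) {
  values <- as.matrix(values)
  if (anyDuplicated(feature_names)) abort_arg("feature names must be unique")
  if (ncol(values) != length(feature_names)) abort_arg("feature_names length must match column count")
  if (nrow(values) != length(labels)) abort_arg("labels length must match row count")
  if (!all(is.finite(values))) abort_arg("feature matrix must be finite (no NaN/Inf)")
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 labels = as.integer(labels)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d features; classes: %s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d(n=%d)", sort(unique(x$labels)),
                            as.integer(table(x$labels))), collapse = " ")))
  invisible(x)
}

#' Supervised linear discriminant projection
#'
#' Projects the feature matrix onto the leading discriminant directions of
#' the between-/within-class scatter problem. The within-class scatter is
#' regularized with `eps * I` (`eps` scaled to the mean diagonal) so the
#' projection is defined even on small, nearly collinear inputs. At most
#' `n_classes - 1` informative directions exist.
#'
#' @param fm A [feature_matrix()] with at least two classes.
#' @param n_components Number of discriminants to keep (<= n_classes - 1).
#' @return A [feature_matrix()] with columns `LD1..LDk`.
#' @export
lda_reduce <- function(fm, n_components = 4L) {
  stopifnot(inherits(fm, "feature_matrix"))
  classes <- sort(unique(fm$labels))
  if (length(classes) < 2L) abort_arg("lda_reduce needs at least two classes")
  if (!is_count(n_components) || n_components > length(classes) - 1L) {
    abort_arg(sprintf("n_components must be in 1..%d (n_classes - 1)",
                      length(classes) - 1L))
  }
  X <- fm$values
  mu <- colMeans(X)
  d <- ncol(X)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (k in classes) {
    Xk <- X[fm$labels == k, , drop = FALSE]
    mk <- colMeans(Xk)
    Xc <- sweep(Xk, 2L, mk)
    Sw <- Sw + crossprod(Xc)
    Sb <- Sb + nrow(Xk) * tcrossprod(mk - mu)
  }
  eps <- 1e-6 * mean(diag(Sw))
  if (!is.finite(eps) || eps <= 0) eps <- 1e-6
  Sw <- Sw + diag(eps, d)
  # whiten within-class scatter, then eigen-decompose the symmetrized
  # between-class scatter in the whitened space
  R <- chol(Sw)
  Rinv <- backsolve(R, diag(d))
  M <- t(Rinv) %*% Sb %*% Rinv
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  W <- Rinv %*% ev$vectors[, seq_len(n_components), drop = FALSE]
  proj <- X %*% W
  feature_matrix(proj, paste0("LD", seq_len(n_components)), fm$labels)
}
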