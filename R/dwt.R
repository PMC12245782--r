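# Periodized orthogonal discrete wavelet transform. Only decomposition is
# needed (features are sub-band summaries, not reconstructions), so this is a
# compact analysis-only implementation. With an orthonormal filter pair and
# periodic extension the transform is orthogonal, hence energy-conserving
# (Parseval), which the feature tests rely on. Odd-length inputs are
# zero-padded by one sample before a level; padding adds no energy.

# Scaling (lowpass decomposition) filters. "db4" follows the common naming
# where the number is the vanishing-moment count (8 taps); "haar"/"db1" and
# "db2" are provided for small exact test cases.
DWT_FILTERS <- list(
  haar = c(1, 1) / sqrt(2),
  db1  = c(1, 1) / sqrt(2),
  db2  = c(0.482962913144690, 0.836516303737469,
           0.224143868041857, -0.129409522550921),
  db4  = c(0.230377813308855, 0.714846570552542, 0.630880767929590,
           -0.027983769416984, -0.187034811718881, 0.030841381835987,
           0.032883011666983, -0.010597401784997)
)

dwt_filters <- function(mother) {
  lo_r <- DWT_FILTERS[[mother]]
  if (is.null(lo_r)) {
    abort_arg(sprintf("unknown wavelet family '%s' (have: %s)",
                      mother, paste(names(DWT_FILTERS), collapse = ", ")))
  }
  dec_lo <- rev(lo_r)
  dec_hi <- lo_r * (-1)^(seq_along(lo_r) - 1L)
  list(lo = dec_lo, hi = dec_hi)
}

# One analysis level: y[k] = sum_m h[m] * x[(2k + m) mod N], k = 0..N/2-1.
dwt_level <- function(x, lo, hi) {
  if (length(x) %% 2L) x <- c(x, 0)
  n <- length(x)
  L <- length(lo)
  idx <- outer(2L * (seq_len(n %/% 2L) - 1L), seq_len(L) - 1L, `+`) %% n + 1L
  xm <- matrix(x[idx], ncol = L)
  list(approx = as.numeric(xm %*% lo), detail = as.numeric(xm %*% hi))
}

#' Multi-level discrete wavelet decomposition
#'
#' Periodized orthogonal DWT returning the detail coefficients of each level
#' and the final approximation. The transform conserves energy: the summed
#' energy of all sub-bands equals the input energy (up to zero-padding of
#' odd-length levels, which adds none).
#'
#' @param x Numeric vector, `length(x) >= 2^levels`.
#' @param mother Wavelet family: `"haar"`/`"db1"`, `"db2"`, or `"db4"`.
#' @param levels Number of decomposition levels (>= 1).
#' @return List with `details` (list of length `levels`, coarse last) and
#'   `approx` (final approximation coefficients).
#' @export
dwt <- function(x, mother = "db4", levels = 4L) {
  if (!is_count(levels)) abort_arg("levels must be a positive integer")
  if (length(x) < 2^levels) {
    abort_arg(sprintf("segment of length %d too short for %d decomposition levels",
                      length(x), levels))
  }
  check_finite(x, "signal")
  f <- dwt_filters(mother)
  details <- vector("list", levels)
  cur <- as.numeric(x)
  for (l in seq_len(levels)) {
    step <- dwt_level(cur, f$lo, f$hi)
    details[[l]] <- step$detail
    cur <- step$approx
  }
  list(details = details, approx = cur)
}
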