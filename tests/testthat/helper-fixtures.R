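# Fixture builders shared across tests. Everything is generated in code,
# seeded, and small enough to keep the suite fast.

# Gaussian one-vs-rest class clusters: column j separates class j.
make_cluster_fm <- function(n_per_class = 20, n_classes = 5, n_noise = 0,
                            amp = 6, seed = 1) {
  set.seed(seed)
  labels <- rep(seq_len(n_classes), each = n_per_class)
  n <- length(labels)
  inf <- vapply(seq_len(n_classes), function(j) {
    rnorm(n, mean = ifelse(labels == j, amp, 0))
  }, numeric(n))
  vals <- if (n_noise > 0) cbind(inf, matrix(rnorm(n * n_noise), n, n_noise)) else inf
  feature_matrix(vals, paste0("f", seq_len(ncol(vals))), labels)
}

# A short record with beats planted at known times (clean, no RR jitter).
make_planted_record <- function(beat_times_s, fs = 360, duration_s = 10,
                                noise_sd = 0, seed = 1) {
  set.seed(seed)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  sig <- rep(0, n)
  for (tc in beat_times_s) {
    sig <- sig + 1.0 * exp(-(t - tc)^2 / (2 * 0.012^2)) -
      0.15 * exp(-(t - tc - 0.03)^2 / (2 * 0.009^2)) +
      0.25 * exp(-(t - tc - 0.22)^2 / (2 * 0.035^2))
  }
  sig <- sig + rnorm(n, 0, noise_sd)
  ann <- data.frame(sample_index = as.integer(round(beat_times_s * fs)),
                    label = "1", stringsAsFactors = FALSE)
  ecg_record("planted", sig, fs, annotations = ann, source = "synthetic")
}

# FFT-based RMS of the component of x nearest frequency f0 (oracle for
# band-pass attenuation checks).
fft_component_rms <- function(x, fs, f0) {
  n <- length(x)
  sp <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  k <- which.min(abs(freqs - f0))
  sqrt(2) * Mod(sp[k]) / n
}
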