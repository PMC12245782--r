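# Seeded synthetic five-class ECG generator. Beats are sums of Gaussian
# bumps (P, Q, R, S, T); RR intervals are log-normal with class-dependent
# mean and coefficient of variation; class-specific morphology flags emulate
# the clinical signatures: AFib (irregular RR, suppressed P), SVT (fast,
# regular), bradycardia (slow), PVC (interspersed wide ectopic beats),
# atrial flutter (sawtooth baseline). Not a physiological simulator: just
# enough structure that filtering, QRS detection, segmentation and the
# feature/selection/classification stack all have analytic ground truth.

#' Class profiles of the five synthetic rhythm classes
#'
#' 1 atrial fibrillation, 2 supraventricular tachycardia, 3 bradycardia,
#' 4 premature ventricular contractions, 5 atrial flutter. Mean RR in
#' seconds, RR coefficient of variation, and morphology flags.
#'
#' @return Named list of profiles (class `class_profile`).
#' @export
class_profiles <- function() {
  prof <- function(id, name, rr_mean_s, rr_cv, suppress_p = FALSE,
                   widen_qrs = FALSE, sawtooth_baseline = FALSE,
                   ectopic_rate = 0) {
    stopifnot(rr_mean_s > 0.25, rr_cv >= 0)
    structure(list(class_id = id, name = name, rr_mean_s = rr_mean_s,
                   rr_cv = rr_cv, suppress_p = suppress_p,
                   widen_qrs = widen_qrs,
                   sawtooth_baseline = sawtooth_baseline,
                   ectopic_rate = ectopic_rate),
              class = "class_profile")
  }
  list(
    afib    = prof(1L, "atrial fibrillation", 0.75, 0.25, suppress_p = TRUE),
    svt     = prof(2L, "supraventricular tachycardia", 0.35, 0.03),
    brady   = prof(3L, "bradycardia", 1.40, 0.05),
    pvc     = prof(4L, "premature ventricular contractions", 0.80, 0.08,
                   ectopic_rate = 0.25),
    flutter = prof(5L, "atrial flutter", 0.60, 0.06, sawtooth_baseline = TRUE)
  )
}

#' Synthetic-data configuration
#'
#' @param fs Sampling rate (360 Hz, the MIT-BIH rate).
#' @param duration_s Record duration in seconds (default 10).
#' @param n_per_class Segments (or rows) per class (default 100).
#' @param noise_sd Gaussian observation noise, mV (default 0.05).
#' @param seed Master seed; every artifact is a pure function of it.
#' @param planted_informative,planted_noise Column counts for the
#'   feature-table mode (defaults 5 and 45).
#' @export
synth_config <- function(fs = 360, duration_s = 10, n_per_class = 100L,
                         noise_sd = 0.05, seed = 1L,
                         planted_informative = 5L, planted_noise = 45L) {
  if (!is_count(n_per_class)) abort_arg("n_per_class must be >= 1")
  if (noise_sd < 0) abort_arg("noise_sd must be >= 0")
  structure(list(fs = fs, duration_s = duration_s,
                 n_per_class = as.integer(n_per_class), noise_sd = noise_sd,
                 seed = as.integer(seed),
                 planted_informative = as.integer(planted_informative),
                 planted_noise = as.integer(planted_noise)),
            class = "synth_config")
}

# Gaussian bump helper: amplitude a, center mu (s), width sd (s)
add_bump <- function(sig, t, a, mu, sd) sig + a * exp(-(t - mu)^2 / (2 * sd^2))

# One beat's waveform contribution centered at time tc.
add_beat <- function(sig, t, tc, profile, ectopic = FALSE) {
  if (ectopic) {
    # wide-QRS ventricular ectopic: no P, broad tall R, discordant T
    sig <- add_bump(sig, t, 1.25, tc, 0.045)
    sig <- add_bump(sig, t, -0.35, tc + 0.09, 0.035)
    return(add_bump(sig, t, -0.30, tc + 0.30, 0.06))
  }
  if (!profile$suppress_p) sig <- add_bump(sig, t, 0.12, tc - 0.18, 0.020)
  sig <- add_bump(sig, t, -0.12, tc - 0.030, 0.008)
  qrs_w <- if (profile$widen_qrs) 0.030 else 0.012
  sig <- add_bump(sig, t, 1.0, tc, qrs_w)
  sig <- add_bump(sig, t, -0.18, tc + 0.030, 0.009)
  add_bump(sig, t, 0.25, tc + 0.22, 0.035)
}

#' Generate one synthetic ECG record
#'
#' RR intervals are drawn from a log-normal matching the profile's mean and
#' coefficient of variation; each beat is a sum of Gaussian bumps with the
#' profile's morphology flags applied; Gaussian observation noise is added.
#' Every beat time is recorded as an annotation labeled with the class id.
#'
#' @param profile A profile from [class_profiles()].
#' @param cfg A [synth_config()]; `cfg$seed` fixes the draw.
#' @return An [ecg_record()] of `round(duration_s * fs)` samples.
#' @export
generate_record <- function(profile, cfg = synth_config()) {
  stopifnot(inherits(profile, "class_profile"))
  if (cfg$duration_s < profile$rr_mean_s + 0.6) {
    abort_arg("duration too short to contain a single beat")
  }
  set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs)
  t <- (seq_len(n) - 1L) / cfg$fs
  # log-normal RR with the requested mean and CV
  s2 <- log(1 + profile$rr_cv^2)
  mu <- log(profile$rr_mean_s) - s2 / 2
  beat_t <- numeric(); ect <- logical()
  tc <- 0.3
  compensatory <- FALSE
  while (tc < cfg$duration_s - 0.3) {
    is_ect <- profile$ectopic_rate > 0 && !compensatory &&
      stats::runif(1) < profile$ectopic_rate
    beat_t <- c(beat_t, tc); ect <- c(ect, is_ect)
    rr <- if (profile$rr_cv > 0) stats::rlnorm(1, mu, sqrt(s2)) else profile$rr_mean_s
    if (is_ect) { rr <- rr * 1.35; compensatory <- TRUE }  # compensatory pause
    else compensatory <- FALSE
    tc <- tc + max(rr, 0.25)
  }
  sig <- numeric(n)
  for (b in seq_along(beat_t)) {
    sig <- add_beat(sig, t, beat_t[b], profile, ectopic = ect[b])
  }
  if (profile$sawtooth_baseline) {
    f_flutter <- 4.5  # ~270/min atrial rate
    phase <- (t * f_flutter) %% 1
    sig <- sig + 0.15 * (2 * phase - 1)
  }
  sig <- sig + stats::rnorm(n, 0, cfg$noise_sd)
  ann <- data.frame(sample_index = as.integer(round(beat_t * cfg$fs)),
                    label = as.character(profile$class_id),
                    stringsAsFactors = FALSE)
  ann <- ann[ann$sample_index < n, , drop = FALSE]
  ecg_record(sprintf("synth_c%d_s%d", profile$class_id, cfg$seed),
             sig, cfg$fs, annotations = ann, source = "synthetic")
}

#' Generate a balanced labeled segment dataset
#'
#' One long record per class (duration scaled to yield `n_per_class` labeled
#' 1-second windows even for sparse bradycardia beats), cut with fixed
#' segmentation; the first `n_per_class` labeled windows of each class are
#' kept and the pooled set is shuffled with the seed.
#'
#' @param cfg A [synth_config()].
#' @return List with `segments` (list of [ecg_segment()]) and `labels`.
#' @export
generate_dataset <- function(cfg = synth_config()) {
  profs <- class_profiles()
  all_seg <- list()
  for (p in profs) {
    dur <- ceiling(cfg$n_per_class * max(1.6, p$rr_mean_s * 1.4) + 4)
    rcfg <- cfg
    rcfg$duration_s <- dur
    rcfg$seed <- cfg$seed + 1000L * p$class_id
    rec <- generate_record(p, rcfg)
    segs <- segment_record(rec, "fixed", window_s = 1, stride_s = 1)
    labeled <- Filter(function(s) !is.na(s$label), segs)
    if (length(labeled) < cfg$n_per_class) {
      abort_degenerate(sprintf("class %d produced only %d labeled windows",
                               p$class_id, length(labeled)))
    }
    all_seg <- c(all_seg, labeled[seq_len(cfg$n_per_class)])
  }
  set.seed(cfg$seed)
  ord <- sample.int(length(all_seg))
  segments <- all_seg[ord]
  list(segments = segments,
       labels = vapply(segments, `[[`, integer(1), "label"))
}

#' Generate a feature table with planted informative columns
#'
#' Ground truth for feature-selection recovery: informative column `j`
#' separates class `((j - 1) mod 5) + 1` from the rest with a 4
#' within-class-standard-deviation margin (mean 4 for its class, 0
#' elsewhere, unit sd), so the informative set is jointly necessary — no
#' strict subset classifies all five classes — and a wrapper search is
#' rewarded for recovering every planted column. `planted_noise` columns are
#' class-independent standard normals. Column order is shuffled.
#'
#' @param cfg A [synth_config()].
#' @return List with `fm` (a [feature_matrix()]) and `informative_mask`
#'   (0/1 vector aligned with the columns).
#' @export
generate_feature_table <- function(cfg = synth_config()) {
  if (cfg$planted_informative < 1L) abort_arg("need at least one informative column")
  set.seed(cfg$seed)
  n_inf <- cfg$planted_informative; n_noise <- cfg$planted_noise
  n_classes <- 5L
  labels <- rep(seq_len(n_classes), each = cfg$n_per_class)
  n <- length(labels)
  inf_cols <- vapply(seq_len(n_inf), function(j) {
    target <- (j - 1L) %% n_classes + 1L
    stats::rnorm(n, mean = ifelse(labels == target, 4, 0), sd = 1)
  }, numeric(n))
  noise_cols <- matrix(stats::rnorm(n * n_noise), n, n_noise)
  values <- cbind(inf_cols, noise_cols)
  nms <- c(paste0("inf_", seq_len(n_inf)), paste0("noise_", seq_len(n_noise)))
  mask <- c(rep(1L, n_inf), rep(0L, n_noise))
  perm <- sample.int(ncol(values))
  list(fm = feature_matrix(values[, perm, drop = FALSE], nms[perm], labels),
       informative_mask = mask[perm])
}

#' Randomized 70-15-15 split
#'
#' Seeded random partition into training (`round(0.70 n)`), validation
#' (`round(0.15 n)`) and test (remainder); disjoint and exhaustive. The
#' stratified mode applies the same proportions within each class, keeping
#' per-class shares within one item of the global shares.
#'
#' @param n Number of items (>= 20).
#' @param seed Integer seed.
#' @param labels Optional class labels of length `n`; when given, the split
#'   is stratified by class.
#' @return List of index vectors: `train`, `validation`, `test`.
#' @export
split_70_15_15 <- function(n, seed = 1L, labels = NULL) {
  if (!is_count(n) || n < 20L) abort_arg("need at least 20 items to split")
  set.seed(seed)
  take <- function(idx) {
    idx <- idx[sample.int(length(idx))]
    n_tr <- round(0.70 * length(idx))
    n_va <- round(0.15 * length(idx))
    list(train = idx[seq_len(n_tr)],
         validation = idx[n_tr + seq_len(n_va)],
         test = idx[(n_tr + n_va + 1L):length(idx)])
  }
  if (is.null(labels)) return(take(seq_len(n)))
  stopifnot(length(labels) == n)
  parts <- lapply(unique(labels), function(k) take(which(labels == k)))
  list(train = sort(unlist(lapply(parts, `[[`, "train"))),
       validation = sort(unlist(lapply(parts, `[[`, "validation"))),
       test = sort(unlist(lapply(parts, `[[`, "test"))))
}
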