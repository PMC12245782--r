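#' ECG record container
#'
#' A single-channel ECG record: the sampled waveform in millivolts, its
#' sampling rate, and optional beat/rhythm annotations. All sample indices in
#' the package are 0-based; conversion from 1-based sources happens at the
#' I/O boundary and nowhere else.
#'
#' @param record_id Character record identifier.
#' @param signal Numeric vector of samples (mV). NaN/Inf are rejected.
#' @param fs Sampling rate in Hz (360 for MIT-BIH-conformant data).
#' @param annotations Data frame with columns `sample_index` (0-based integer,
#'   nondecreasing) and `label` (character), or `NULL` for none.
#' @param source One of `"wfdb"`, `"csv"`, `"synthetic"`.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, signal, fs,
                       annotations = NULL, source = "synthetic") {
  if (!is.numeric(signal) || length(signal) < 1L) {
    abort_arg("signal must be a nonempty numeric vector")
  }
  check_finite(signal, sprintf("record '%s' signal", record_id))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort_arg("fs must be a single positive number")
  }
  source <- match.arg(source, c("wfdb", "csv", "synthetic"))
  if (is.null(annotations)) {
    annotations <- data.frame(sample_index = integer(), label = character(),
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample_index", "label") %in% names(annotations)))
  ann <- data.frame(sample_index = as.integer(annotations$sample_index),
                    label = as.character(annotations$label),
                    stringsAsFactors = FALSE)
  if (nrow(ann)) {
    if (any(ann$sample_index < 0L) || any(ann$sample_index >= length(signal))) {
      abort_arg("annotation sample_index out of range [0, length(signal))")
    }
    if (is.unsorted(ann$sample_index)) {
      abort_arg("annotation sample_index must be nondecreasing")
    }
  }
  structure(
    list(record_id = as.character(record_id), signal = as.numeric(signal),
         fs = as.numeric(fs), annotations = ann, source = source),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> %d samples @ %g Hz (%.1f s), %d annotations, source=%s\n",
              x$record_id, length(x$signal), x$fs, length(x$signal) / x$fs,
              nrow(x$annotations), x$source))
  invisible(x)
}

# --- WFDB (.hea/.dat/.atr) ---------------------------------------------------
#
# Minimal MIT/PhysioNet waveform-database support: format 16 (16-bit
# little-endian) read/write, format 212 read-only (the MIT-BIH native packing),
# and the MIT annotation file format. Only what the pipeline needs; no R or
# Python WFDB binding is available in this stack.

DEFAULT_GAIN <- 200      # adu per mV, the MIT-BIH convention
ANN_AUX_CODE <- 63L
ANN_SKIP_CODE <- 59L
ANN_MOD_CODES <- c(60L, 61L, 62L)  # NUM, SUB, CHN modifiers: parsed, ignored

# Standard annotation mnemonics for the codes the MIT-BIH database uses.
WFDB_ANN_SYMBOLS <- c(
  "N", "L", "R", "a", "V", "F", "J", "A", "S", "E",
  "j", "/", "Q", "~", "[15]", "|", "[17]", "s", "T", "*",
  "D", "\"", "=", "p", "B", "^", "t", "+", "u", "?",
  "!", "[", "]", "e", "n", "@", "x", "f", "(", ")", "r"
)

wfdb_symbol <- function(code) {
  ifelse(code >= 1L & code <= length(WFDB_ANN_SYMBOLS),
         WFDB_ANN_SYMBOLS[code], paste0("[", code, "]"))
}

wfdb_code <- function(label) {
  i <- match(label, WFDB_ANN_SYMBOLS)
  ifelse(is.na(i), 1L, i)
}

strip_hea_ext <- function(path) sub("\\.hea$", "", path)

#' Read a WFDB record
#'
#' Reads a `.hea`/`.dat` pair (formats 16 and 212) and, when present, the
#' `.atr` annotation sidecar. Sample indices are converted to the package's
#' 0-based convention on read.
#'
#' @param path Path to the record, with or without the `.hea` extension.
#' @param channel 0-based channel to extract (default 0, the first channel).
#' @return An [ecg_record()] for the selected channel.
#' @export
read_wfdb_record <- function(path, channel = 0L) {
  base <- strip_hea_ext(path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) abort_format(sprintf("WFDB header not found: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) abort_format(sprintf("empty WFDB header: %s", hea))
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(head_tok) < 3L) abort_format(sprintf("malformed WFDB header line: %s", hea))
  record_id <- head_tok[1]
  n_sig <- as.integer(head_tok[2])
  fs <- as.numeric(sub("/.*$", "", head_tok[3]))  # strip counter frequency
  n_samp <- if (length(head_tok) >= 4L) as.integer(head_tok[4]) else NA_integer_
  if (!is.numeric(channel) || length(channel) != 1L || channel < 0 || channel >= n_sig) {
    abort_arg(sprintf("channel %s out of range for %d-channel record", channel, n_sig))
  }
  channel <- as.integer(channel)
  if (length(lines) < 1L + n_sig) abort_format(sprintf("header %s declares %d signals but lists fewer", hea, n_sig))

  sig_lines <- lines[2L:(1L + n_sig)]
  parse_sig <- function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt <- as.integer(sub("[x:+].*$", "", tok[2]))
    gain_tok <- if (length(tok) >= 3L) tok[3] else as.character(DEFAULT_GAIN)
    gain <- as.numeric(sub("[(/].*$", "", gain_tok))
    if (!is.finite(gain) || gain == 0) gain <- DEFAULT_GAIN
    baseline <- if (grepl("\\(", gain_tok)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_tok))
    } else if (length(tok) >= 5L) as.numeric(tok[5]) else 0
    list(file = tok[1], fmt = fmt, gain = gain,
         baseline = ifelse(is.finite(baseline), baseline, 0))
  }
  sigs <- lapply(sig_lines, parse_sig)
  dat_file <- file.path(dirname(hea), sigs[[1L]]$file)
  if (!file.exists(dat_file)) abort_format(sprintf("WFDB signal file not found: %s", dat_file))
  fmts <- vapply(sigs, `[[`, integer(1), "fmt")
  if (length(unique(fmts)) != 1L) abort_format("mixed signal formats are not supported")

  raw_all <- readBin(dat_file, "raw", n = file.size(dat_file))
  adus <- switch(as.character(fmts[1]),
    "16" = {
      v <- readBin(raw_all, "integer", n = length(raw_all) %/% 2L,
                   size = 2L, signed = TRUE, endian = "little")
      matrix(v, nrow = n_sig)  # interleaved frames
    },
    "212" = read_fmt212(raw_all, n_sig),
    abort_format(sprintf("unsupported WFDB format %d in %s", fmts[1], hea))
  )
  if (!is.na(n_samp) && ncol(adus) > n_samp) adus <- adus[, seq_len(n_samp), drop = FALSE]
  s <- sigs[[channel + 1L]]
  signal <- (adus[channel + 1L, ] - s$baseline) / s$gain

  atr <- paste0(base, ".atr")
  ann <- if (file.exists(atr)) read_mit_annotations(atr) else NULL
  ecg_record(record_id, signal, fs, annotations = ann, source = "wfdb")
}

# Format 212 packs two 12-bit samples into 3 bytes.
read_fmt212 <- function(raw_all, n_sig) {
  n_triplet <- length(raw_all) %/% 3L
  b <- as.integer(raw_all[seq_len(3L * n_triplet)])
  b1 <- b[seq(1L, by = 3L, length.out = n_triplet)]
  b2 <- b[seq(2L, by = 3L, length.out = n_triplet)]
  b3 <- b[seq(3L, by = 3L, length.out = n_triplet)]
  s1 <- bitwOr(bitwShiftL(bitwAnd(b2, 15L), 8L), b1)
  s2 <- bitwOr(bitwShiftL(bitwAnd(b2, 240L), 4L), b3)
  s1 <- ifelse(s1 >= 2048L, s1 - 4096L, s1)
  s2 <- ifelse(s2 >= 2048L, s2 - 4096L, s2)
  v <- as.vector(rbind(s1, s2))
  matrix(v, nrow = n_sig)
}

#' Write a WFDB record
#'
#' Emits `<path>.hea` and `<path>.dat` (format 16, gain 200 adu/mV) plus a
#' `<path>.atr` annotation file when the record carries annotations.
#' [read_wfdb_record()] inverts it up to one ADC quantum (1/200 mV).
#'
#' @param record An [ecg_record()].
#' @param path Output path (extension ignored if given).
#' @return Invisibly, the header path.
#' @export
write_wfdb_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(record$signal) < 1L) abort_arg("cannot write an empty signal")
  base <- strip_hea_ext(path)
  dir <- dirname(base)
  if (!dir.exists(dir)) abort("output directory does not exist", "ecgwolf_io_error")
  name <- basename(base)
  adus <- as.integer(round(record$signal * DEFAULT_GAIN))
  if (any(abs(adus) > 32767L)) abort_arg("signal amplitude exceeds 16-bit range at gain 200")
  hea <- c(
    sprintf("%s 1 %g %d", name, record$fs, length(adus)),
    sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 ECG", name, DEFAULT_GAIN, adus[1])
  )
  writeLines(hea, paste0(base, ".hea"))
  writeBin(adus, paste0(base, ".dat"), size = 2L, endian = "little")
  if (nrow(record$annotations)) {
    write_mit_annotations(record$annotations, paste0(base, ".atr"))
  }
  invisible(paste0(base, ".hea"))
}

# MIT annotation format: a stream of 16-bit little-endian words; the top 6
# bits are the annotation code, the low 10 bits the sample increment since the
# previous annotation. SKIP (59) escapes increments > 1023 via a following
# 32-bit interval in PDP-11 word order; AUX (63) attaches a byte string we use
# to round-trip arbitrary label text. A zero word terminates the stream.
read_mit_annotations <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  words <- readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
                   signed = FALSE, endian = "little")
  idx <- 1L
  t_cur <- 0L
  pending_skip <- 0
  sample_index <- integer()
  label <- character()
  while (idx <= length(words)) {
    w <- words[idx]
    code <- bitwShiftR(w, 10L)
    inc <- bitwAnd(w, 1023L)
    if (code == 0L && inc == 0L) break
    if (code == ANN_SKIP_CODE && inc == 0L) {
      hi <- words[idx + 1L]; lo <- words[idx + 2L]
      pending_skip <- pending_skip + hi * 65536 + lo
      idx <- idx + 3L
      next
    }
    if (code == ANN_AUX_CODE) {
      n_bytes <- inc
      n_words <- (n_bytes + n_bytes %% 2L) %/% 2L
      aux_raw <- bytes[(2L * idx + 1L):(2L * idx + n_bytes)]
      if (length(sample_index)) label[length(label)] <- rawToChar(aux_raw)
      idx <- idx + 1L + n_words
      next
    }
    if (code %in% ANN_MOD_CODES) { idx <- idx + 1L; next }
    t_cur <- t_cur + inc + pending_skip
    pending_skip <- 0
    sample_index <- c(sample_index, as.integer(t_cur))
    label <- c(label, wfdb_symbol(code))
    idx <- idx + 1L
  }
  data.frame(sample_index = sample_index, label = label, stringsAsFactors = FALSE)
}

write_mit_annotations <- function(ann, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  put_word <- function(code, inc) {
    writeBin(as.integer(bitwOr(bitwShiftL(code, 10L), inc)), con,
             size = 2L, endian = "little")
  }
  t_prev <- 0L
  for (i in seq_len(nrow(ann))) {
    dt <- ann$sample_index[i] - t_prev
    t_prev <- ann$sample_index[i]
    if (dt > 1023L) {
      put_word(ANN_SKIP_CODE, 0L)
      # 32-bit interval in PDP-11 word order: high 16 bits first
      writeBin(as.integer(dt %/% 65536L), con, size = 2L, endian = "little")
      writeBin(as.integer(dt %% 65536L), con, size = 2L, endian = "little")
      dt <- 0L
    }
    lab <- ann$label[i]
    put_word(wfdb_code(lab), dt)
    # AUX word carrying the exact label text so round-trips are lossless
    aux <- charToRaw(lab)
    put_word(ANN_AUX_CODE, length(aux))
    if (length(aux) %% 2L) aux <- c(aux, as.raw(0L))
    writeBin(aux, con)
  }
  put_word(0L, 0L)
  invisible(path)
}
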