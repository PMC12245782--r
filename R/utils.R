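# Internal condition helpers: every user-facing precondition failure carries a
# condition class so callers (and tests) can distinguish argument errors from
# format/ingestion errors and degenerate-input errors.

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "ecgwolf_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_arg <- function(msg) abort(msg, "ecgwolf_argument_error")
abort_format <- function(msg) abort(msg, "ecgwolf_format_error")
abort_degenerate <- function(msg) abort(msg, "ecgwolf_degenerate_error")

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort_format(sprintf("%s contains NaN/Inf or missing values; rejected at ingestion", what))
  }
  invisible(x)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x) && x >= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
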