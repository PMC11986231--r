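# Shared input validation. All user-facing validation failures signal a
# condition of class "hepafuse_validation_error" so the CLI can map them to a
# dedicated exit code.

stop_invalid <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "hepafuse_validation_error")
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop_invalid("%s contains non-finite values", what)
  invisible(x)
}

check_same_shape <- function(a, b, what = "inputs") {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (length(da) != length(db) || any(da != db)) {
    stop_invalid("%s must share the same shape (%s vs %s)", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x"))
  }
  invisible(NULL)
}

check_binary <- function(x, what = "mask") {
  if (!all(x %in% c(0, 1))) stop_invalid("%s must be binary (0/1)", what)
  invisible(x)
}

check_range <- function(lo, hi, what) {
  if (lo > hi) stop_invalid("%s range is degenerate (%s > %s)", what, lo, hi)
  invisible(NULL)
}
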