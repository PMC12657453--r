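# internal helpers shared across modules

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "kneegait_format_error")
}

assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) abort(sprintf(msg, ...), class = "kneegait_error")
  invisible(TRUE)
}

# linear interpolation of a sampled signal at arbitrary times; constant
# extrapolation is deliberately disallowed (rule = 1 -> NA outside range)
interp_at <- function(time, values, at) {
  approx(time, values, xout = at, method = "linear", rule = 1, ties = "ordered")$y
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# strictly-increasing check with informative failure
check_time <- function(time, what = "time") {
  assert_that(length(time) >= 1L && all(is.finite(time)),
              "%s must be finite", what)
  assert_that(all(diff(time) > 0), "%s must be strictly increasing", what)
  invisible(TRUE)
}

fmt_num <- function(x, digits = 6L) {
  out <- ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
  out
}
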