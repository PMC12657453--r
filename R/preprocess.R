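#' Savitzky-Golay smoothing
#'
#' Smooths a uniformly sampled signal by local least-squares polynomial
#' fitting. Interior samples use the closed-form convolution weights of the
#' centred window; within half a window of either end the polynomial is
#' refitted on the window truncated at the series boundary and evaluated at
#' the sample position, so the output has the same length as the input with
#' no padding artefacts. The filter reproduces any polynomial of degree
#' `<= order` exactly and is linear in its input.
#'
#' The default 31-frame window (about 0.52 s at 60 Hz) with a cubic
#' polynomial is the classic choice for marker trajectories sampled at
#' 60 Hz; the window must be odd, so a requested even width should be
#' rounded up by the caller.
#'
#' @param x Numeric vector without missing values (interpolate gaps first,
#'   see [fill_gaps()]).
#' @param window Odd window length in frames (default 31).
#' @param order Polynomial order (default 3); must be `< window`.
#' @return Numeric vector, same length as `x`.
#' @export
savgol_smooth <- function(x, window = 31L, order = 3L) {
  window <- as.integer(window)
  order <- as.integer(order)
  assert_that(window %% 2L == 1L, "window must be odd (got %d)", window)
  assert_that(order >= 0L && order < window, "order must satisfy 0 <= order < window")
  assert_that(!anyNA(x), "x contains missing values; fill gaps first")
  n <- length(x)
  if (n < window) {
    abort(sprintf(
      "series length %d is shorter than the %d-frame window; use a smaller window",
      n, window), class = "kneegait_error")
  }
  h <- (window - 1L) %/% 2L
  A <- outer(-h:h, 0:order, "^")
  w0 <- (A %*% solve(crossprod(A), t(A)))[h + 1L, ]

  out <- numeric(n)
  # interior: convolution with the centre-row weights
  idx <- (h + 1L):(n - h)
  out[idx] <- as.numeric(stats::filter(x, rev(w0), sides = 2))[idx]
  # edges: refit on the truncated window, evaluate at the sample itself;
  # the order drops when the truncated window has too few points
  for (i in seq_len(h)) {
    oe <- min(order, i + h - 1L)
    li <- 1:(i + h)
    Ai <- outer(li - i, 0:oe, "^")
    out[i] <- (Ai %*% solve(crossprod(Ai), crossprod(Ai, x[li])))[i]
    ri <- (n - i - h + 1L):n
    Ar <- outer(ri - (n - i + 1L), 0:oe, "^")
    out[n - i + 1L] <- (Ar %*% solve(crossprod(Ar), crossprod(Ar, x[ri])))[h + 1L]
  }
  out
}

#' Linear interpolation of short gaps
#'
#' Fills interior runs of missing samples no longer than `max_gap` frames by
#' linear interpolation between the bracketing observations. Longer interior
#' gaps and any leading/trailing missing samples are left untouched (never
#' extrapolated) and reported in the `gap_report` attribute, which quality
#' control uses to reject cycles crossing an unfillable marker discontinuity.
#'
#' @param x Numeric vector, `NA` marking missing samples.
#' @param max_gap Longest gap, in frames, that may be interpolated.
#' @return `x` with short interior gaps filled; attribute `gap_report` is a
#'   tibble (`start`, `end`, `length`, `filled`) with one row per gap.
#' @export
fill_gaps <- function(x, max_gap = 10L) {
  n <- length(x)
  miss <- is.na(x)
  if (!any(miss)) {
    attr(x, "gap_report") <- tibble(start = integer(), end = integer(),
                                    length = integer(), filled = logical())
    return(x)
  }
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gaps <- tibble(start = starts[r$values], end = ends[r$values],
                 length = r$lengths[r$values])
  interior <- gaps$start > 1L & gaps$end < n
  gaps$filled <- interior & gaps$length <= max_gap
  out <- x
  for (i in which(gaps$filled)) {
    s <- gaps$start[i]; e <- gaps$end[i]
    out[s:e] <- approx(c(s - 1L, e + 1L), x[c(s - 1L, e + 1L)], xout = s:e)$y
  }
  attr(out, "gap_report") <- gaps
  out
}

#' Time-normalize one gait cycle to a percentage grid
#'
#' Resamples a curve covering exactly one gait cycle onto `n_points` evenly
#' spaced cycle percentages (0 to 100 inclusive; the conventional grid has
#' 101 points so that integer percents are grid indices) by piecewise linear
#' interpolation. Endpoints are preserved exactly and a 101-point input is
#' returned unchanged, making the operation idempotent at native resolution.
#'
#' @param x Numeric samples spanning the cycle; assumed uniformly spaced
#'   unless `time` is given.
#' @param n_points Grid size (default 101).
#' @param time Optional sample times (same length as `x`); need not be
#'   uniform.
#' @return Tibble with columns `percent` (0..100) and `value`.
#' @export
time_normalize <- function(x, n_points = 101L, time = NULL) {
  assert_that(length(x) >= 2L, "at least 2 samples required to normalize a cycle")
  assert_that(!anyNA(x), "x contains missing values; fill gaps first")
  if (is.null(time)) time <- seq_along(x)
  check_time(time)
  pct <- seq(0, 100, length.out = n_points)
  t_out <- time[1] + (time[length(time)] - time[1]) * pct / 100
  tibble(percent = pct, value = approx(time, x, xout = t_out)$y)
}

#' Pooled-dataset outlier mask
#'
#' Flags which values of a pooled sample lie within `k` standard deviations
#' of the pooled mean. Mean and SD are computed once on the full input (no
#' iterative re-masking); a zero-variance sample keeps everything. The
#' +/- 3 SD threshold applied to the pooled per-cycle dataset is the
#' conventional screen for tracking artefacts before per-participant
#' averaging.
#'
#' @param x Numeric values (pooled across cycles/participants); `NA` values
#'   are kept (they carry their own missingness downstream).
#' @param k SD multiplier (default 3).
#' @return Logical vector, `TRUE` = keep.
#' @export
outlier_mask <- function(x, k = 3) {
  assert_that(sum(is.finite(x)) >= 3L, "need at least 3 finite values")
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(x)))
  is.na(x) | abs(x - m) <= k * s
}
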