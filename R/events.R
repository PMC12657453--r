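# Gait event detection from vertical marker displacement.
#
# Heel strike is taken as a prominent local minimum of the vertical heel
# trajectory; toe off as the instant of maximum upward toe-marker velocity
# within each rise out of the stance plateau. Both are the common
# displacement-based definitions when no force plate is available.

# prominence of peak i in y (peaks = local maxima)
peak_prominence <- function(y, i) {
  n <- length(y)
  left <- if (i == 1) y[1] else {
    j <- i - 1; lo <- y[i]
    while (j >= 1 && y[j] <= y[i]) { lo <- min(lo, y[j]); j <- j - 1 }
    lo
  }
  right <- if (i == n) y[n] else {
    j <- i + 1; lo <- y[i]
    while (j <= n && y[j] <= y[i]) { lo <- min(lo, y[j]); j <- j + 1 }
    lo
  }
  y[i] - max(left, right)
}

# prominent local maxima with a refractory interval, sub-frame refinement
find_peaks <- function(y, time, min_interval, prominence_frac) {
  n <- length(y)
  if (n < 3) return(numeric())
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(cand) == 0) return(numeric())
  prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
  rng <- diff(quantile(y, c(0.05, 0.95), names = FALSE))
  # absolute floor guards against float-noise "peaks" on flat signals
  floor_ <- 1e-9 * (1 + max(abs(y)))
  cand <- cand[prom > pmax(prominence_frac * rng, floor_)]
  if (length(cand) == 0) return(numeric())
  # refractory rule: keep the taller of any two peaks closer than min_interval
  cand <- cand[order(y[cand], decreasing = TRUE)]
  kept <- integer()
  for (i in cand) {
    if (all(abs(time[i] - time[kept]) >= min_interval)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  # parabolic refinement around each retained sample
  vapply(kept, function(i) {
    if (i == 1L || i == n) return(time[i])
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    delta <- if (denom == 0) 0 else 0.5 * (y[i - 1] - y[i + 1]) / denom
    delta <- max(min(delta, 0.5), -0.5)
    time[i] + delta * (time[i + 1] - time[i - 1]) / 2
  }, numeric(1))
}

#' Detect heel-strike times from a vertical heel trajectory
#'
#' Heel strikes are the prominent local minima of the (smoothed, gap-free)
#' vertical heel displacement: prominence must exceed `prominence_frac`
#' times the trajectory's 5th-to-95th percentile range, minima closer
#' together than `min_interval` are resolved in favour of the deeper one
#' (a refractory rule bounding cadence at 240 steps/min by default), and the
#' returned times are refined below the frame period by parabolic
#' interpolation through the three samples around each minimum.
#'
#' @param height Vertical heel position in metres, smoothed and gap-filled.
#' @param frame_rate Sampling rate in Hz (used when `time` is absent).
#' @param min_interval Minimum separation between events, seconds.
#' @param prominence_frac Adaptive prominence threshold as a fraction of the
#'   5-95 percentile range (default 0.2).
#' @param time Optional explicit sample times in seconds.
#' @return Numeric vector of event times in seconds (possibly empty). A flat
#'   trajectory (range under 1 mm) yields an empty result with a warning.
#' @export
detect_heel_strikes <- function(height, frame_rate, min_interval = 0.5,
                                prominence_frac = 0.2, time = NULL) {
  assert_that(!anyNA(height), "height contains missing values; fill gaps first")
  if (is.null(time)) time <- (seq_along(height) - 1) / frame_rate
  if (diff(range(height)) < 1e-3) {
    warn("vertical trajectory is flat (range < 1 mm); no heel strikes detected")
    return(numeric())
  }
  find_peaks(-height, time, min_interval, prominence_frac)
}

#' Detect toe-off times from a vertical toe trajectory
#'
#' Toe offs are the onsets of rapid vertical rise of the toe marker: within
#' each rise out of the stance plateau, the instant of maximum upward
#' velocity, with velocity computed by central difference on the smoothed
#' trajectory. Prominence thresholding, the refractory rule and parabolic
#' sub-frame refinement mirror [detect_heel_strikes()], applied to the
#' velocity signal.
#'
#' @inheritParams detect_heel_strikes
#' @param height Vertical toe position in metres, smoothed and gap-filled.
#' @return Numeric vector of event times in seconds (possibly empty).
#' @export
detect_toe_offs <- function(height, frame_rate, min_interval = 0.5,
                            prominence_frac = 0.2, time = NULL) {
  assert_that(!anyNA(height), "height contains missing values; fill gaps first")
  n <- length(height)
  if (is.null(time)) time <- (seq_len(n) - 1) / frame_rate
  if (diff(range(height)) < 1e-3) {
    warn("vertical trajectory is flat (range < 1 mm); no toe offs detected")
    return(numeric())
  }
  if (n < 3) return(numeric())
  v <- numeric(n)
  v[2:(n - 1)] <- (height[3:n] - height[1:(n - 2)]) / (time[3:n] - time[1:(n - 2)])
  v[1] <- v[2]; v[n] <- v[n - 1]
  find_peaks(v, time, min_interval, prominence_frac)
}

#' Detect all gait events of a trial
#'
#' Runs heel-strike and toe-off detection on the heel and toe markers of
#' both feet and assembles a tidy event table. Marker naming follows the
#' `L_heel`/`R_heel`/`L_toe`/`R_toe` convention; vertical trajectories are
#' gap-filled and Savitzky-Golay smoothed before detection.
#'
#' @param markers A [marker_set()] (raw or conditioned; vertical profiles
#'   are gap-filled and smoothed here with landmark-specific windows).
#' @param min_interval Refractory interval in seconds.
#' @param heel_window,toe_window,smooth_order Savitzky-Golay settings
#'   applied to the vertical trajectories before detection. The heel-strike
#'   landmark (a sharp, locally symmetric height minimum) tolerates heavy
#'   smoothing, so the heel keeps the 31-frame trajectory window; the
#'   toe-off landmark (a broad velocity peak) is skewed by long windows
#'   under marker noise, so the toe uses a 19-frame window (about 0.32 s
#'   at 60 Hz).
#' @param max_gap Longest marker gap interpolated, frames.
#' @return A tibble of class `gait_events` with columns `foot` ("L"/"R"),
#'   `event` ("heel_strike"/"toe_off") and `time` (seconds), ordered in time
#'   within foot and event type.
#' @export
detect_gait_events <- function(markers, min_interval = 0.5,
                               heel_window = 31L, toe_window = 19L,
                               smooth_order = 3L, max_gap = 10L) {
  assert_that(inherits(markers, "marker_set"), "'markers' must be a marker_set")
  fr <- markers$frame_rate
  one_foot <- function(foot) {
    heel <- marker_xyz(markers, paste0(foot, "_heel"))
    toe <- marker_xyz(markers, paste0(foot, "_toe"))
    cond <- function(x, time, w) {
      v <- condition_signal(x, time, max_gap)$values
      if (w > 1 && length(v) >= w) savgol_smooth(v, w, smooth_order) else v
    }
    hv <- cond(heel$vertical, heel$time, heel_window)
    tv <- cond(toe$vertical, toe$time, toe_window)
    bind_rows(
      tibble(foot = foot, event = "heel_strike",
             time = detect_heel_strikes(hv, fr, min_interval, time = heel$time)),
      tibble(foot = foot, event = "toe_off",
             time = detect_toe_offs(tv, fr, min_interval, time = toe$time))
    )
  }
  out <- bind_rows(one_foot("L"), one_foot("R")) %>%
    arrange(.data$foot, .data$event, .data$time)
  class(out) <- c("gait_events", class(out))
  attr(out, "frame_rate") <- fr
  out
}

#' Stance intervals from paired gait events
#'
#' Pairs each heel strike of a foot with the first subsequent toe off of the
#' same foot, yielding non-overlapping stance intervals. A toe off preceding
#' the first heel strike, or a heel strike with no following toe off before
#' the next ipsilateral heel strike, is dropped (reported via the
#' `dropped_events` attribute). After pairing, exactly one toe off lies
#' between consecutive heel strikes of the foot.
#'
#' @param events A `gait_events` tibble (see [detect_gait_events()]).
#' @param foot `"L"` or `"R"`.
#' @return Tibble with columns `foot`, `start`, `end` (seconds).
#' @export
stance_intervals <- function(events, foot = c("L", "R")) {
  foot <- match.arg(foot)
  hs <- sort(events$time[events$foot == foot & events$event == "heel_strike"])
  to <- sort(events$time[events$foot == foot & events$event == "toe_off"])
  dropped <- 0L
  out <- list()
  used <- rep(FALSE, length(to))
  for (h in hs) {
    cand <- which(!used & to > h)
    if (length(cand)) {
      used[cand[1]] <- TRUE
      out[[length(out) + 1L]] <- tibble(foot = foot, start = h,
                                        end = to[cand[1]])
    } else {
      dropped <- dropped + 1L
    }
  }
  dropped <- dropped + sum(!used)
  res <- if (length(out)) bind_rows(out) else
    tibble(foot = character(), start = numeric(), end = numeric())
  attr(res, "dropped_events") <- dropped
  res
}
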