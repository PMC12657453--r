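# Spatiotemporal parameters and peak joint angles.

#' Walking direction of a trial
#'
#' Estimates the forward direction as the first principal direction of the
#' pelvis marker's horizontal displacement, oriented along the net
#' displacement; the lateral axis is the horizontal perpendicular. All
#' length/width projections use these axes, which makes the derived
#' parameters invariant to rotations of the laboratory frame.
#'
#' @param markers A [marker_set()] (conditioned: gaps filled).
#' @param pelvis_marker Name of the pelvis-region marker.
#' @return Unit-length numeric vector `c(h1, h2)` in the horizontal plane,
#'   with attribute `lateral` (the perpendicular unit vector).
#' @export
walking_direction <- function(markers, pelvis_marker = "pelvis") {
  p <- marker_xyz(markers, pelvis_marker)
  ok <- is.finite(p$h1) & is.finite(p$h2)
  h <- cbind(p$h1[ok], p$h2[ok])
  net <- h[nrow(h), ] - h[1, ]
  if (sqrt(sum(net^2)) < 0.5) {
    abort("trial too short: net pelvis displacement under 0.5 m",
          class = "kneegait_error")
  }
  pc <- stats::prcomp(h, center = TRUE, scale. = FALSE)$rotation[, 1]
  if (sum(pc * net) < 0) pc <- -pc
  fwd <- pc / sqrt(sum(pc^2))
  attr(fwd, "lateral") <- c(-fwd[2], fwd[1])
  fwd
}

heel_coord <- function(markers, foot, at, direction, axis = c("forward", "lateral")) {
  axis <- match.arg(axis)
  u <- if (axis == "forward") as.numeric(direction) else attr(direction, "lateral")
  m <- marker_xyz(markers, paste0(foot, "_heel"))
  interp_at(m$time, m$h1, at) * u[1] + interp_at(m$time, m$h2, at) * u[2]
}

#' Gait speed over one cycle
#'
#' Forward displacement of the pelvis marker over the cycle divided by the
#' cycle duration. Pelvis progression is steadier than heel progression;
#' a heel-based alternative is available via `source = "heels"` (mean of
#' both heels' forward displacement).
#'
#' @param markers A [marker_set()].
#' @param start,end Cycle-bounding heel-strike times (s).
#' @param direction Output of [walking_direction()].
#' @param pelvis_marker Pelvis marker name.
#' @param source `"pelvis"` (default) or `"heels"`.
#' @return Speed in m/s.
#' @export
gait_speed <- function(markers, start, end, direction,
                       pelvis_marker = "pelvis", source = c("pelvis", "heels")) {
  source <- match.arg(source)
  assert_that(end > start, "cycle end must follow start")
  u <- as.numeric(direction)
  if (source == "pelvis") {
    p <- marker_xyz(markers, pelvis_marker)
    disp <- (interp_at(p$time, p$h1, end) - interp_at(p$time, p$h1, start)) * u[1] +
      (interp_at(p$time, p$h2, end) - interp_at(p$time, p$h2, start)) * u[2]
  } else {
    disp <- mean(vapply(c("L", "R"), function(f) {
      heel_coord(markers, f, end, direction) - heel_coord(markers, f, start, direction)
    }, numeric(1)))
  }
  disp / (end - start)
}

#' Stride length of one cycle
#'
#' Forward-projected distance between the ipsilateral heel positions at the
#' two heel strikes bounding the cycle.
#'
#' @inheritParams gait_speed
#' @param foot `"L"` or `"R"` (the cycle's foot).
#' @return Stride length in metres.
#' @export
stride_length <- function(markers, foot, start, end, direction) {
  heel_coord(markers, foot, end, direction) -
    heel_coord(markers, foot, start, direction)
}

#' Step length between consecutive contralateral heel strikes
#'
#' Forward-projected distance between the landing foot's heel at its heel
#' strike and the other heel at its preceding heel strike. The step is
#' attributed to the landing foot.
#'
#' @inheritParams gait_speed
#' @param landing_foot Foot striking at `hs_landing`.
#' @param hs_landing,hs_previous Heel-strike times (s) of the landing foot
#'   and of the other foot's preceding strike.
#' @return Step length in metres.
#' @export
step_length <- function(markers, landing_foot, hs_landing, hs_previous, direction) {
  other <- setdiff(c("L", "R"), landing_foot)
  heel_coord(markers, landing_foot, hs_landing, direction) -
    heel_coord(markers, other, hs_previous, direction)
}

#' Step width at heel-strike instants
#'
#' Absolute lateral-axis distance between the left and right heel positions,
#' each evaluated at its own bounding heel strike.
#'
#' @inheritParams gait_speed
#' @param hs_left,hs_right Heel-strike times (s) of the left and right foot.
#' @return Step width in metres.
#' @export
step_width <- function(markers, hs_left, hs_right, direction) {
  abs(heel_coord(markers, "L", hs_left, direction, "lateral") -
        heel_coord(markers, "R", hs_right, direction, "lateral"))
}

#' Cadence from cycle duration
#'
#' `120 / duration`: one gait cycle comprises two steps.
#'
#' @param duration Cycle duration in seconds.
#' @return Cadence in steps/min.
#' @export
cadence <- function(duration) {
  assert_that(all(duration > 0), "duration must be positive")
  120 / duration
}

# total overlap between one interval [a1,a2] and a set of intervals
interval_overlap <- function(a1, a2, starts, ends) {
  lo <- pmax(a1, starts)
  hi <- pmin(a2, ends)
  sum(pmax(hi - lo, 0))
}

#' Double support percentage of one cycle
#'
#' Proportion of the gait cycle during which both feet are in ground
#' contact: the total duration, inside the cycle, where a left and a right
#' stance interval overlap, divided by the cycle duration. Stance intervals
#' are built from the full trial's event table so overlap spanning the cycle
#' boundary is counted. Returns `NA` when the contralateral foot has no
#' events inside the cycle.
#'
#' @param events A `gait_events` tibble for the whole trial.
#' @param start,end Cycle bounds (s).
#' @param foot The cycle's foot (`"L"` or `"R"`).
#' @return Percentage in `[0, 100]`, or `NA`.
#' @export
double_support_pct <- function(events, start, end, foot = "L") {
  contra <- setdiff(c("L", "R"), foot)
  sl <- stance_intervals(events, "L")
  sr <- stance_intervals(events, "R")
  if (nrow(sl) == 0 || nrow(sr) == 0) return(NA_real_)
  sc <- if (contra == "L") sl else sr
  # contralateral stance information must reach into the cycle at all
  if (!any(sc$end > start & sc$start < end)) return(NA_real_)
  # an unpaired leading contralateral toe-off inside the cycle means the
  # stance interval it terminates was never observed -> overlap at cycle
  # onset is unknowable, mark the cycle missing
  hs_c <- events$time[events$foot == contra & events$event == "heel_strike"]
  to_c <- events$time[events$foot == contra & events$event == "toe_off"]
  lead_to <- to_c[to_c >= start & to_c < end & to_c < min(c(hs_c, Inf))]
  if (length(lead_to)) return(NA_real_)
  total <- 0
  for (i in seq_len(nrow(sl))) {
    a1 <- max(sl$start[i], start); a2 <- min(sl$end[i], end)
    if (a2 > a1) total <- total + interval_overlap(a1, a2, sr$start, sr$end)
  }
  100 * total / (end - start)
}

#' Step length asymmetry
#'
#' Percentage difference between the mean left and mean right step lengths
#' relative to their average: `100 * |mean(L) - mean(R)| / (0.5 * (mean(L)
#' + mean(R)))`. Symmetric in its arguments.
#'
#' @param left_steps,right_steps Step lengths in metres, attributed to the
#'   landing foot.
#' @return Asymmetry in percent.
#' @export
step_length_asymmetry <- function(left_steps, right_steps) {
  ml <- mean(left_steps, na.rm = TRUE)
  mr <- mean(right_steps, na.rm = TRUE)
  assert_that(is.finite(ml) && is.finite(mr), "step lengths required for both feet")
  denom <- 0.5 * (ml + mr)
  assert_that(denom != 0, "mean step length is zero; asymmetry undefined")
  100 * abs(ml - mr) / denom
}

peak_measure_map <- list(
  knee_angle = c(max = "flexion", min = "extension"),
  hip_flexion = c(max = "flexion", min = "extension"),
  hip_adduction = c(max = "adduction", min = "abduction"),
  hip_rotation = c(max = "internal_rotation", min = "external_rotation"),
  ankle_angle = c(max = "dorsiflexion", min = "plantarflexion"),
  subtalar_angle = c(max = "inversion", min = "eversion"),
  pelvis_tilt = c(max = "peak"),
  pelvis_list = c(max = "peak"),
  pelvis_rotation = c(max = "peak")
)

#' Peak joint angles of one normalized cycle
#'
#' For each degree of freedom, the signed extrema of the time-normalized
#' curve: flexion / adduction / internal-rotation / dorsiflexion / inversion
#' peaks are curve maxima, their antagonist peaks are curve minima, signs
#' kept in the model's convention (so negative peaks are reported as such).
#' Pelvis degrees of freedom report a single signed peak (the maximum).
#'
#' @param curves Numeric matrix (grid points x dofs) with dof column names,
#'   e.g. the `curves` entry of one [segment_cycles()] row.
#' @return Tidy tibble with `dof`, `side` (`"L"`, `"R"` or `NA`), `measure`
#'   and `value` (degrees).
#' @export
peak_angles <- function(curves) {
  assert_that(is.matrix(curves) && !is.null(colnames(curves)),
              "'curves' must be a named matrix")
  purrr::map_dfr(colnames(curves), function(d) {
    base <- sub("_[lr]$", "", d)
    side <- if (grepl("_l$", d)) "L" else if (grepl("_r$", d)) "R" else NA_character_
    mm <- peak_measure_map[[base]]
    if (is.null(mm)) return(tibble())
    v <- curves[, d]
    out <- tibble(dof = base, side = side, measure = unname(mm["max"]),
                  value = max(v, na.rm = TRUE))
    if ("min" %in% names(mm)) {
      out <- bind_rows(out, tibble(dof = base, side = side,
                                   measure = unname(mm["min"]),
                                   value = min(v, na.rm = TRUE)))
    }
    out
  })
}

#' Per-cycle spatiotemporal parameters of a trial
#'
#' Computes, for every accepted cycle of one foot, the six spatiotemporal
#' parameters: gait speed, stride length, step width, cadence, double
#' support percentage, and the two step lengths (attributed to the landing
#' foot) from which step-length asymmetry is later derived per participant.
#'
#' @param markers Conditioned [marker_set()].
#' @param events Trial `gait_events`.
#' @param cycles Cycle tibble from [segment_cycles()] (possibly QC-filtered).
#' @param direction Optional [walking_direction()] (recomputed if `NULL`).
#' @param pelvis_marker Pelvis marker name.
#' @param speed_source `"pelvis"` or `"heels"` (see [gait_speed()]).
#' @return Tibble, one row per cycle: `foot`, `cycle`, `start`, `end`,
#'   `duration`, `gait_speed`, `stride_length`, `step_width`, `cadence`,
#'   `double_support_pct`, `step_contra`, `step_ipsi` (m).
#' @export
cycle_parameters <- function(markers, events, cycles, direction = NULL,
                             pelvis_marker = "pelvis",
                             speed_source = "pelvis") {
  if (nrow(cycles) == 0) return(tibble())
  if (is.null(direction)) direction <- walking_direction(markers, pelvis_marker)
  purrr::map_dfr(seq_len(nrow(cycles)), function(i) {
    foot <- cycles$foot[i]
    contra <- setdiff(c("L", "R"), foot)
    t0 <- cycles$start[i]; t1 <- cycles$end[i]
    hs_c <- events$time[events$foot == contra & events$event == "heel_strike"]
    hs_c <- hs_c[hs_c >= t0 & hs_c < t1]
    tc <- if (length(hs_c)) hs_c[1] else NA_real_
    sw <- if (is.na(tc)) NA_real_ else {
      if (foot == "L") step_width(markers, t0, tc, direction)
      else step_width(markers, tc, t0, direction)
    }
    tibble(
      foot = foot, cycle = cycles$cycle[i], start = t0, end = t1,
      duration = t1 - t0,
      gait_speed = gait_speed(markers, t0, t1, direction, pelvis_marker,
                              speed_source),
      stride_length = stride_length(markers, foot, t0, t1, direction),
      step_width = sw,
      cadence = cadence(t1 - t0),
      double_support_pct = double_support_pct(events, t0, t1, foot),
      step_contra = if (is.na(tc)) NA_real_ else
        step_length(markers, contra, tc, t0, direction),
      step_ipsi = if (is.na(tc)) NA_real_ else
        step_length(markers, foot, t1, tc, direction)
    )
  })
}
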