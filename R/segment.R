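#' Quality-control criteria for gait cycles
#'
#' Bundles the rules used to exclude gait cycles with abnormal timing,
#' marker discontinuities, or biomechanically implausible trajectories.
#' Duration bounds default to 0.4-2.5 s, bracketing cadences from 48 to 300
#' steps/min; plausibility bounds are per joint family in degrees.
#'
#' @param duration_bounds Length-2 numeric, admissible cycle duration (s).
#' @param max_gap_frames Longest marker gap (frames) tolerated inside a
#'   cycle; longer unfilled gaps reject the cycle.
#' @param angle_bounds Named list of length-2 numeric bounds per joint
#'   family (`knee`, `hip`, `ankle`, `subtalar`, `pelvis`), degrees.
#' @return A list of class `qc_criteria`.
#' @export
qc_criteria <- function(duration_bounds = c(0.4, 2.5),
                        max_gap_frames = 10L,
                        angle_bounds = list(
                          knee = c(-20, 100),
                          hip = c(-45, 60),
                          ankle = c(-60, 50),
                          subtalar = c(-60, 60),
                          pelvis = c(-40, 40)
                        )) {
  assert_that(duration_bounds[1] < duration_bounds[2],
              "duration bounds must be ordered")
  for (nm in names(angle_bounds)) {
    assert_that(angle_bounds[[nm]][1] < angle_bounds[[nm]][2],
                "angle bounds for '%s' must be ordered", nm)
  }
  structure(list(duration_bounds = duration_bounds,
                 max_gap_frames = as.integer(max_gap_frames),
                 angle_bounds = angle_bounds),
            class = "qc_criteria")
}

dof_family <- function(dof) {
  dplyr::case_when(
    grepl("knee", dof) ~ "knee",
    grepl("hip", dof) ~ "hip",
    grepl("subtalar", dof) ~ "subtalar",
    grepl("ankle", dof) ~ "ankle",
    grepl("pelvis|pelvic", dof) ~ "pelvis",
    TRUE ~ NA_character_
  )
}

#' Segment a trial into gait cycles
#'
#' Cuts the joint-angle series into gait cycles of one foot, each defined
#' from one heel strike to the subsequent ipsilateral heel strike, and
#' time-normalizes every degree of freedom onto the 0-100% grid by linear
#' interpolation at the cycle's own event times. Contralateral heel strike
#' and both toe offs falling inside the cycle are recorded as percentages
#' of the cycle.
#'
#' @param events A `gait_events` tibble (see [detect_gait_events()]).
#' @param angles A [joint_angle_series()] (already smoothed as desired).
#' @param foot `"L"` or `"R"`.
#' @param n_points Normalization grid size (default 101).
#' @return Tibble with one row per cycle: `foot`, `cycle`, `start`, `end`,
#'   `duration`, list-column `curves` (a `n_points` x dofs matrix in
#'   degrees) and list-column `cycle_events` (named percentages).
#' @export
segment_cycles <- function(events, angles, foot = c("L", "R"),
                           n_points = 101L) {
  foot <- match.arg(foot)
  assert_that(inherits(angles, "joint_angle_series"),
              "'angles' must be a joint_angle_series")
  hs <- sort(events$time[events$foot == foot & events$event == "heel_strike"])
  if (length(hs) < 2) {
    return(tibble(foot = character(), cycle = integer(), start = numeric(),
                  end = numeric(), duration = numeric(),
                  curves = list(), cycle_events = list()))
  }
  contra <- setdiff(c("L", "R"), foot)
  hs_c <- events$time[events$foot == contra & events$event == "heel_strike"]
  to_i <- events$time[events$foot == foot & events$event == "toe_off"]
  to_c <- events$time[events$foot == contra & events$event == "toe_off"]
  tm <- angles$data$time
  dofs <- angles$dof_names

  purrr::map_dfr(seq_len(length(hs) - 1L), function(k) {
    t0 <- hs[k]; t1 <- hs[k + 1L]
    grid <- t0 + (t1 - t0) * seq(0, 1, length.out = n_points)
    mat <- vapply(dofs, function(d) interp_at(tm, angles$data[[d]], grid),
                  numeric(n_points))
    pct <- function(x) {
      x <- x[x >= t0 & x < t1]
      if (length(x)) 100 * (x[1] - t0) / (t1 - t0) else NA_real_
    }
    tibble(foot = foot, cycle = k, start = t0, end = t1, duration = t1 - t0,
           curves = list(mat),
           cycle_events = list(c(contra_heel_strike = pct(hs_c),
                                 ipsi_toe_off = pct(to_i),
                                 contra_toe_off = pct(to_c))))
  })
}

#' Apply quality control to segmented cycles
#'
#' Rejects a cycle when its duration falls outside the admissible bounds
#' (`abnormal_timing`), when an unfilled marker gap longer than
#' `max_gap_frames` overlaps the cycle (`marker_discontinuity`), or when any
#' degree of freedom leaves its joint-family plausibility bounds
#' (`implausible`). One reason code is reported per rejected cycle (checked
#' in that order).
#'
#' @param cycles Output of [segment_cycles()].
#' @param criteria A [qc_criteria()] object.
#' @param gap_report Optional tibble of unfilled marker gaps with columns
#'   `start_time`, `end_time` (seconds), as assembled by [run_trial()].
#' @return List with `accepted` (cycles tibble) and `rejections` (tibble of
#'   `foot`, `cycle`, `reason`).
#' @export
qc_cycles <- function(cycles, criteria = qc_criteria(), gap_report = NULL) {
  if (nrow(cycles) == 0) {
    return(list(accepted = cycles,
                rejections = tibble(foot = character(), cycle = integer(),
                                    reason = character())))
  }
  reason <- vapply(seq_len(nrow(cycles)), function(i) {
    dur <- cycles$duration[i]
    if (dur < criteria$duration_bounds[1] || dur > criteria$duration_bounds[2]) {
      return("abnormal_timing")
    }
    if (!is.null(gap_report) && nrow(gap_report) > 0) {
      hit <- gap_report$end_time >= cycles$start[i] &
        gap_report$start_time <= cycles$end[i]
      if (any(hit)) return("marker_discontinuity")
    }
    mat <- cycles$curves[[i]]
    fams <- dof_family(colnames(mat))
    for (j in seq_len(ncol(mat))) {
      b <- criteria$angle_bounds[[fams[j]]]
      if (!is.null(b)) {
        v <- mat[, j]
        if (any(v < b[1] | v > b[2], na.rm = TRUE)) return("implausible")
      }
    }
    NA_character_
  }, character(1))
  list(
    accepted = cycles[is.na(reason), , drop = FALSE],
    rejections = tibble(foot = cycles$foot, cycle = cycles$cycle,
                        reason = reason)[!is.na(reason), ]
  )
}
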