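# Trial- and cohort-level orchestration: conditioning -> events ->
# segmentation -> QC -> parameters -> group statistics -> phase analysis.

#' Pipeline configuration
#'
#' All tunable settings of the analysis pipeline with their defaults:
#' marker-trajectory smoothing (31-frame cubic Savitzky-Golay, about 0.52 s
#' at 60 Hz), kinematic-curve smoothing (11-frame cubic: angle curves carry
#' meaningful content up to the fourth gait harmonic, which a half-second
#' window would attenuate), gap filling, event detection, QC, pooled
#' outlier screening, and bootstrap settings for phase analysis.
#'
#' @param marker_smooth,angle_smooth Enable Savitzky-Golay smoothing of
#'   marker trajectories / angle curves (each individually switchable).
#' @param marker_window,marker_order,angle_window,angle_order Filter
#'   settings (frames / polynomial order).
#' @param event_heel_window,event_toe_window,event_order Savitzky-Golay
#'   settings for the vertical profiles inside event detection (see
#'   [detect_gait_events()]); applied to the raw gap-filled trajectories,
#'   independent of `marker_window`.
#' @param max_gap Longest marker gap interpolated, frames.
#' @param min_interval Event refractory interval, seconds.
#' @param prominence_frac Adaptive event prominence threshold.
#' @param n_points Cycle normalization grid size.
#' @param qc [qc_criteria()] object.
#' @param outlier_k Pooled outlier screen SD multiplier.
#' @param speed_source `"pelvis"` or `"heels"`.
#' @param B,alpha,min_run,ci_type Bootstrap band/region settings.
#' @param vertical_axis Vertical coordinate axis of the marker files.
#' @return A `gait_config` list.
#' @export
gait_config <- function(marker_smooth = TRUE, marker_window = 31L,
                        marker_order = 3L, angle_smooth = TRUE,
                        angle_window = 11L, angle_order = 3L,
                        event_heel_window = 31L, event_toe_window = 19L,
                        event_order = 3L,
                        max_gap = 10L, min_interval = 0.5,
                        prominence_frac = 0.2, n_points = 101L,
                        qc = qc_criteria(), outlier_k = 3,
                        speed_source = "pelvis", B = 1000L, alpha = 0.05,
                        min_run = 3L, ci_type = "expanded",
                        vertical_axis = "Y") {
  structure(as.list(environment()), class = "gait_config")
}

# fill short gaps, interpolate anything left so filters can run, and
# report unfilled gaps with their time extent
condition_signal <- function(x, time, max_gap) {
  filled <- fill_gaps(x, max_gap)
  rep_ <- attr(filled, "gap_report")
  unfilled <- rep_[!rep_$filled, , drop = FALSE]
  if (anyNA(filled)) {
    ok <- !is.na(filled)
    filled <- approx(which(ok), filled[ok], xout = seq_along(filled),
                     rule = 2)$y
  }
  list(values = filled,
       gaps = if (nrow(unfilled)) tibble(start_time = time[unfilled$start],
                                         end_time = time[unfilled$end])
       else tibble(start_time = numeric(), end_time = numeric()))
}

condition_markers <- function(markers, config) {
  d <- markers$data
  gaps <- list()
  for (col in setdiff(names(d), c("frame", "time"))) {
    cs <- condition_signal(d[[col]], d$time, config$max_gap)
    v <- cs$values
    if (config$marker_smooth && length(v) >= config$marker_window) {
      v <- savgol_smooth(v, config$marker_window, config$marker_order)
    }
    d[[col]] <- v
    if (nrow(cs$gaps)) {
      gaps[[col]] <- mutate(cs$gaps, marker = sub("_[XYZ]$", "", col))
    }
  }
  out <- marker_set(d, markers$frame_rate, markers$units,
                    markers$vertical_axis)
  attr(out, "gap_report") <- if (length(gaps)) bind_rows(gaps) else
    tibble(start_time = numeric(), end_time = numeric(), marker = character())
  out
}

condition_angles <- function(angles, config) {
  if (!config$angle_smooth) return(angles)
  d <- angles$data
  for (col in angles$dof_names) {
    if (nrow(d) >= config$angle_window) {
      d[[col]] <- savgol_smooth(d[[col]], config$angle_window,
                                config$angle_order)
    }
  }
  joint_angle_series(d)
}

#' Run the full pipeline on one trial
#'
#' Conditions the marker and angle data (gap filling and Savitzky-Golay
#' smoothing), detects gait events, segments and time-normalizes cycles
#' for both feet, applies quality control, and extracts per-cycle
#' spatiotemporal parameters and peak joint angles.
#'
#' @param markers A [marker_set()] or path to a TRC file.
#' @param angles A [joint_angle_series()] or path to a MOT file.
#' @param config A [gait_config()].
#' @return List with conditioned `markers`/`angles`, `events`, `cycles`
#'   (accepted, both feet), `rejections`, `params` (per-cycle tibble),
#'   `peaks` (tidy per-cycle peak tibble) and `direction`.
#' @export
run_trial <- function(markers, angles, config = gait_config()) {
  if (is.character(markers)) markers <- read_trc(markers, config$vertical_axis)
  if (is.character(angles)) angles <- read_mot(angles)
  raw_markers <- markers
  markers <- condition_markers(markers, config)
  angles <- condition_angles(angles, config)
  gap_report <- attr(markers, "gap_report")

  # events are timed on the raw gap-filled profiles with their own window:
  # the long spatial-smoothing window would skew the toe-velocity peak
  events <- detect_gait_events(raw_markers, min_interval = config$min_interval,
                               heel_window = config$event_heel_window,
                               toe_window = config$event_toe_window,
                               smooth_order = config$event_order,
                               max_gap = config$max_gap)
  direction <- walking_direction(markers)

  cycles <- bind_rows(segment_cycles(events, angles, "L", config$n_points),
                      segment_cycles(events, angles, "R", config$n_points))
  qc <- qc_cycles(cycles, config$qc, gap_report)
  accepted <- qc$accepted
  params <- cycle_parameters(markers, events, accepted,
                             direction = direction,
                             speed_source = config$speed_source)
  peaks <- if (nrow(accepted)) purrr::map_dfr(seq_len(nrow(accepted)),
    function(i) mutate(peak_angles(accepted$curves[[i]]),
                       foot = accepted$foot[i], cycle = accepted$cycle[i]))
    else tibble()
  list(markers = markers, angles = angles, events = events,
       cycles = accepted, rejections = qc$rejections, params = params,
       peaks = peaks, direction = direction)
}

# participant-side mean curves for one dof family from pooled cycles
side_mean_curves <- function(trial_results, dof) {
  rows <- purrr::map_dfr(trial_results, function(tr) {
    cyc <- tr$result$cycles
    if (nrow(cyc) == 0) return(tibble())
    purrr::map_dfr(seq_len(nrow(cyc)), function(i) {
      col <- if (dof %in% colnames(cyc$curves[[i]])) dof else
        paste0(dof, "_", tolower(cyc$foot[i]))
      if (!col %in% colnames(cyc$curves[[i]])) return(tibble())
      tibble(participant = tr$participant, foot = cyc$foot[i],
             curve = list(cyc$curves[[i]][, col]))
    })
  })
  if (nrow(rows) == 0) return(rows)
  rows %>%
    group_by(.data$participant, .data$foot) %>%
    summarise(curve = list(colMeans(do.call(rbind, .data$curve))),
              .groups = "drop")
}

#' Run the full pipeline on two cohorts and compare them
#'
#' Processes every trial of both cohorts, pools cycles, screens outliers on
#' the pooled dataset, summarises per participant, and produces the three
#' standard comparisons: the demographics/spatiotemporal table (group A,
#' conventionally the control group, versus group B), the 15-row peak-angle
#' table (affected and unaffected side of group B versus the control
#' bilateral average), and phase-wise bootstrap comparisons of the
#' normalized kinematic curves (affected vs control, unaffected vs control,
#' affected vs unaffected).
#'
#' @param cohort_a,cohort_b [generate_cohort()] results (group A playing
#'   the control role; group B must carry `affected_side` labels for the
#'   side-specific table and phase contrasts).
#' @param config A [gait_config()].
#' @param phase_dofs Dof families for phase analysis (default knee only;
#'   any of the nine template families).
#' @param seed Optional seed for the bootstrap stage.
#' @return A `cohort_comparison` object: `$table1`, `$table2`,
#'   `$summaries`, `$phase` (nested list dof -> contrast ->
#'   [difference_regions()] result), `$cycle_counts`.
#' @export
run_cohort <- function(cohort_a, cohort_b, config = gait_config(),
                       phase_dofs = "knee_angle", seed = NULL) {
  process <- function(cohort) {
    purrr::map(seq_len(nrow(cohort$trials)), function(i) {
      list(participant = cohort$trials$participant[i],
           result = run_trial(cohort$trials$markers[[i]],
                              cohort$trials$angles[[i]], config))
    })
  }
  res_a <- process(cohort_a)
  res_b <- process(cohort_b)

  pool <- function(res) {
    params <- purrr::map_dfr(res, function(tr)
      if (nrow(tr$result$params)) mutate(tr$result$params,
                                         participant = tr$participant)
      else tibble())
    peaks <- purrr::map_dfr(res, function(tr)
      if (nrow(tr$result$peaks)) mutate(tr$result$peaks,
                                        participant = tr$participant)
      else tibble())
    # per-side dofs: attribute the ipsilateral side to the cycle's foot
    peaks <- peaks %>%
      mutate(side = dplyr::coalesce(.data$side, .data$foot)) %>%
      filter(is.na(.data$side) | .data$side == .data$foot)
    list(params = params, peaks = peaks)
  }
  pa <- pool(res_a); pb <- pool(res_b)
  sum_a <- participant_summary(pa$params, pa$peaks, config$outlier_k)
  sum_b <- participant_summary(pb$params, pb$peaks, config$outlier_k)

  demo <- function(cohort) {
    if (is.null(cohort$participants)) return(NULL)
    select(cohort$participants, "participant", "age", "sex", "bmi")
  }
  table1 <- build_table1(sum_a$spatiotemporal, sum_b$spatiotemporal,
                         demo(cohort_a), demo(cohort_b))
  affected <- select(cohort_b$participants, "participant", "affected_side")
  table2 <- build_table2(sum_a$peaks, sum_b$peaks, affected)

  if (!is.null(seed)) set.seed(seed)
  phase <- purrr::map(setNames(phase_dofs, phase_dofs), function(dof) {
    ca <- side_mean_curves(res_a, dof)
    cb <- side_mean_curves(res_b, dof)
    bilat_a <- ca %>% group_by(.data$participant) %>%
      summarise(curve = list(colMeans(do.call(rbind, .data$curve))),
                .groups = "drop")
    cb2 <- left_join(cb, affected, by = "participant") %>%
      mutate(role = dplyr::if_else(.data$foot == .data$affected_side,
                                   "affected", "unaffected"))
    mat <- function(tb) do.call(rbind, tb$curve)
    aff <- filter(cb2, .data$role == "affected")
    unaff <- filter(cb2, .data$role == "unaffected")
    list(
      affected_vs_control = difference_regions(
        mat(aff), mat(bilat_a), B = config$B, alpha = config$alpha,
        min_run = config$min_run, ci_type = config$ci_type),
      unaffected_vs_control = difference_regions(
        mat(unaff), mat(bilat_a), B = config$B, alpha = config$alpha,
        min_run = config$min_run, ci_type = config$ci_type),
      affected_vs_unaffected = difference_regions(
        mat(aff), mat(unaff), B = config$B, alpha = config$alpha,
        min_run = config$min_run, ci_type = config$ci_type)
    )
  })

  counts <- tibble(
    group = c("A", "B"),
    n_participants = c(nrow(cohort_a$participants),
                       nrow(cohort_b$participants)),
    cycles_retained = c(nrow(pa$params), nrow(pb$params)),
    cycles_rejected = c(
      sum(purrr::map_int(res_a, ~ nrow(.x$result$rejections))),
      sum(purrr::map_int(res_b, ~ nrow(.x$result$rejections))))
  )
  structure(list(table1 = table1, table2 = table2,
                 summaries = list(a = sum_a, b = sum_b),
                 phase = phase, cycle_counts = counts),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("<cohort_comparison>\n")
  print(x$cycle_counts)
  cat("\nSpatiotemporal and demographic comparison:\n")
  print(select(x$table1, "parameter", "mean_a", "sd_a", "mean_b", "sd_b",
               "p_value"), n = Inf)
  invisible(x)
}
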