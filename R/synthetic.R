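# Synthetic two-group gait cohort generator.
#
# Emits walking trials (marker trajectories + joint-angle series) whose
# group-level spatiotemporal and peak-angle structure is configurable, with
# exact ground truth for every event and parameter, so each pipeline stage
# has a known-answer test. Geometry is idealized: the heel's vertical
# trajectory is a raised cosine per cycle (unique minimum exactly at heel
# strike), the toe's a raised-cosine bump whose steepest ascent falls
# exactly at toe off, forward progression advances by the drawn step
# lengths with zero end-slope transitions, and joint angles are calibrated
# Fourier waveform templates evaluated at each foot's cycle phase.

#' Built-in group parameter targets
#'
#' Group mean/SD targets for the six spatiotemporal parameters and the
#' fifteen peak joint angles, encoding the structure of a published medial
#' knee-osteoarthritis cohort versus healthy controls (reduced speed and
#' cadence, widened steps, prolonged double support, raised asymmetry,
#' flattened knee excursion). `"koa"` peaks carry both an affected-side and
#' an unaffected-side distribution; `"control"` peaks describe the
#' bilateral average.
#'
#' @param group `"control"` or `"koa"`.
#' @return List with `spatiotemporal` (tibble: parameter, mean, sd),
#'   `peaks` (tibble: dof, measure, role, mean, sd) and `demographics`.
#' @export
group_targets <- function(group = c("control", "koa")) {
  group <- match.arg(group)
  if (group == "control") {
    list(
      spatiotemporal = tibble(
        parameter = c("gait_speed", "stride_length", "step_width_cm",
                      "cadence", "double_support_pct",
                      "step_length_asymmetry_pct"),
        mean = c(1.24, 1.32, 8.87, 112.50, 22.68, 2.75),
        sd = c(0.37, 0.55, 2.10, 12.33, 3.27, 1.17)),
      peaks = tibble(
        dof = rep(c("pelvis_tilt", "pelvis_list", "pelvis_rotation",
                    "hip_flexion", "hip_flexion", "hip_adduction",
                    "hip_adduction", "hip_rotation", "hip_rotation",
                    "knee_angle", "knee_angle", "ankle_angle", "ankle_angle",
                    "subtalar_angle", "subtalar_angle"), each = 1),
        measure = c("peak", "peak", "peak", "flexion", "extension",
                    "adduction", "abduction", "internal_rotation",
                    "external_rotation", "flexion", "extension",
                    "dorsiflexion", "plantarflexion", "inversion",
                    "eversion"),
        role = "bilateral",
        mean = c(-3.25, -3.90, 5.39, 23.07, -14.81, 5.32, -7.35, -3.02,
                 -11.41, 50.60, 2.50, 6.88, -5.43, 2.88, -10.37),
        sd = c(5.74, 4.74, 5.16, 7.06, 6.82, 4.64, 5.13, 5.85, 8.15,
               8.78, 4.90, 14.13, 19.55, 12.84, 10.86)),
      demographics = list(age_mean = 66.25, age_sd = 6.78,
                          n_male = 30, n_female = 48,
                          bmi_mean = 23.94, bmi_sd = 2.77,
                          left_affected_prop = NA_real_)
    )
  } else {
    meas <- c("peak", "peak", "peak", "flexion", "extension", "adduction",
              "abduction", "internal_rotation", "external_rotation",
              "flexion", "extension", "dorsiflexion", "plantarflexion",
              "inversion", "eversion")
    dofs <- c("pelvis_tilt", "pelvis_list", "pelvis_rotation",
              "hip_flexion", "hip_flexion", "hip_adduction", "hip_adduction",
              "hip_rotation", "hip_rotation", "knee_angle", "knee_angle",
              "ankle_angle", "ankle_angle", "subtalar_angle",
              "subtalar_angle")
    list(
      spatiotemporal = tibble(
        parameter = c("gait_speed", "stride_length", "step_width_cm",
                      "cadence", "double_support_pct",
                      "step_length_asymmetry_pct"),
        mean = c(0.87, 0.97, 13.23, 98.30, 38.54, 7.67),
        sd = c(0.44, 0.62, 3.92, 18.89, 10.26, 4.83)),
      peaks = bind_rows(
        tibble(dof = dofs, measure = meas, role = "affected",
               mean = c(-5.10, -0.86, 4.00, 20.25, -11.96, 1.63, -5.17,
                        -7.65, -13.47, 37.39, 0.30, 6.49, -8.94, 5.37,
                        -4.60),
               sd = c(5.59, 3.18, 6.26, 7.72, 6.49, 4.52, 4.43, 6.33,
                      6.77, 13.69, 3.21, 12.35, 9.91, 12.79, 11.44)),
        tibble(dof = dofs, measure = meas, role = "unaffected",
               mean = c(-2.12, -3.01, 0.40, 17.75, -10.92, 3.01, -5.31,
                        -9.63, -20.46, 36.13, 0.05, 8.68, -7.82, 13.39,
                        0.69),
               sd = c(5.56, 3.15, 7.19, 7.54, 8.34, 5.33, 11.36, 7.69,
                      12.61, 16.51, 2.75, 12.00, 10.45, 11.06, 18.75))),
      demographics = list(age_mean = 68.82, age_sd = 5.54,
                          n_male = 11, n_female = 22,
                          bmi_mean = 24.84, bmi_sd = 3.76,
                          left_affected_prop = 14 / 33)
    )
  }
}

#' Specification of a synthetic gait cohort
#'
#' Bundles everything needed to generate one group of walking trials:
#' group size, trial structure, sampling rate, the spatiotemporal and
#' peak-angle targets (group mean and between-participant SD), and the
#' noise model. The defaults encode the built-in [group_targets()].
#'
#' Internal consistency is validated at construction: the cadence-implied
#' stride (`speed * 120 / cadence`) must match any stride target within
#' 10%, and the double-support target must keep the stance fraction
#' `s = 0.5 + DS/200` inside (0.5, 0.75).
#'
#' @param group `"control"` or `"koa"`.
#' @param n Participants (defaults: 78 control, 33 koa).
#' @param trials Walking trials per participant (default 3).
#' @param cycles_per_trial Gait cycles per trial per foot (default 4,
#'   what a 6 m walkway at these stride lengths yields).
#' @param frame_rate Sampling rate in Hz (default 60).
#' @param targets,peak_targets Optional overrides of the built-in target
#'   tibbles (same columns as [group_targets()]).
#' @param marker_noise_sd White marker noise SD in metres (default 0.002,
#'   i.e. 2 mm, the scale of smartphone-video keypoint jitter).
#' @param angle_noise_sd White joint-angle noise SD in degrees (default 0.5).
#' @param cycle_jitter_cv CV of per-cycle duration jitter (default 0.02).
#' @param cycle_amp_jitter SD of the per-cycle multiplicative amplitude
#'   jitter on angle waveforms (default 0.03).
#' @param side_sd Between-side SD (degrees) added to bilateral peak draws
#'   for control participants (default 2).
#' @param moment_match Standardize participant draws so the sample mean/SD
#'   equal the targets exactly (default `TRUE`); draws are then clipped to
#'   physical bounds and re-centred once.
#' @param seed_note Free-text note stored with the spec (not used).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(group = c("control", "koa"), n = NULL, trials = 3L,
                        cycles_per_trial = 4L, frame_rate = 60,
                        targets = NULL, peak_targets = NULL,
                        marker_noise_sd = 0.002, angle_noise_sd = 0.5,
                        cycle_jitter_cv = 0.02, cycle_amp_jitter = 0.03,
                        side_sd = 2, moment_match = TRUE, seed_note = NULL) {
  group <- match.arg(group)
  built <- group_targets(group)
  targets <- targets %||% built$spatiotemporal
  peak_targets <- peak_targets %||% built$peaks
  n <- n %||% if (group == "control") 78L else 33L
  assert_that(n >= 1 && trials >= 1 && cycles_per_trial >= 1,
              "cohort sizes must be positive")
  assert_that(all(targets$sd >= 0) && all(peak_targets$sd >= 0),
              "target SDs must be non-negative")
  tv <- function(p) targets$mean[targets$parameter == p]
  implied_stride <- tv("gait_speed") * 120 / tv("cadence")
  if (length(tv("stride_length"))) {
    rel <- abs(implied_stride - tv("stride_length")) / tv("stride_length")
    assert_that(rel <= 0.10,
                "inconsistent targets: cadence-implied stride %.3f m vs stride target %.3f m (%.0f%% apart)",
                implied_stride, tv("stride_length"), 100 * rel)
  }
  s_mean <- 0.5 + tv("double_support_pct") / 200
  assert_that(s_mean > 0.5 && s_mean < 0.75,
              "double-support target %.1f%% implies stance fraction %.3f outside (0.5, 0.75)",
              tv("double_support_pct"), s_mean)
  structure(
    list(group = group, n = as.integer(n), trials = as.integer(trials),
         cycles_per_trial = as.integer(cycles_per_trial),
         frame_rate = frame_rate, targets = targets,
         peak_targets = peak_targets, demographics = built$demographics,
         marker_noise_sd = marker_noise_sd, angle_noise_sd = angle_noise_sd,
         cycle_jitter_cv = cycle_jitter_cv,
         cycle_amp_jitter = cycle_amp_jitter, side_sd = side_sd,
         moment_match = moment_match, seed_note = seed_note),
    class = "cohort_spec"
  )
}

# moment-matched draws clipped to physical bounds
moment_draws <- function(n, mean, sd, lo = -Inf, hi = Inf,
                         moment_match = TRUE) {
  if (sd == 0 || n == 1) return(pmin(pmax(rep(mean, n), lo), hi))
  z <- rnorm(n)
  if (moment_match && n >= 2) z <- (z - mean(z)) / sd(z)
  x <- mean + sd * z
  x <- pmin(pmax(x, lo), hi)
  if (moment_match) x <- pmin(pmax(x + (mean - mean(x)), lo), hi)
  x
}

spat_bounds <- list(
  gait_speed = c(0.2, 3), stride_length = c(0.3, 2.5),
  step_width_cm = c(1, 30), cadence = c(45, 200),
  double_support_pct = c(5, 49.5), step_length_asymmetry_pct = c(0.05, 45)
)

peak_bounds <- list(
  knee_angle = list(flexion = c(8, 95), extension = c(-15, 30)),
  hip_flexion = list(flexion = c(0, 55), extension = c(-40, 12)),
  hip_adduction = list(adduction = c(-12, 28), abduction = c(-35, 10)),
  hip_rotation = list(internal_rotation = c(-28, 30),
                      external_rotation = c(-40, 8)),
  ankle_angle = list(dorsiflexion = c(-25, 45), plantarflexion = c(-55, 25)),
  subtalar_angle = list(inversion = c(-40, 55), eversion = c(-55, 40)),
  pelvis_tilt = list(peak = c(-35, 35)),
  pelvis_list = list(peak = c(-35, 35)),
  pelvis_rotation = list(peak = c(-35, 35))
)

# which measure is the curve maximum vs minimum of its dof
measure_is_max <- c(flexion = TRUE, extension = FALSE, adduction = TRUE,
                    abduction = FALSE, internal_rotation = TRUE,
                    external_rotation = FALSE, dorsiflexion = TRUE,
                    plantarflexion = FALSE, inversion = TRUE,
                    eversion = FALSE, peak = TRUE)

#' Draw participant-level ground-truth parameters
#'
#' Draws each participant's true spatiotemporal parameters and peak-angle
#' targets from the cohort spec's group mean/SD (moment-matched by default,
#' clipped at physical bounds), assigns demographics, and derives the
#' per-participant stance fraction and stride length. Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble, one row per participant, with a `peaks` list-column of
#'   per-dof/side target extrema.
#' @export
draw_participants <- function(spec) {
  n <- spec$n
  tg <- spec$targets
  draw_one <- function(p) {
    b <- spat_bounds[[p]] %||% c(-Inf, Inf)
    i <- which(tg$parameter == p)
    moment_draws(n, tg$mean[i], tg$sd[i], b[1], b[2], spec$moment_match)
  }
  out <- tibble(
    participant = sprintf("%s%03d", spec$group, seq_len(n)),
    group = spec$group,
    gait_speed = draw_one("gait_speed"),
    cadence = draw_one("cadence"),
    step_width_cm = draw_one("step_width_cm"),
    double_support_pct = draw_one("double_support_pct"),
    step_length_asymmetry_pct = draw_one("step_length_asymmetry_pct")
  )
  out$stance_fraction <- 0.5 + out$double_support_pct / 200
  out$stride_length <- out$gait_speed * 120 / out$cadence

  dg <- spec$demographics
  male_n <- round(n * dg$n_male / (dg$n_male + dg$n_female))
  out$sex <- sample(c(rep("M", male_n), rep("F", n - male_n)))
  out$age <- moment_draws(n, dg$age_mean, dg$age_sd, 30, 95, spec$moment_match)
  out$bmi <- moment_draws(n, dg$bmi_mean, dg$bmi_sd, 15, 45, spec$moment_match)
  out$affected_side <- if (is.na(dg$left_affected_prop)) NA_character_ else {
    nl <- round(n * dg$left_affected_prop)
    sample(c(rep("L", nl), rep("R", n - nl)))
  }

  # peak-angle targets: one draw per dof/measure/role, then mapped to sides
  pk <- spec$peak_targets
  draws <- pk %>%
    group_by(.data$dof, .data$measure, .data$role) %>%
    dplyr::group_modify(function(g, key) {
      b <- peak_bounds[[key$dof]][[key$measure]] %||% c(-Inf, Inf)
      tibble(participant = out$participant,
             value = moment_draws(n, g$mean, g$sd, b[1], b[2],
                                  spec$moment_match))
    }) %>% ungroup()

  side_of <- function(i, role) {
    if (role == "affected") out$affected_side[i]
    else if (role == "unaffected") setdiff(c("L", "R"), out$affected_side[i])
    else NA_character_
  }
  out$peaks <- purrr::map(seq_len(n), function(i) {
    di <- draws[draws$participant == out$participant[i], ]
    res <- list()
    for (r in unique(di$role)) {
      sides <- if (r == "bilateral") c("L", "R") else side_of(i, r)
      for (sd_ in sides) {
        for (dof in unique(di$dof)) {
          # one physical pelvis: calibrated once, to the affected-side
          # (or bilateral) target; skip the would-be second assignment
          if (startsWith(dof, "pelvis") && r == "unaffected") next
          rows <- di[di$dof == dof & di$role == r, ]
          vals <- setNames(rows$value, rows$measure)
          if (r == "bilateral" && spec$side_sd > 0 && dof != "pelvis_tilt" &&
              !startsWith(dof, "pelvis")) {
            vals <- vals + rnorm(length(vals), 0, spec$side_sd)
          }
          is_max <- measure_is_max[names(vals)]
          tmax <- unname(vals[is_max]); tmin <- unname(vals[!is_max])
          key <- if (startsWith(dof, "pelvis")) dof else
            paste0(dof, "_", tolower(sd_))
          if (length(tmin) == 0) {
            res[[key]] <- c(max = tmax)
          } else {
            if (tmax < tmin + 3) {           # keep extrema separated
              mid <- (tmax + tmin) / 2
              tmax <- mid + 1.5; tmin <- mid - 1.5
            }
            res[[key]] <- c(max = tmax, min = tmin)
          }
        }
      }
    }
    res
  })
  out
}

# calibrated templates for one participant's peak targets
calibrate_participant <- function(peaks) {
  tpl <- gait_templates()
  purrr::imap(peaks, function(tg, key) {
    base <- sub("_[lr]$", "", key)
    if (is.na(tg["min"]) || length(tg) == 1) {
      calibrate_template(tpl[[base]], tg[["max"]])
    } else {
      calibrate_template(tpl[[base]], tg[["max"]], tg[["min"]])
    }
  })
}

# phase of each time point given an (extended) strike sequence
phase_of <- function(t, strikes) {
  k <- findInterval(t, strikes, all.inside = TRUE)
  (t - strikes[k]) / (strikes[k + 1] - strikes[k])
}

cycle_index_of <- function(t, strikes) {
  findInterval(t, strikes, all.inside = TRUE)
}

# zero-end-slope transition from 0 to 1 on [a, 1]
ease_from <- function(phi, a) {
  u <- pmax(pmin((phi - a) / (1 - a), 1), 0)
  (1 - cos(pi * u)) / 2
}

#' Synthesize one walking trial
#'
#' Builds marker trajectories (heels, toes, pelvis; millimetres) and the
#' joint-angle series for one trial of one participant, together with the
#' ground-truth event times. The trial contains `spec$cycles_per_trial`
#' gait cycles per foot with per-cycle duration jitter, plus lead-in and
#' lead-out padding so every recorded event has full local support.
#' Consumes the current RNG state.
#'
#' @param draw One row of [draw_participants()] (as a list or 1-row tibble).
#' @param spec The [cohort_spec()].
#' @param templates Optional pre-calibrated template list (computed from
#'   `draw$peaks` when `NULL`).
#' @param heading Walking direction in radians within the horizontal plane
#'   (default 0 = along +X).
#' @return List with `markers` (a [marker_set()], mm), `angles` (a
#'   [joint_angle_series()]), `events_truth` (tibble `foot`, `event`,
#'   `time`) and `truth` (the participant's true parameter values).
#' @export
synth_trial <- function(draw, spec, templates = NULL, heading = 0) {
  if (is.data.frame(draw)) draw <- as.list(draw[1, ])
  if (is.list(draw$peaks) && !is.null(draw$peaks[[1]]) &&
      is.list(draw$peaks[[1]]) && is.null(names(draw$peaks))) {
    draw$peaks <- draw$peaks[[1]]
  }
  templates <- templates %||% calibrate_participant(draw$peaks)
  fr <- spec$frame_rate
  n_cyc <- spec$cycles_per_trial
  T0 <- 120 / draw$cadence
  s <- draw$stance_fraction
  v <- draw$gait_speed
  width <- draw$step_width_cm / 100
  delta <- draw$step_length_asymmetry_pct / 200

  # extended left-strike sequence: one virtual cycle each side
  durs <- T0 * (1 + rnorm(n_cyc + 2, 0, spec$cycle_jitter_cv))
  durs <- pmax(durs, 0.3 * T0)
  hL_ext <- 0.8 * T0 - durs[1] + cumsum(c(0, durs))   # h_{-1} .. h_{n+1}
  hL <- hL_ext[2:(n_cyc + 2)]                          # recorded strikes
  t_end <- hL[length(hL)] + 0.8 * T0
  time <- seq(0, floor(t_end * fr) / fr, by = 1 / fr)

  # right strikes at mid-cycle of the left sequence
  hR_ext <- hL_ext[-length(hL_ext)] + 0.5 * diff(hL_ext)
  # forward position ladder: alternate left/right landings
  nseg <- length(hL_ext) - 1
  XL <- numeric(length(hL_ext)); XR <- numeric(length(hR_ext))
  XL[1] <- 0
  for (k in seq_len(nseg)) {
    stride_k <- v * (hL_ext[k + 1] - hL_ext[k])
    XR[k] <- XL[k] + stride_k * (1 + delta) / 2
    XL[k + 1] <- XR[k] + stride_k * (1 - delta) / 2
  }

  foot_traj <- function(strikes, Xs, lateral, s_frac) {
    phi <- phase_of(time, strikes)
    k <- cycle_index_of(time, strikes)
    x0 <- Xs[k]; x1 <- Xs[pmin(k + 1, length(Xs))]
    a_heel <- 0.8 * s_frac
    heel_f <- x0 + (x1 - x0) * ease_from(phi, a_heel)
    heel_v <- 0.06 * (1 - cos(2 * pi * phi)) / 2
    # toe bump: raised cosine whose steepest ascent falls exactly at the
    # true toe-off (phase = stance fraction); the toe touches down 8% of a
    # cycle after the next heel strike, as in real gait, which keeps the
    # velocity peak locally symmetric even at high stance fractions
    toe_land <- 0.08
    w_toe <- 4 * (1 + toe_land - s_frac) / 3
    a_toe <- s_frac - w_toe / 4
    bump <- function(u) {
      u <- pmax(pmin(u, 1), 0)
      (1 - cos(2 * pi * u)) / 2
    }
    toe_v <- 0.05 * (bump((phi - a_toe) / w_toe) +
                       bump((phi + 1 - a_toe) / w_toe))
    toe_f <- x0 + 0.20 + (x1 - x0) * ease_from(phi, s_frac)
    list(heel_f = heel_f, heel_v = heel_v, heel_l = rep(lateral, length(time)),
         toe_f = toe_f, toe_v = toe_v, toe_l = rep(lateral, length(time)))
  }
  L <- foot_traj(hL_ext, XL, +width / 2, s)
  R <- foot_traj(hR_ext, XR, -width / 2, s)

  phiL <- phase_of(time, hL_ext)
  pel_f <- XL[1] + 0.3 + v * time
  pel_v <- 0.95 + 0.015 * cos(4 * pi * phiL)
  pel_l <- 0.02 * sin(2 * pi * phiL)

  rot <- function(f, l) list(h1 = cos(heading) * f - sin(heading) * l,
                             h2 = sin(heading) * f + cos(heading) * l)
  nz <- function() rnorm(length(time), 0, spec$marker_noise_sd)
  mk_cols <- function(f, vtc, l) {
    h <- rot(f, l)
    tibble(X = (h$h1 + nz()) * 1000, Y = (vtc + nz()) * 1000,
           Z = (h$h2 + nz()) * 1000)
  }
  mk <- list(
    L_heel = mk_cols(L$heel_f, L$heel_v, L$heel_l),
    R_heel = mk_cols(R$heel_f, R$heel_v, R$heel_l),
    L_toe = mk_cols(L$toe_f, L$toe_v, L$toe_l),
    R_toe = mk_cols(R$toe_f, R$toe_v, R$toe_l),
    pelvis = mk_cols(pel_f, pel_v, pel_l)
  )
  mdata <- tibble(frame = seq_along(time), time = time)
  for (nm in names(mk)) {
    mdata[[paste0(nm, "_X")]] <- mk[[nm]]$X
    mdata[[paste0(nm, "_Y")]] <- mk[[nm]]$Y
    mdata[[paste0(nm, "_Z")]] <- mk[[nm]]$Z
  }
  markers <- marker_set(mdata, frame_rate = fr, units = "mm")

  # joint angles: each side's dofs at that side's phase with per-cycle
  # amplitude jitter around the waveform midline
  phiR <- phase_of(time, hR_ext)
  kL <- cycle_index_of(time, hL_ext); kR <- cycle_index_of(time, hR_ext)
  jitL <- rnorm(nseg + 1, 0, spec$cycle_amp_jitter)
  jitR <- rnorm(nseg + 1, 0, spec$cycle_amp_jitter)
  ang_noise <- function() rnorm(length(time), 0, spec$angle_noise_sd)
  eval_dof <- function(key, phi, kk, jit) {
    tpl <- templates[[key]]
    tg <- draw$peaks[[key]]
    mid <- if (length(tg) == 1) tpl$a0 else (tg[["max"]] + tg[["min"]]) / 2
    base <- eval_template(tpl, phi)
    mid + (1 + jit[kk]) * (base - mid) + ang_noise()
  }
  adata <- tibble(time = time)
  for (p in c("pelvis_tilt", "pelvis_list", "pelvis_rotation")) {
    adata[[p]] <- eval_dof(p, phiL, kL, jitL)
  }
  for (dof in c("hip_flexion", "hip_adduction", "hip_rotation",
                "knee_angle", "ankle_angle", "subtalar_angle")) {
    adata[[paste0(dof, "_l")]] <- eval_dof(paste0(dof, "_l"), phiL, kL, jitL)
    adata[[paste0(dof, "_r")]] <- eval_dof(paste0(dof, "_r"), phiR, kR, jitR)
  }
  angles <- joint_angle_series(adata)

  ev_in <- function(x) x[x >= 0.25 * T0 & x <= t_end - 0.25 * T0]
  to_L <- hL_ext[-length(hL_ext)] + s * diff(hL_ext)
  to_R <- hR_ext[-length(hR_ext)] + s * diff(hR_ext)
  events_truth <- bind_rows(
    tibble(foot = "L", event = "heel_strike", time = ev_in(hL_ext)),
    tibble(foot = "L", event = "toe_off", time = ev_in(to_L)),
    tibble(foot = "R", event = "heel_strike", time = ev_in(hR_ext)),
    tibble(foot = "R", event = "toe_off", time = ev_in(to_R))
  ) %>% arrange(.data$foot, .data$event, .data$time)

  list(markers = markers, angles = angles, events_truth = events_truth,
       truth = draw[c("participant", "group", "gait_speed", "cadence",
                      "step_width_cm", "double_support_pct",
                      "step_length_asymmetry_pct", "stride_length")])
}

#' Generate a synthetic gait cohort
#'
#' Draws participant-level ground truth (see [draw_participants()]) and
#' synthesizes all trials. Deterministic for a given seed. With `dir` set,
#' trials are also written as TRC/MOT file pairs alongside `truth.csv`,
#' `events_truth.csv` and `demographics.csv`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @param dir Optional output directory.
#' @return List with `spec`, `participants` (ground-truth tibble),
#'   `trials` (tibble with list-columns `markers`, `angles`,
#'   `events_truth`), and `dir` (or `NULL`).
#' @export
generate_cohort <- function(spec, seed = NULL, dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  participants <- draw_participants(spec)
  trials <- purrr::map_dfr(seq_len(nrow(participants)), function(i) {
    draw <- as.list(participants[i, ])
    draw$peaks <- participants$peaks[[i]]
    templates <- calibrate_participant(draw$peaks)
    purrr::map_dfr(seq_len(spec$trials), function(tr) {
      syn <- synth_trial(draw, spec, templates = templates)
      tibble(participant = draw$participant, group = draw$group,
             trial = tr, markers = list(syn$markers),
             angles = list(syn$angles),
             events_truth = list(syn$events_truth))
    })
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(trials))) {
      stem <- file.path(dir, sprintf("%s_trial%d", trials$participant[i],
                                     trials$trial[i]))
      write_trc(trials$markers[[i]], paste0(stem, ".trc"))
      write_mot(trials$angles[[i]], paste0(stem, ".mot"))
    }
    truth_long <- participants %>%
      select("participant", "group", "gait_speed", "cadence",
             "step_width_cm", "double_support_pct",
             "step_length_asymmetry_pct", "stride_length") %>%
      tidyr::pivot_longer(-c("participant", "group"),
                          names_to = "parameter", values_to = "true_value")
    utils::write.csv(truth_long, file.path(dir, "truth.csv"),
                     row.names = FALSE)
    ev <- purrr::map_dfr(seq_len(nrow(trials)), function(i)
      mutate(trials$events_truth[[i]], participant = trials$participant[i],
             trial = trials$trial[i]))
    utils::write.csv(ev, file.path(dir, "events_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(
      select(participants, "participant", "group", "age", "sex", "bmi",
             "affected_side"),
      file.path(dir, "demographics.csv"), row.names = FALSE)
  }
  list(spec = spec, participants = participants, trials = trials, dir = dir)
}

#' Load a cohort directory written by [generate_cohort()]
#'
#' Reads the TRC/MOT trial pairs plus `demographics.csv` and `truth.csv`
#' back into the in-memory cohort form accepted by [run_cohort()].
#'
#' @param dir Directory written by `generate_cohort(..., dir = )`.
#' @return List with `participants`, `trials` and `dir`.
#' @export
read_cohort <- function(dir) {
  assert_that(dir.exists(dir), "directory '%s' does not exist", dir)
  trcs <- sort(list.files(dir, pattern = "_trial\\d+\\.trc$",
                          full.names = TRUE))
  assert_that(length(trcs) > 0, "no trial files in '%s'", dir)
  trials <- purrr::map_dfr(trcs, function(f) {
    stem <- sub("\\.trc$", "", f)
    id <- sub("_trial\\d+$", "", basename(stem))
    tr <- as.integer(sub(".*_trial", "", basename(stem)))
    tibble(participant = id, trial = tr,
           markers = list(read_trc(f)),
           angles = list(read_mot(paste0(stem, ".mot"))))
  })
  demo <- utils::read.csv(file.path(dir, "demographics.csv"),
                          stringsAsFactors = FALSE)
  truth <- utils::read.csv(file.path(dir, "truth.csv"),
                           stringsAsFactors = FALSE)
  participants <- as_tibble(demo) %>%
    left_join(tidyr::pivot_wider(as_tibble(truth),
                                 names_from = "parameter",
                                 values_from = "true_value"),
              by = c("participant", "group"))
  list(participants = participants, trials = trials, dir = dir)
}
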