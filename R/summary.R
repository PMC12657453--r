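#' Per-participant representative values
#'
#' Averages per-cycle parameters across each participant's valid gait
#' cycles after screening the pooled dataset with the +/- `outlier_k` SD
#' rule (applied once per parameter over all cycles of all participants,
#' see [outlier_mask()]). Step-length asymmetry is computed per participant
#' from the retained step lengths of each landing foot. Peak joint angles
#' are screened per dof/side/measure and averaged per participant and side.
#'
#' @param cycle_params Pooled per-cycle tibble from [cycle_parameters()],
#'   with an added `participant` column.
#' @param cycle_peaks Optional pooled tidy peak tibble from [peak_angles()]
#'   with added `participant` (and `cycle`) columns.
#' @param outlier_k Pooled SD multiplier (default 3).
#' @return List with `spatiotemporal` (one row per participant: means of
#'   gait speed, stride length, step width, cadence, double support, plus
#'   `step_length_asymmetry_pct` and `n_cycles`) and `peaks` (one row per
#'   participant x dof x side x measure with `value` and `n_cycles`).
#' @export
participant_summary <- function(cycle_params, cycle_peaks = NULL, outlier_k = 3) {
  assert_that("participant" %in% names(cycle_params),
              "cycle_params needs a 'participant' column")
  p <- cycle_params
  num_cols <- c("gait_speed", "stride_length", "step_width", "cadence",
                "double_support_pct")
  for (cl in intersect(num_cols, names(p))) {
    if (sum(is.finite(p[[cl]])) >= 3) {
      keep <- outlier_mask(p[[cl]], outlier_k)
      p[[cl]][!keep] <- NA_real_
    }
  }

  # step lengths attributed to the landing foot, pooled screen, then the
  # asymmetry formula on each participant's mean left/right step
  steps <- bind_rows(
    tibble(participant = p$participant,
           landing_foot = ifelse(p$foot == "L", "R", "L"),
           length = p$step_contra),
    tibble(participant = p$participant, landing_foot = p$foot,
           length = p$step_ipsi)
  ) %>% filter(is.finite(.data$length))
  if (sum(is.finite(steps$length)) >= 3) {
    steps <- steps[outlier_mask(steps$length, outlier_k), ]
  }
  asym <- steps %>%
    group_by(.data$participant, .data$landing_foot) %>%
    summarise(m = mean(.data$length), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "landing_foot", values_from = "m") %>%
    mutate(step_length_asymmetry_pct = dplyr::if_else(
      is.finite(.data$L) & is.finite(.data$R),
      100 * abs(.data$L - .data$R) / (0.5 * (.data$L + .data$R)),
      NA_real_)) %>%
    select("participant", "step_length_asymmetry_pct")

  spat <- p %>%
    group_by(.data$participant) %>%
    summarise(across(all_of(intersect(num_cols, names(p))),
                     ~ mean(.x, na.rm = TRUE)),
              n_cycles = dplyr::n(), .groups = "drop") %>%
    left_join(asym, by = "participant")

  peaks <- NULL
  if (!is.null(cycle_peaks) && nrow(cycle_peaks) > 0) {
    pk <- cycle_peaks %>%
      group_by(.data$dof, .data$side, .data$measure) %>%
      mutate(.keep_val = if (dplyr::n() >= 3) outlier_mask(.data$value, outlier_k)
             else TRUE) %>%
      ungroup() %>%
      filter(.data$.keep_val)
    peaks <- pk %>%
      group_by(.data$participant, .data$dof, .data$side, .data$measure) %>%
      summarise(value = mean(.data$value), n_cycles = dplyr::n(),
                .groups = "drop")
  }
  list(spatiotemporal = spat, peaks = peaks)
}
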