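test_that("flat trajectories yield no events, with a warning", {
  expect_warning(hs <- detect_heel_strikes(rep(0.05, 200), 60), "flat")
  expect_length(hs, 0)
  expect_warning(to <- detect_toe_offs(rep(0.05, 200), 60), "flat")
  expect_length(to, 0)
})

test_that("refractory rule keeps the deeper of two close minima", {
  t <- seq(0, 2, by = 1 / 60)
  # two dips 0.2 s apart, the second deeper
  y <- 0.05 - 0.02 * exp(-((t - 0.9) / 0.05)^2) -
    0.04 * exp(-((t - 1.1) / 0.05)^2)
  hs <- detect_heel_strikes(y, 60, min_interval = 0.5)
  expect_length(hs, 1)
  expect_equal(hs, 1.1, tolerance = 0.02)
})

test_that("a monotone rising ramp yields at most one toe-off", {
  to <- detect_toe_offs(seq(0, 0.5, length.out = 120), 60)
  expect_lte(length(to), 1)
})

test_that("detection is invariant to vertical offsets", {
  co <- small_cohort(n = 1, cycles = 4, seed = 21)
  ms <- co$trials$markers[[1]]
  h <- marker_xyz(ms, "L_heel")$vertical
  a <- detect_heel_strikes(savgol_smooth(h, 15, 3), 60)
  b <- detect_heel_strikes(savgol_smooth(h + 0.37, 15, 3), 60)
  expect_equal(a, b)
})

test_that("events on noise-free synthetic trials match truth within 1 frame", {
  co <- small_cohort(n = 3, trials = 1, cycles = 4, seed = 31,
                     marker_noise_sd = 0)
  for (i in seq_len(nrow(co$trials))) {
    det <- detect_gait_events(co$trials$markers[[i]])
    err <- event_errors_frames(det, co$trials$events_truth[[i]])
    expect_lt(max(err$err), 1)
  }
})

test_that("stance pairing matches each heel strike to the next toe-off", {
  ev <- tibble::tibble(
    foot = "L",
    event = rep(c("heel_strike", "toe_off"), each = 2),
    time = c(0, 1, 0.62, 1.62))
  si <- stance_intervals(ev, "L")
  expect_equal(si$start, c(0, 1))
  expect_equal(si$end, c(0.62, 1.62))

  # leading toe-off dropped
  ev2 <- dplyr::bind_rows(tibble::tibble(foot = "L", event = "toe_off",
                                         time = -0.4), ev)
  expect_equal(nrow(stance_intervals(ev2, "L")), 2)

  empty <- tibble::tibble(foot = character(), event = character(),
                          time = numeric())
  expect_equal(nrow(stance_intervals(empty, "L")), 0)
})

test_that("cycle segmentation follows consecutive ipsilateral heel strikes", {
  angles <- joint_angle_series(tibble::tibble(
    time = seq(0, 3, by = 1 / 60),
    knee_angle_l = sin(seq(0, 3, by = 1 / 60) * 2 * pi)))
  ev <- tibble::tibble(foot = "L", event = "heel_strike",
                       time = c(0.0, 1.0, 2.1))
  cyc <- segment_cycles(ev, angles, "L")
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$duration, c(1.0, 1.1))
  expect_true(all(vapply(cyc$curves, nrow, integer(1)) == 101))

  # a single heel strike gives no cycles
  ev1 <- ev[1, ]
  expect_equal(nrow(segment_cycles(ev1, angles, "L")), 0)
})

test_that("cycle count equals heel strikes minus one before QC", {
  co <- small_cohort(n = 2, cycles = 5, seed = 41)
  for (i in seq_len(nrow(co$trials))) {
    det <- detect_gait_events(co$trials$markers[[i]])
    for (f in c("L", "R")) {
      n_hs <- sum(det$foot == f & det$event == "heel_strike")
      cyc <- segment_cycles(det, co$trials$angles[[i]], f)
      expect_equal(nrow(cyc), max(n_hs - 1, 0))
    }
  }
})

test_that("QC rejects duration, discontinuity and implausibility faults", {
  mat <- matrix(20, nrow = 101, ncol = 1,
                dimnames = list(NULL, "knee_angle_l"))
  base <- tibble::tibble(foot = "L", cycle = 1L, start = 1, end = 2.1,
                         duration = 1.1, curves = list(mat),
                         cycle_events = list(NULL))

  long <- dplyr::mutate(base, end = 6, duration = 5)
  out <- qc_cycles(long, qc_criteria())
  expect_equal(out$rejections$reason, "abnormal_timing")

  hot <- base
  hot$curves[[1]][50, 1] <- 170
  out <- qc_cycles(hot, qc_criteria())
  expect_equal(out$rejections$reason, "implausible")

  gaps <- tibble::tibble(start_time = 1.4, end_time = 1.6, marker = "L_heel")
  out <- qc_cycles(base, qc_criteria(), gap_report = gaps)
  expect_equal(out$rejections$reason, "marker_discontinuity")

  # clean cycle passes
  out <- qc_cycles(base, qc_criteria())
  expect_equal(nrow(out$accepted), 1)
  expect_equal(nrow(out$rejections), 0)
})

test_that("a clean synthetic cohort passes QC completely", {
  co <- small_cohort(n = 2, trials = 2, cycles = 4, seed = 51)
  for (i in seq_len(nrow(co$trials))) {
    res <- run_trial(co$trials$markers[[i]], co$trials$angles[[i]])
    expect_equal(nrow(res$rejections), 0)
    expect_gt(nrow(res$cycles), 0)
  }
})
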